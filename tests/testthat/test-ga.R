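test_that("subset fitness is penalized cross-validated performance", {
  syn <- fixture_classification()
  inf <- syn$informative_columns
  res0 <- evaluate_subset(inf, syn$data, syn$labels, "classification",
                          penalty_per_descriptor = 0, seed = 4)
  expect_equal(res0$fitness, res0$raw_score)
  res <- evaluate_subset(inf, syn$data, syn$labels, "classification",
                         penalty_per_descriptor = 0.01, seed = 4)
  expect_equal(res$fitness, res$raw_score - 0.01 * length(inf))
  # seeded CV is deterministic
  res2 <- evaluate_subset(inf, syn$data, syn$labels, "classification",
                          penalty_per_descriptor = 0.01, seed = 4)
  expect_identical(res, res2)
  expect_error(
    evaluate_subset(c("nope"), syn$data, syn$labels, "classification"),
    "unknown columns")
})

test_that("planted subsets outscore size-matched noise subsets", {
  wins <- 0
  for (s in 1:20) {
    syn <- make_synthetic_classification(150, 30, 10, effect_size = 1,
                                         seed = 100 + s)
    noise <- setdiff(setdiff(names(syn$data), "compound_id"),
                     syn$informative_columns)[1:10]
    f_inf <- evaluate_subset(syn$informative_columns, syn$data, syn$labels,
                             "classification", seed = s)$fitness
    f_noise <- evaluate_subset(noise, syn$data, syn$labels,
                               "classification", seed = s)$fitness
    wins <- wins + (f_inf > f_noise)
  }
  expect_gt(wins, 10)  # majority over 20 seeds
})

test_that("parent selection keeps the top fraction with size tie-breaks", {
  pop <- list(
    list(members = c("a", "b"), fitness = 0.5),
    list(members = c("a"), fitness = 0.9),
    list(members = c("a", "b", "c"), fitness = 0.7),
    list(members = c("b"), fitness = 0.3))
  parents <- select_parents(pop, 0.5)
  expect_equal(length(parents), 2)
  expect_equal(parents[[1]]$fitness, 0.9)
  expect_equal(parents[[2]]$fitness, 0.7)
  # all-equal fitness: smallest subsets win
  pop_eq <- list(
    list(members = letters[1:3], fitness = 0.5),
    list(members = letters[1:2], fitness = 0.5),
    list(members = "a", fitness = 0.5),
    list(members = letters[1:4], fitness = 0.5))
  expect_equal(select_parents(pop_eq, 0.5)[[1]]$members, "a")
  # degenerate single-member population
  expect_equal(length(select_parents(pop[2], 0.5)), 1)
})

test_that("crossover recombines halves and never invents descriptors", {
  a <- c("d1", "d2", "d3", "d4"); b <- c("e1", "e2", "e3", "e4")
  kids <- ga_crossover(a, b, seed = 12)
  for (child in kids) {
    expect_true(all(child %in% union(a, b)))
    expect_equal(length(child), 4)  # 2 + 2 from disjoint size-4 parents
  }
  # identical parents: children stay within the parent set
  kids2 <- ga_crossover(a, a, seed = 3)
  expect_true(all(unlist(kids2) %in% a))
  expect_lte(length(kids2[[1]]), length(a))
})

test_that("mutation and deletion fire at their configured rates", {
  pool <- sprintf("d%02d", 1:20)
  sub <- pool[1:6]
  # zero probabilities: identity
  expect_equal(ga_mutate(sub, pool, 0, 0, seed = 1), sub)
  # deletion suppressed at size 1
  one <- ga_mutate(pool[1], pool, mutation_prob = 0, deletion_prob = 1,
                   seed = 2)
  expect_equal(length(one), 1)
  # pool == subset: mutation skipped, only deletion can act
  same <- ga_mutate(pool, pool, mutation_prob = 1, deletion_prob = 0,
                    seed = 3)
  expect_setequal(same, pool)
  # Monte-Carlo frequency of the mutation event
  fired <- vapply(1:10000, function(s) {
    out <- ga_mutate(sub, pool, mutation_prob = 0.3, deletion_prob = 0,
                     seed = s)
    !setequal(out, sub)
  }, logical(1))
  expect_equal(mean(fired), 0.3, tolerance = 0.05)
})

test_that("the GA is elitist, deterministic and pool-closed", {
  syn <- fixture_classification()
  cfg <- ga_config(population_size = 10, generations = 6, seed = 99)
  ga <- run_ga(syn$data, syn$labels, "classification", config = cfg)
  expect_true(all(diff(ga$trace$best_fitness) >= 0))
  expect_equal(nrow(ga$trace), 6)
  pool <- setdiff(names(syn$data), "compound_id")
  for (s in ga$population) expect_true(all(s$members %in% pool))
  # identical config and data reproduce the identical run
  ga2 <- run_ga(syn$data, syn$labels, "classification", config = cfg)
  expect_identical(ga$trace, ga2$trace)
  expect_identical(ga$best, ga2$best)
  # a single generation still returns a valid scored population
  ga1 <- run_ga(syn$data, syn$labels, "classification",
                config = ga_config(population_size = 6, generations = 1,
                                   seed = 1))
  expect_equal(nrow(ga1$trace), 1)
  expect_true(all(vapply(ga1$population, function(s) is.finite(s$fitness),
                         logical(1))))
  expect_error(run_ga(syn$data[, "compound_id", drop = FALSE], syn$labels,
                      "classification", config = cfg),
               "empty candidate")
})

test_that("penalty makes fitness strictly decreasing in subset size", {
  raw <- 0.8
  sizes <- 1:10
  fits <- raw - 0.001 * sizes
  expect_true(all(diff(fits) < 0))
  # and through the evaluator: same raw score columns, larger subset loses
  syn <- fixture_classification()
  inf <- syn$informative_columns
  small <- evaluate_subset(inf, syn$data, syn$labels, "classification",
                           penalty_per_descriptor = 0.05, seed = 2)
  big_members <- c(inf, setdiff(setdiff(names(syn$data), "compound_id"),
                                inf)[1:4])
  big <- evaluate_subset(big_members, syn$data, syn$labels, "classification",
                         penalty_per_descriptor = 0.05, seed = 2)
  expect_equal(small$fitness, small$raw_score - 0.05 * length(inf))
  expect_equal(big$fitness, big$raw_score - 0.05 * length(big_members))
})

test_that("GA tidiers expose the ranked population and trace", {
  syn <- fixture_classification(n = 80, d = 8)
  ga <- run_ga(syn$data, syn$labels, "classification",
               config = ga_config(population_size = 6, generations = 2,
                                  seed = 3))
  td <- tidy(ga)
  expect_equal(nrow(td), length(ga$population))
  expect_true(all(diff(td$fitness) <= 0))  # ranked best-first
  g <- glance(ga)
  expect_equal(g$best_fitness, td$fitness[1])
  p <- ggplot2::autoplot(ga)
  expect_s3_class(p, "ggplot")
})
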