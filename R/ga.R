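#' Genetic-algorithm configuration
#'
#' Collects every tunable of the wrapper feature-selection GA. Defaults
#' follow the evolutionary scheme used for descriptor selection in QSAR
#' model generation: 30% mutation, 30% deletion, top-50% parent selection,
#' five-fold internal cross-validation, a 200-generation stopping criterion,
#' and a linear size penalty favouring smaller descriptor subsets.
#'
#' @param population_size Number of subsets per generation; default 50.
#' @param generations Generation cap; default 200.
#' @param parent_fraction Fraction of the population kept as parents;
#'   default 0.5.
#' @param mutation_prob Per-child probability of swapping one member for a
#'   random non-member; default 0.3.
#' @param deletion_prob Per-child probability of removing one member;
#'   default 0.3.
#' @param cv_folds Internal CV folds per fitness evaluation; default 5.
#' @param penalty_per_descriptor Linear fitness penalty per retained
#'   descriptor; default 0.001.
#' @param initial_inclusion_prob Per-descriptor inclusion probability when
#'   seeding the initial population; default 0.5.
#' @param init_mode `"per_subset"` (each subset independently includes each
#'   pool descriptor with `initial_inclusion_prob`, default) or
#'   `"restricted_pool"` (a single random half of the pool seeds all
#'   subsets).
#' @param seed Integer master seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 50, generations = 200,
                      parent_fraction = 0.5, mutation_prob = 0.3,
                      deletion_prob = 0.3, cv_folds = 5,
                      penalty_per_descriptor = 0.001,
                      initial_inclusion_prob = 0.5,
                      init_mode = c("per_subset", "restricted_pool"),
                      seed = 1) {
  init_mode <- match.arg(init_mode)
  stopifnot(population_size >= 2, generations >= 1, cv_folds >= 2,
            mutation_prob >= 0, mutation_prob <= 1,
            deletion_prob >= 0, deletion_prob <= 1,
            parent_fraction > 0, parent_fraction <= 1,
            initial_inclusion_prob > 0, initial_inclusion_prob <= 1,
            penalty_per_descriptor >= 0)
  structure(list(
    population_size = population_size, generations = generations,
    parent_fraction = parent_fraction, mutation_prob = mutation_prob,
    deletion_prob = deletion_prob, cv_folds = cv_folds,
    penalty_per_descriptor = penalty_per_descriptor,
    initial_inclusion_prob = initial_inclusion_prob,
    init_mode = init_mode, seed = as.integer(seed)
  ), class = "ga_config")
}

# Fast default CV learners for subset fitness: a logistic model for
# classification, ordinary least squares for regression, both fitted on raw
# matrices (stats::glm.fit / lm.fit) so thousands of subset evaluations per
# run stay cheap. Rank-deficient (aliased) columns get zero coefficients.
default_subset_builder <- function(task) {
  if (task == "classification") {
    function(x, y) {
      xm <- cbind(`(Intercept)` = 1, as.matrix(x))
      fit <- suppressWarnings(
        stats::glm.fit(xm, as.integer(y == "active"),
                       family = stats::binomial()))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      structure(list(beta = beta), class = "qsarens_glm_cls")
    }
  } else {
    function(x, y) {
      xm <- cbind(`(Intercept)` = 1, as.matrix(x))
      fit <- stats::lm.fit(xm, as.numeric(y))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      structure(list(beta = beta), class = "qsarens_lm_reg")
    }
  }
}

#' @export
predict.qsarens_glm_cls <- function(object, newdata, ...) {
  eta <- cbind(1, as.matrix(newdata)) %*% object$beta
  ifelse(stats::plogis(as.numeric(eta)) >= 0.5, "active", "inactive")
}

#' @export
predict.qsarens_lm_reg <- function(object, newdata, ...) {
  as.numeric(cbind(1, as.matrix(newdata)) %*% object$beta)
}

#' Penalized cross-validated fitness of a descriptor subset
#'
#' Trains the builder on the subset's columns under k-fold cross-validation
#' (stratified for classification), scores each fold (F1 for
#' classification, R-squared for regression), and penalizes the mean score
#' linearly in the subset size: fitness = raw_score - penalty * |subset|.
#'
#' @param members Character vector of descriptor names (non-empty).
#' @param data Feature tibble containing those columns.
#' @param labels Response vector.
#' @param task `"classification"` or `"regression"`.
#' @param cv_folds Folds; default 5.
#' @param penalty_per_descriptor Linear penalty; default 0.001.
#' @param seed Fold-assignment seed.
#' @param builder Model builder `function(x, y)`; default glm/lm.
#' @param id_col Id column name.
#' @return List with `raw_score` and `fitness`.
#' @export
evaluate_subset <- function(members, data, labels,
                            task = c("classification", "regression"),
                            cv_folds = 5, penalty_per_descriptor = 0.001,
                            seed = 1, builder = NULL,
                            id_col = "compound_id") {
  task <- match.arg(task)
  stopifnot(length(members) > 0)
  unknown <- setdiff(members, names(data))
  if (length(unknown) > 0) {
    stop("subset references unknown columns: ", paste(unknown, collapse = ", "))
  }
  builder <- builder %||% default_subset_builder(task)
  x <- data[, members, drop = FALSE]
  fold <- if (task == "classification") stratified_folds(labels, cv_folds, seed)
          else unstratified_folds(nrow(x), cv_folds, seed)
  scores <- vapply(seq_len(cv_folds), function(k) {
    tr <- fold != k
    fit <- builder(x[tr, , drop = FALSE], labels[tr])
    pred <- predict(fit, x[!tr, , drop = FALSE])
    if (task == "classification") {
      s <- f1_score(labels[!tr], pred)
      if (is.na(s)) 0 else s   # no positive predictions/cases: worst score
    } else {
      r_squared(labels[!tr], as.numeric(pred))
    }
  }, double(1))
  raw <- mean(scores)
  list(raw_score = raw,
       fitness = raw - penalty_per_descriptor * length(members))
}

#' Select the parent subsets of a generation
#'
#' Returns the top `parent_fraction` of the population by fitness
#' (`ceiling(fraction * N)` subsets). Ties break to the smaller subset,
#' then to the earlier position (stable).
#'
#' @param population List of subsets, each a list with `members` and
#'   `fitness`.
#' @param parent_fraction Fraction to keep; default 0.5.
#' @return The selected subsets, best first.
#' @export
select_parents <- function(population, parent_fraction = 0.5) {
  stopifnot(length(population) >= 1)
  n_keep <- ceiling(parent_fraction * length(population))
  fitness <- vapply(population, function(s) s$fitness, double(1))
  size <- vapply(population, function(s) length(s$members), double(1))
  ord <- order(-fitness, size, seq_along(population))
  population[ord[seq_len(n_keep)]]
}

#' Recombine two parent subsets into two children
#'
#' Each child receives a random half of one parent's members (ceiling for
#' the first child, floor for the second) and the complementary-sized random
#' half of the other parent's; duplicates collapse by set union, so children
#' are always subsets of the parents' union.
#'
#' @param parent_a,parent_b Character vectors of descriptor names.
#' @param seed Integer seed.
#' @return List of two character vectors.
#' @export
ga_crossover <- function(parent_a, parent_b, seed = 1) {
  stopifnot(length(parent_a) > 0, length(parent_b) > 0)
  with_seed(seed, {
    take_a1 <- sample(parent_a, ceiling(length(parent_a) / 2))
    take_b1 <- sample(parent_b, floor(length(parent_b) / 2))
    take_a2 <- setdiff(parent_a, take_a1)
    take_b2 <- setdiff(parent_b, take_b1)
    child_1 <- union(take_a1, take_b1)
    child_2 <- union(take_a2, take_b2)
    if (length(child_2) == 0) child_2 <- take_b1  # both floors empty at size 1
    list(child_1, child_2)
  })
}

#' Mutate a descriptor subset
#'
#' With probability `mutation_prob`, one uniformly chosen member is replaced
#' by a uniformly chosen non-member; independently, with probability
#' `deletion_prob`, one uniformly chosen member is removed. The subset never
#' shrinks below one member; mutation is skipped (no candidates) when the
#' subset already spans the pool.
#'
#' @param members Character vector (non-empty).
#' @param pool Candidate descriptor pool (superset of `members`).
#' @param mutation_prob,deletion_prob Event probabilities; defaults 0.3.
#' @param seed Integer seed.
#' @return Mutated character vector.
#' @export
ga_mutate <- function(members, pool, mutation_prob = 0.3,
                      deletion_prob = 0.3, seed = 1) {
  stopifnot(length(members) > 0, all(members %in% pool))
  with_seed(seed, {
    if (stats::runif(1) < mutation_prob) {
      candidates <- setdiff(pool, members)
      if (length(candidates) > 0) {
        out_m <- sample(members, 1)
        in_m <- candidates[sample.int(length(candidates), 1)]
        members <- c(setdiff(members, out_m), in_m)
      }
    }
    if (stats::runif(1) < deletion_prob && length(members) > 1) {
      members <- setdiff(members, sample(members, 1))
    }
    members
  })
}

subset_key <- function(members) paste(sort(members), collapse = "|")

#' Run the genetic algorithm for descriptor selection
#'
#' Evolves descriptor subsets toward maximal penalized cross-validated
#' performance: initialize by independent per-descriptor inclusion, then per
#' generation score the population, keep the top fraction as parents, pair
#' them, produce two children per pair by recombination, mutate/delete in
#' the children, and form the next generation from parents plus children
#' truncated to the population size by fitness (elitist, so the best fitness
#' never decreases). Fitness evaluations are cached by member set within a
#' run.
#'
#' @param data Preprocessed feature tibble.
#' @param labels Response vector.
#' @param task `"classification"` or `"regression"`.
#' @param config A [ga_config()].
#' @param builder Optional fitness model builder (see [evaluate_subset()]).
#' @param pool Candidate descriptor names; default all feature columns.
#' @param id_col Id column name.
#' @return A `qsar_ga` object: `population` (final, best first), `best`
#'   (members of the top subset), and `trace` (per-generation best fitness,
#'   raw score and size).
#' @export
run_ga <- function(data, labels, task = c("classification", "regression"),
                   config = ga_config(), builder = NULL, pool = NULL,
                   id_col = "compound_id") {
  task <- match.arg(task)
  pool <- pool %||% setdiff(names(data), id_col)
  if (length(pool) == 0) stop("empty candidate descriptor pool")
  cache <- new.env(parent = emptyenv())
  score <- function(members, eval_seed) {
    key <- subset_key(members)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- evaluate_subset(members, data, labels, task = task,
                           cv_folds = config$cv_folds,
                           penalty_per_descriptor = config$penalty_per_descriptor,
                           seed = eval_seed, builder = builder,
                           id_col = id_col)
    cache[[key]] <- res
    res
  }
  seeds <- derive_seeds(config$seed, 2 + config$generations)
  eval_seed <- seeds[1]   # one fold split per run: comparable fitnesses
  init_pool <- if (config$init_mode == "restricted_pool") {
    with_seed(seeds[2], sample(pool, max(1, floor(length(pool) / 2))))
  } else pool
  population <- with_seed(seeds[2], {
    purrr::map(seq_len(config$population_size), function(i) {
      inc <- stats::runif(length(init_pool)) < config$initial_inclusion_prob
      members <- init_pool[inc]
      if (length(members) == 0) members <- sample(init_pool, 1)
      list(members = members)
    })
  })
  population <- purrr::map(population, function(s) {
    res <- score(s$members, eval_seed)
    list(members = s$members, fitness = res$fitness, raw_score = res$raw_score)
  })
  trace <- vector("list", config$generations)
  for (gen in seq_len(config$generations)) {
    gen_seed <- seeds[2 + gen]
    parents <- select_parents(population, config$parent_fraction)
    sub_seeds <- derive_seeds(gen_seed, 2 * length(parents) + 2)
    # pair parents in rank order: (1,2), (3,4), ...
    children <- list()
    pair_idx <- if (length(parents) >= 2)
      seq(1, length(parents) - 1, by = 2) else integer(0)
    if (length(parents) >= 2) {
      for (pi in seq_along(pair_idx)) {
        a <- parents[[pair_idx[pi]]]$members
        b <- parents[[pair_idx[pi] + 1]]$members
        kids <- ga_crossover(a, b, seed = sub_seeds[2 * pi - 1])
        children <- c(children, kids)
      }
    } else {
      children <- list(parents[[1]]$members)
    }
    children <- purrr::imap(children, function(m, i) {
      ga_mutate(m, pool = init_pool, mutation_prob = config$mutation_prob,
                deletion_prob = config$deletion_prob,
                seed = sub_seeds[2 * length(pair_idx) + 1] + i)
    })
    scored_children <- purrr::map(children, function(m) {
      res <- score(m, eval_seed)
      list(members = m, fitness = res$fitness, raw_score = res$raw_score)
    })
    candidates <- c(parents, scored_children)
    fitness <- vapply(candidates, function(s) s$fitness, double(1))
    size <- vapply(candidates, function(s) length(s$members), double(1))
    ord <- order(-fitness, size, seq_along(candidates))
    population <- candidates[ord[seq_len(min(config$population_size,
                                             length(candidates)))]]
    best <- population[[1]]
    trace[[gen]] <- tibble::tibble(
      generation = gen, best_fitness = best$fitness,
      best_raw = best$raw_score, best_size = length(best$members))
  }
  structure(list(
    population = population,
    best = population[[1]]$members,
    trace = dplyr::bind_rows(trace),
    config = config, task = task, pool = pool
  ), class = "qsar_ga")
}

#' @export
print.qsar_ga <- function(x, ...) {
  cat(sprintf("GA feature selection (%s): %d generations, population %d\n",
              x$task, x$config$generations, x$config$population_size))
  cat(sprintf("best subset: %d descriptors, fitness %.4f (raw %.4f)\n",
              length(x$best), x$population[[1]]$fitness,
              x$population[[1]]$raw_score))
  invisible(x)
}

#' @method tidy qsar_ga
#' @export
tidy.qsar_ga <- function(x, ...) {
  tibble::tibble(
    rank = seq_along(x$population),
    members = purrr::map(x$population, "members"),
    size = purrr::map_int(x$population, ~ length(.x$members)),
    raw_score = purrr::map_dbl(x$population, "raw_score"),
    fitness = purrr::map_dbl(x$population, "fitness"))
}

#' @method glance qsar_ga
#' @export
glance.qsar_ga <- function(x, ...) {
  tibble::tibble(
    task = x$task, generations = x$config$generations,
    population_size = x$config$population_size,
    best_fitness = x$population[[1]]$fitness,
    best_raw = x$population[[1]]$raw_score,
    best_size = length(x$best))
}

#' Plot the GA best-fitness trace
#'
#' @param object A `qsar_ga` object.
#' @param ... Unused.
#' @return A ggplot of best fitness (and raw score) per generation.
#' @method autoplot qsar_ga
#' @export
autoplot.qsar_ga <- function(object, ...) {
  d <- tidyr::pivot_longer(object$trace, c("best_fitness", "best_raw"),
                           names_to = "series")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "score",
                  title = "GA descriptor-selection trace") +
    ggplot2::theme_minimal()
}

#' Write GA outputs (trace CSV + final subsets JSON)
#'
#' @param ga A `qsar_ga` object.
#' @param trace_path CSV path for the per-generation trace.
#' @param subsets_path Optional JSON path for the final population's member
#'   lists.
#' @return `ga`, invisibly.
#' @export
write_ga <- function(ga, trace_path, subsets_path = NULL) {
  readr::write_csv(ga$trace, trace_path)
  if (!is.null(subsets_path)) {
    jsonlite::write_json(purrr::map(ga$population, "members"), subsets_path)
  }
  invisible(ga)
}
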