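test_that("hard vote follows the majority for all 8 patterns", {
  pats <- expand.grid(m1 = c("active", "inactive"),
                      m2 = c("active", "inactive"),
                      m3 = c("active", "inactive"),
                      stringsAsFactors = FALSE)
  got <- hard_vote(as.matrix(pats))
  want <- ifelse(rowSums(pats == "active") > rowSums(pats == "inactive"),
                 "active", "inactive")
  expect_equal(got, want)
})

test_that("soft vote is a weight-normalized average with the 0.5 cutoff", {
  # hand arithmetic with the deployed weights
  sv <- soft_vote(c(0.9, 0.4, 0.6), weights = c(0.1, 0.7, 0.2))
  expect_equal(sv$probability, 0.49)
  expect_equal(sv$label, "inactive")
  # equal probabilities are a fixed point for any weights
  expect_equal(soft_vote(c(0.7, 0.7, 0.7), c(0.3, 1.2, 0.5))$probability, 0.7)
  # degenerate weighting selects the single model
  expect_equal(soft_vote(c(0.9, 0.4, 0.6), c(0, 1, 0))$probability, 0.4)
  # invariance to positive rescaling
  p <- matrix(runif(30), 10, 3)
  expect_equal(soft_vote(p, c(0.1, 0.7, 0.2))$probability,
               soft_vote(p, 2 * c(0.1, 0.7, 0.2))$probability)
  expect_error(soft_vote(c(0.5, 0.5, 0.5), c(0, 0, 0)), "all-zero")
  # hard vote equals soft vote with unit weights on 0/1 probabilities
  votes01 <- expand.grid(c(0, 1), c(0, 1), c(0, 1))
  sv01 <- soft_vote(as.matrix(votes01), c(1, 1, 1))
  hv <- hard_vote(ifelse(as.matrix(votes01) == 1, "active", "inactive"))
  expect_equal(sv01$label, hv)
})

test_that("weight optimization scans the lattice with stated tie-breaks", {
  withr::with_seed(10, {
    truth <- rep(c("active", "inactive"), each = 25)
    good <- ifelse(truth == "active", 0.9, 0.1) + rnorm(50, 0, 0.05)
    noise1 <- runif(50); noise2 <- runif(50)
    probs <- cbind(pmin(pmax(good, 0), 1), noise1, noise2)
  })
  res <- optimize_weights(probs, truth, step = 0.5)
  # the dominant model receives the maximal weight in the winning triple
  expect_equal(which.max(res$weights), 1L)
  # the optimum cannot be worse than equal weighting
  eq <- soft_vote(probs, c(1, 1, 1))
  f1_eq <- classification_metrics(confusion_counts(truth, eq$label))$f1
  expect_gte(res$score, f1_eq)
  # rescaling the winning triple leaves predictions unchanged
  if (all(res$weights * 2 <= 2)) {
    expect_equal(soft_vote(probs, res$weights)$label,
                 soft_vote(probs, res$weights * 2)$label)
  }
})

test_that("base learners fit, predict and stay reproducible", {
  syn <- fixture_classification()
  for (alg in c("random_forest", "extra_trees", "adaboost")) {
    m <- fit_qsar_model(syn$data, syn$labels, alg, seed = 7)
    p <- predict(m, syn$data, type = "prob")
    expect_true(all(p >= 0 & p <= 1))
    lab <- predict(m, syn$data)
    expect_true(all(lab %in% c("active", "inactive")))
    m2 <- fit_qsar_model(syn$data, syn$labels, alg, seed = 7)
    expect_equal(predict(m2, syn$data, type = "prob"), p)
    # better than chance on its own training data with planted signal
    acc <- mean(lab == syn$labels)
    expect_gt(acc, 0.6)
  }
  reg <- make_synthetic_regression(100, 8, 3, noise_sd = 0.5, seed = 5)
  mr <- fit_qsar_model(reg$data, reg$response, "extra_trees_regressor",
                       seed = 3)
  expect_gt(r_squared(reg$response, predict(mr, reg$data)), 0.5)
  expect_error(predict(mr, reg$data[, 1:3]), "missing descriptor")
})

test_that("grid search scores every combination and refits the winner", {
  syn <- fixture_classification(n = 80, d = 6, n_informative = 3)
  grid <- list(n_trees = c(5, 15), max_depth = c(1, 2))
  gs <- grid_search_fit(syn$data, syn$labels, "adaboost", grid = grid,
                        cv_folds = 4, seed = 13)
  expect_equal(nrow(gs$results), 4)
  expect_equal(gs$best_score, max(gs$results$cv_score))
  # the winner's reported score is independently reproducible
  redo <- qsarens:::cv_score_model(syn$data, syn$labels, "adaboost",
                                   gs$best_params, 4, 13)
  expect_equal(redo, gs$best_score)
  # determinism of the winning combination
  gs2 <- grid_search_fit(syn$data, syn$labels, "adaboost", grid = grid,
                         cv_folds = 4, seed = 13)
  expect_identical(gs2$best_params, gs$best_params)
  # single-combination grid is a plain fit
  gs1 <- grid_search_fit(syn$data, syn$labels, "adaboost",
                         grid = list(n_trees = 10), cv_folds = 4, seed = 2)
  expect_equal(nrow(gs1$results), 1)
  expect_s3_class(glance(gs1), "tbl_df")
  expect_equal(nrow(tidy(gs)), 4)
})

test_that("ensemble predictions combine the three base models", {
  syn <- fixture_classification()
  rf <- fit_qsar_model(syn$data, syn$labels, "random_forest", seed = 1)
  et <- fit_qsar_model(syn$data, syn$labels, "extra_trees", seed = 1)
  ab <- fit_qsar_model(syn$data, syn$labels, "adaboost", seed = 1)
  ens <- build_ensemble(rf, et, ab, weights = c(0.1, 0.7, 0.2))
  pred <- predict(ens, syn$data)
  expect_equal(nrow(pred), nrow(syn$data))
  manual <- (0.1 * pred$random_forest + 0.7 * pred$extra_trees +
               0.2 * pred$adaboost) / 1.0
  expect_equal(pred$probability, manual)
  hard <- build_ensemble(rf, et, ab, mode = "hard")
  ph <- predict(hard, syn$data)
  expect_true(all(ph$label %in% c("active", "inactive")))
  expect_equal(glance(ens)$w_extra_trees, 0.7)
})
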