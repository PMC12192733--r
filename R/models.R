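CLASS_LEVELS <- c("active", "inactive")

as_class_factor <- function(y) factor(y, levels = CLASS_LEVELS)

# ---- AdaBoost (discrete SAMME over rpart trees) -------------------------
# No boosting package ships with the stack, so the classic two-class
# algorithm is implemented directly: exponential reweighting of stumps/trees,
# ensemble score = alpha-weighted vote share for the positive class.
fit_adaboost <- function(x, y, n_trees = 50, max_depth = 1,
                         learning_rate = 1) {
  y <- as_class_factor(y)
  n <- nrow(x)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  df <- data.frame(x, check.names = FALSE)
  for (m in seq_len(n_trees)) {
    fit <- rpart::rpart(
      y ~ ., data = cbind(df, y = y), weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = max_depth, cp = -1,
                                     minsplit = 2, minbucket = 1, xval = 0))
    pred <- predict(fit, df, type = "class")
    mis <- pred != y
    err <- sum(w[mis])
    if (err <= 1e-12) {           # perfect tree: dominate and stop
      trees[[length(trees) + 1]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break         # no better than chance under current weights
    alpha <- learning_rate * 0.5 * log((1 - err) / err)
    trees[[length(trees) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(mis, 1, -1))
    w <- w / sum(w)
  }
  if (length(trees) == 0) {       # degenerate data: fall back to one tree
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = y), method = "class",
                        control = rpart::rpart.control(maxdepth = max_depth,
                                                       cp = -1, xval = 0))
    trees <- list(fit); alphas <- 1
  }
  structure(list(trees = trees, alphas = alphas), class = "qsarens_adaboost")
}

predict_adaboost_prob <- function(object, newdata) {
  df <- data.frame(newdata, check.names = FALSE)
  votes <- vapply(object$trees, function(tr) {
    predict(tr, df, type = "class") == "active"
  }, logical(nrow(df)))
  votes <- matrix(votes, nrow = nrow(df))
  as.numeric(votes %*% object$alphas) / sum(object$alphas)
}

# ---- unified base-learner interface -------------------------------------

default_hyperparameters <- function(algorithm_id) {
  switch(algorithm_id,
    random_forest = list(num_trees = 200, mtry = NULL, min_node_size = 1),
    extra_trees = list(num_trees = 200, mtry = NULL, min_node_size = 1),
    adaboost = list(n_trees = 50, max_depth = 1, learning_rate = 1),
    extra_trees_regressor = list(num_trees = 200, mtry = NULL,
                                 min_node_size = 5),
    stop("unknown algorithm: ", algorithm_id))
}

#' Default hyperparameter grids for grid search
#'
#' Small, documented grids per algorithm (tree count, feature sampling,
#' leaf/depth control) suitable for desk-scale tuning; override freely.
#'
#' @param algorithm_id One of `"random_forest"`, `"extra_trees"`,
#'   `"adaboost"`, `"extra_trees_regressor"`.
#' @return Named list of hyperparameter value vectors.
#' @export
default_grid <- function(algorithm_id) {
  switch(algorithm_id,
    random_forest = list(num_trees = c(100, 300), min_node_size = c(1, 5)),
    extra_trees = list(num_trees = c(100, 300), min_node_size = c(1, 5)),
    adaboost = list(n_trees = c(25, 50), max_depth = c(1, 2)),
    extra_trees_regressor = list(num_trees = c(100, 300),
                                 min_node_size = c(2, 5)),
    stop("unknown algorithm: ", algorithm_id))
}

#' Fit a single base learner
#'
#' Unified wrapper over the three classification algorithms (random forest
#' and extra trees via `ranger`, AdaBoost implemented in-package over
#' `rpart` trees) and the extra-trees regressor. The fitted object stores
#' its descriptor subset; prediction subsets new data to exactly those
#' columns.
#'
#' @param data Feature tibble (numeric columns; id column dropped).
#' @param labels `"active"`/`"inactive"` vector (classification) or numeric
#'   response (regression).
#' @param algorithm_id Algorithm identifier, see [default_grid()].
#' @param hyperparameters Named list; unset entries take defaults.
#' @param seed Integer seed (tree learners are stochastic).
#' @param id_col Id column name, dropped before fitting.
#' @return A `qsar_model` object.
#' @export
fit_qsar_model <- function(data, labels, algorithm_id,
                           hyperparameters = list(), seed = 1,
                           id_col = "compound_id") {
  x <- data[, setdiff(names(data), id_col), drop = FALSE]
  hp <- utils::modifyList(default_hyperparameters(algorithm_id),
                          hyperparameters)
  task <- if (algorithm_id == "extra_trees_regressor") "regression"
          else "classification"
  fit <- if (algorithm_id == "adaboost") {
    with_seed(seed, fit_adaboost(x, labels, n_trees = hp$n_trees,
                                 max_depth = hp$max_depth,
                                 learning_rate = hp$learning_rate))
  } else {
    df <- data.frame(x, check.names = FALSE)
    df$.response <- if (task == "classification") as_class_factor(labels)
                    else as.numeric(labels)
    ranger::ranger(
      dependent.variable.name = ".response", data = df,
      num.trees = hp$num_trees,
      mtry = hp$mtry %||% floor(sqrt(ncol(x))),
      min.node.size = hp$min_node_size,
      splitrule = switch(algorithm_id,
        random_forest = "gini",
        extra_trees = "extratrees",
        extra_trees_regressor = "extratrees"),
      num.random.splits = 1,
      replace = algorithm_id == "random_forest",
      sample.fraction = 1,
      probability = task == "classification",
      seed = seed, num.threads = 1)
  }
  structure(list(
    algorithm_id = algorithm_id, task = task, fit = fit,
    descriptor_subset = names(x), hyperparameters = hp, seed = seed
  ), class = "qsar_model")
}

#' Predict from a fitted base learner
#'
#' @param object A `qsar_model`.
#' @param newdata Feature tibble containing the model's descriptor subset.
#' @param type `"label"` (default), `"prob"` (P(active)), or `"response"`
#'   (numeric, regression).
#' @param threshold Probability cutoff for `"label"`; default 0.5.
#' @param ... Unused.
#' @return Vector of labels, probabilities, or responses.
#' @export
predict.qsar_model <- function(object, newdata, type = c("label", "prob", "response"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$descriptor_subset, names(newdata))
  if (length(missing_cols) > 0) {
    stop("missing descriptor columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- newdata[, object$descriptor_subset, drop = FALSE]
  if (object$task == "regression") {
    return(predict(object$fit, data.frame(x, check.names = FALSE),
                   num.threads = 1)$predictions)
  }
  prob <- if (object$algorithm_id == "adaboost") {
    predict_adaboost_prob(object$fit, x)
  } else {
    p <- predict(object$fit, data.frame(x, check.names = FALSE),
                 num.threads = 1)$predictions
    if ("active" %in% colnames(p)) p[, "active"] else 1 - p[, "inactive"]
  }
  switch(type,
    prob = prob,
    label = ifelse(prob >= threshold, "active", "inactive"),
    response = prob)
}

# ---- grid search ---------------------------------------------------------

cv_score_model <- function(data, labels, algorithm_id, hp, cv_folds, seed,
                           id_col = "compound_id") {
  x <- data[, setdiff(names(data), id_col), drop = FALSE]
  task <- if (algorithm_id == "extra_trees_regressor") "regression"
          else "classification"
  fold <- if (task == "classification") {
    if (any(table(labels) < cv_folds)) {
      stop("stratification error: a class has fewer members than folds")
    }
    stratified_folds(labels, cv_folds, seed)
  } else unstratified_folds(nrow(x), cv_folds, seed)
  scores <- vapply(seq_len(cv_folds), function(k) {
    tr <- fold != k
    fit <- fit_qsar_model(x[tr, , drop = FALSE], labels[tr], algorithm_id,
                          hyperparameters = hp, seed = seed, id_col = id_col)
    if (task == "classification") {
      f1_score(labels[!tr], predict(fit, x[!tr, , drop = FALSE]))
    } else {
      r_squared(labels[!tr], predict(fit, x[!tr, , drop = FALSE]))
    }
  }, double(1))
  mean(scores, na.rm = TRUE)
}

#' Exhaustive grid search with cross-validated scoring
#'
#' Scores every combination in the hyperparameter grid by mean k-fold
#' cross-validation (F1 for classification, R-squared for regression;
#' stratified folds for classification), then refits the winning
#' combination on the full training data. Ties break to the first
#' combination in grid order.
#'
#' @param data Feature tibble.
#' @param labels Response vector.
#' @param algorithm_id See [fit_qsar_model()].
#' @param grid Named list of value vectors (crossed), or `NULL` for
#'   [default_grid()].
#' @param cv_folds Folds; default 10.
#' @param seed Integer seed shared by fold assignment and learners.
#' @param id_col Id column name.
#' @return A `qsar_grid_fit`: the refitted `model`, `best_params`,
#'   `best_score`, and the full `results` tibble.
#' @export
grid_search_fit <- function(data, labels, algorithm_id, grid = NULL,
                            cv_folds = 10, seed = 1, id_col = "compound_id") {
  grid <- grid %||% default_grid(algorithm_id)
  stopifnot(length(grid) > 0)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- vapply(seq_len(nrow(combos)), function(i) {
    cv_score_model(data, labels, algorithm_id, as.list(combos[i, , drop = FALSE]),
                   cv_folds, seed, id_col)
  }, double(1))
  best <- which.max(scores)  # first max wins ties
  best_params <- as.list(combos[best, , drop = FALSE])
  model <- fit_qsar_model(data, labels, algorithm_id,
                          hyperparameters = best_params, seed = seed,
                          id_col = id_col)
  structure(list(
    model = model, best_params = best_params, best_score = scores[best],
    results = dplyr::bind_cols(tibble::as_tibble(combos),
                               tibble::tibble(cv_score = scores)),
    cv_folds = cv_folds, seed = seed
  ), class = "qsar_grid_fit")
}

#' @method tidy qsar_grid_fit
#' @export
tidy.qsar_grid_fit <- function(x, ...) x$results

#' @method glance qsar_grid_fit
#' @export
glance.qsar_grid_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(algorithm = x$model$algorithm_id,
                   best_cv_score = x$best_score, cv_folds = x$cv_folds),
    tibble::as_tibble(x$best_params))
}

#' @export
predict.qsar_grid_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

# ---- voting --------------------------------------------------------------

#' Hard (majority) vote over three classifiers
#'
#' @param votes Character vector of three labels, or an n x 3 matrix/data
#'   frame of labels (one row per compound).
#' @return Majority label per row; three voters mean no ties.
#' @export
hard_vote <- function(votes) {
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  votes <- as.matrix(votes)
  stopifnot(ncol(votes) == 3)
  ifelse(rowSums(votes == "active") >= 2, "active", "inactive")
}

#' Weighted soft vote over three classifiers
#'
#' Ensemble probability is the weight-normalized average of the base
#' probabilities, P = sum(w_i p_i) / sum(w_i); the label is `"active"` when
#' P is at or above the decision threshold. Invariant to positive rescaling
#' of the weights.
#'
#' @param probs Numeric vector of three P(active) values, or an n x 3
#'   matrix (rows = compounds, columns = base models).
#' @param weights Three non-negative weights, not all zero. The reference
#'   deployment uses (0.1, 0.7, 0.2) for (random forest, extra trees,
#'   AdaBoost).
#' @param threshold Decision threshold; default 0.5.
#' @return Tibble with `probability` and `label`.
#' @examples
#' soft_vote(c(0.9, 0.4, 0.6), weights = c(0.1, 0.7, 0.2))
#' @export
soft_vote <- function(probs, weights = c(1, 1, 1), threshold = 0.5) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 3, length(weights) == 3, all(weights >= 0))
  if (sum(weights) == 0) stop("all-zero weights")
  p <- as.numeric(probs %*% weights) / sum(weights)
  tibble::tibble(probability = p,
                 label = ifelse(p >= threshold, "active", "inactive"))
}

#' Optimize soft-vote weights over a lattice
#'
#' Exhaustively scans every weight triple on the grid (default 0 to 2.0 in
#' steps of 0.1, all-zero excluded) and returns the triple maximizing the
#' objective (default F1) on the supplied evaluation probabilities and
#' labels. Ties break to the lowest total weight, then lexicographically.
#'
#' @param probs n x 3 matrix of base-model P(active) on evaluation data.
#' @param truth Evaluation labels (`"active"`/`"inactive"`).
#' @param weight_range Numeric length-2; default `c(0, 2)`.
#' @param step Lattice step; default 0.1.
#' @param threshold Decision threshold; default 0.5.
#' @param objective `"f1"` or `"accuracy"`.
#' @return List with `weights` (length-3), `score`, and the scanned
#'   `lattice` tibble.
#' @export
optimize_weights <- function(probs, truth, weight_range = c(0, 2),
                             step = 0.1, threshold = 0.5,
                             objective = c("f1", "accuracy")) {
  objective <- match.arg(objective)
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 3, nrow(probs) == length(truth), step > 0)
  vals <- seq(weight_range[1], weight_range[2], by = step)
  w_grid <- as.matrix(expand.grid(w1 = vals, w2 = vals, w3 = vals))
  w_grid <- w_grid[rowSums(w_grid) > 0, , drop = FALSE]
  # vectorized scan: ensemble probabilities for all triples at once
  p_all <- (probs %*% t(w_grid)) / rep(rowSums(w_grid), each = nrow(probs))
  pred_act <- p_all >= threshold
  t_pos <- truth == "active"
  tp <- colSums(pred_act & t_pos)
  fp <- colSums(pred_act & !t_pos)
  fn <- colSums(!pred_act & t_pos)
  tn <- colSums(!pred_act & !t_pos)
  score <- if (objective == "f1") {
    ifelse(2 * tp + fp + fn == 0, NA_real_, 2 * tp / (2 * tp + fp + fn))
  } else (tp + tn) / length(truth)
  score[is.na(score)] <- -Inf
  best_score <- max(score)
  cand <- which(score == best_score)
  # tie-breaks: lowest total weight, then lexicographic on (w1, w2, w3)
  ord <- order(rowSums(w_grid[cand, , drop = FALSE]),
               w_grid[cand, 1], w_grid[cand, 2], w_grid[cand, 3])
  best <- cand[ord[1]]
  list(weights = unname(w_grid[best, ]), score = best_score,
       lattice = dplyr::bind_cols(tibble::as_tibble(w_grid),
                                  tibble::tibble(score = score)))
}

#' Assemble a voting ensemble from three fitted classifiers
#'
#' @param random_forest,extra_trees,adaboost Fitted `qsar_model` classifiers
#'   (the ensemble's fixed base-model order).
#' @param mode `"soft"` (weighted probability averaging, default) or
#'   `"hard"` (majority vote).
#' @param weights Soft-vote weights in base-model order; default the
#'   deployed (0.1, 0.7, 0.2).
#' @param threshold Decision threshold; default 0.5.
#' @return A `qsar_ensemble` object.
#' @export
build_ensemble <- function(random_forest, extra_trees, adaboost,
                           mode = c("soft", "hard"),
                           weights = c(0.1, 0.7, 0.2), threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  base <- list(random_forest = random_forest, extra_trees = extra_trees,
               adaboost = adaboost)
  for (m in base) stopifnot(inherits(m, "qsar_model"),
                            m$task == "classification")
  structure(list(base_models = base, mode = mode, weights = weights,
                 threshold = threshold), class = "qsar_ensemble")
}

#' Predict with a voting ensemble
#'
#' @param object A `qsar_ensemble`.
#' @param newdata Feature tibble covering all base models' descriptor
#'   subsets.
#' @param ... Unused.
#' @return Tibble with per-model probabilities, the ensemble `probability`
#'   (soft mode) and `label`.
#' @export
predict.qsar_ensemble <- function(object, newdata, ...) {
  probs <- vapply(object$base_models, predict, double(nrow(newdata)),
                  newdata = newdata, type = "prob")
  probs <- matrix(probs, nrow = nrow(newdata),
                  dimnames = list(NULL, names(object$base_models)))
  if (object$mode == "soft") {
    sv <- soft_vote(probs, object$weights, object$threshold)
    dplyr::bind_cols(tibble::as_tibble(probs), sv)
  } else {
    labels <- ifelse(probs >= object$threshold, "active", "inactive")
    dplyr::bind_cols(tibble::as_tibble(probs),
                     tibble::tibble(label = hard_vote(labels)))
  }
}

#' @method glance qsar_ensemble
#' @export
glance.qsar_ensemble <- function(x, ...) {
  tibble::tibble(mode = x$mode,
                 w_random_forest = x$weights[1],
                 w_extra_trees = x$weights[2],
                 w_adaboost = x$weights[3],
                 threshold = x$threshold)
}
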