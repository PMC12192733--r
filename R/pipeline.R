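# Out-of-fold P(active) for weight optimization: refit each algorithm per
# fold so the evaluation probabilities never come from a model that saw the
# compound.
oof_probabilities <- function(data, labels, algorithms, params, subsets,
                              folds = 3, seed = 1, id_col = "compound_id") {
  fold <- stratified_folds(labels, folds, seed)
  probs <- matrix(NA_real_, nrow(data), length(algorithms),
                  dimnames = list(NULL, algorithms))
  for (k in seq_len(folds)) {
    tr <- fold != k
    for (ai in seq_along(algorithms)) {
      cols <- subsets[[ai]]
      fit <- fit_qsar_model(data[tr, cols, drop = FALSE], labels[tr],
                            algorithms[ai], hyperparameters = params[[ai]],
                            seed = seed, id_col = id_col)
      probs[!tr, ai] <- predict(fit, data[!tr, cols, drop = FALSE],
                                type = "prob")
    }
  }
  probs
}

#' Train a complete QSAR screening bundle
#'
#' Runs the full model-construction pipeline on an activity table: curation
#' (classification and regression datasets), descriptor computation,
#' per-task preprocessing, GA descriptor selection per algorithm,
#' grid-search tuning of the three base classifiers (random forest, extra
#' trees, AdaBoost) and the extra-trees regressor, soft-voting ensemble
#' assembly (fixed weights or lattice optimization on out-of-fold
#' probabilities), and per-model kNN applicability domains.
#'
#' @param activities Activity tibble (`compound_id`, `smiles`, `ic50`,
#'   `relation`).
#' @param provider Descriptor provider id.
#' @param ga_cls,ga_reg [ga_config()]s for the classification and
#'   regression GA runs (algorithm-specific sub-seeds are derived from
#'   them).
#' @param grids Named list of hyperparameter grids per algorithm; defaults
#'   from [default_grid()].
#' @param weights Length-3 numeric soft-vote weights (default the deployed
#'   0.1/0.7/0.2), or `"optimize"` to scan the weight lattice on
#'   out-of-fold probabilities.
#' @param grid_cv_folds CV folds inside the grid search; default 5 (use 10
#'   for full-scale datasets).
#' @param ad_k Applicability-domain neighbour count; default 3.
#' @param seed Master seed.
#' @return A `qsar_bundle` with everything [predict_batch()] needs.
#' @export
train_qsar_bundle <- function(activities, provider = "chemmine",
                              ga_cls = ga_config(population_size = 10,
                                                 generations = 5),
                              ga_reg = ga_config(population_size = 10,
                                                 generations = 5),
                              grids = NULL,
                              weights = c(0.1, 0.7, 0.2),
                              grid_cv_folds = 5, ad_k = 3, seed = 1) {
  seeds <- derive_seeds(seed, 10)
  algorithms <- c("random_forest", "extra_trees", "adaboost")
  grids <- grids %||% stats::setNames(
    lapply(c(algorithms, "extra_trees_regressor"), default_grid),
    c(algorithms, "extra_trees_regressor"))

  curated_cls <- curate_activities(activities, "classification")
  curated_reg <- curate_activities(activities, "regression")
  if (nrow(curated_cls) < 10) stop("too few curated compounds to train")

  desc_cls <- compute_descriptors(curated_cls, provider = provider)
  desc_reg <- compute_descriptors(curated_reg, provider = provider)
  prep_cls <- fit_preprocess(desc_cls)
  prep_reg <- fit_preprocess(desc_reg)
  x_cls <- apply_preprocess(prep_cls, desc_cls)
  x_reg <- apply_preprocess(prep_reg, desc_reg)
  y_cls <- curated_cls$label
  y_reg <- curated_reg$pic50

  # GA feature selection, one run per classification algorithm
  subsets <- vector("list", length(algorithms))
  for (ai in seq_along(algorithms)) {
    cfg <- ga_cls; cfg$seed <- seeds[ai]
    subsets[[ai]] <- run_ga(x_cls, y_cls, task = "classification",
                            config = cfg)$best
  }
  cfg_reg <- ga_reg; cfg_reg$seed <- seeds[4]
  subset_reg <- run_ga(x_reg, y_reg, task = "regression",
                       config = cfg_reg)$best

  fits <- purrr::map2(algorithms, subsets, function(alg, cols) {
    grid_search_fit(x_cls[, c("compound_id", cols)], y_cls, alg,
                    grid = grids[[alg]], cv_folds = grid_cv_folds,
                    seed = seeds[5])
  })
  models <- purrr::map(fits, "model")
  names(models) <- algorithms

  if (identical(weights, "optimize")) {
    probs <- oof_probabilities(x_cls, y_cls, algorithms,
                               purrr::map(fits, "best_params"), subsets,
                               folds = 3, seed = seeds[6])
    weights <- optimize_weights(probs, y_cls)$weights
  }
  ensemble <- build_ensemble(models$random_forest, models$extra_trees,
                             models$adaboost, mode = "soft",
                             weights = weights)

  reg_fit <- grid_search_fit(x_reg[, c("compound_id", subset_reg)], y_reg,
                             "extra_trees_regressor",
                             grid = grids$extra_trees_regressor,
                             cv_folds = grid_cv_folds, seed = seeds[7])

  k_cls <- min(ad_k, nrow(x_cls) - 1)
  ad_models <- purrr::map(subsets, function(cols) {
    fit_ad(x_cls[, c("compound_id", cols)], k = k_cls)
  })
  names(ad_models) <- algorithms
  ad_reg <- fit_ad(x_reg[, c("compound_id", subset_reg)],
                   k = min(ad_k, nrow(x_reg) - 1))

  structure(list(
    provider = provider,
    preprocess_cls = prep_cls, preprocess_reg = prep_reg,
    models = models, ensemble = ensemble,
    regressor = reg_fit$model,
    ad_models = ad_models, ad_regression = ad_reg,
    manifest = list(
      seed = seed, weights = weights,
      descriptor_subsets = stats::setNames(subsets, algorithms),
      regression_subset = subset_reg,
      grids = grids, grid_cv_folds = grid_cv_folds, ad_k = ad_k,
      n_train_classification = nrow(x_cls),
      n_train_regression = nrow(x_reg))
  ), class = "qsar_bundle")
}

#' @export
print.qsar_bundle <- function(x, ...) {
  cat("QSAR screening bundle\n")
  cat(sprintf("  classifiers: %s (soft vote, weights %s)\n",
              paste(names(x$models), collapse = ", "),
              paste(x$ensemble$weights, collapse = "/")))
  cat(sprintf("  regressor: %s (%d descriptors)\n",
              x$regressor$algorithm_id, length(x$regressor$descriptor_subset)))
  cat(sprintf("  trained on %d (classification) / %d (regression) compounds\n",
              x$manifest$n_train_classification,
              x$manifest$n_train_regression))
  invisible(x)
}

#' Batch prediction from a SMILES list
#'
#' The full prediction workflow: per compound, validate and standardize the
#' structure (invalid entries become error rows, never abort the batch),
#' compute descriptors, apply the stored preprocessing, soft-vote the three
#' classifiers into a probability and label, predict pIC50 (reported also
#' as IC50 in nM), and attach per-model plus ensemble applicability-domain
#' verdicts. Row order follows the input.
#'
#' @param smiles Character vector of SMILES, or a tibble with
#'   `compound_id` and `smiles` columns.
#' @param bundle A `qsar_bundle` from [train_qsar_bundle()].
#' @return Tibble, one row per input: ids, standardized SMILES, error flag,
#'   class probability and label, predicted pIC50/IC50, AD columns.
#' @export
predict_batch <- function(smiles, bundle) {
  stopifnot(inherits(bundle, "qsar_bundle"))
  input <- if (is.data.frame(smiles)) {
    tibble::tibble(compound_id = as.character(smiles$compound_id),
                   input_smiles = as.character(smiles$smiles))
  } else {
    tibble::tibble(compound_id = sprintf("Q%04d", seq_along(smiles)),
                   input_smiles = as.character(smiles))
  }
  std <- standardize_structures(input, smiles_col = "input_smiles")
  out <- dplyr::mutate(
    std,
    error = .data$reject_reason,
    class_probability = NA_real_, class_label = NA_character_,
    predicted_pic50 = NA_real_, predicted_ic50_nM = NA_real_,
    ad_random_forest = NA, ad_extra_trees = NA, ad_adaboost = NA,
    ad_ensemble_score = NA_real_, ad_inside_ensemble = NA,
    ad_regression = NA)
  ok <- is.na(std$reject_reason)
  if (any(ok)) {
    valid <- std[ok, , drop = FALSE]
    desc <- compute_descriptors(valid, provider = bundle$provider)
    xc <- apply_preprocess(bundle$preprocess_cls, desc)
    xr <- apply_preprocess(bundle$preprocess_reg, desc)
    ens <- predict(bundle$ensemble, xc)
    pic50 <- predict(bundle$regressor, xr)
    inside <- vapply(names(bundle$ad_models), function(alg) {
      query_ad(bundle$ad_models[[alg]], xc)
    }, logical(nrow(xc)))
    inside <- matrix(inside, nrow = nrow(xc))
    ad <- ensemble_ad(inside)
    out$class_probability[ok] <- ens$probability
    out$class_label[ok] <- ens$label
    out$predicted_pic50[ok] <- pic50
    out$predicted_ic50_nM[ok] <- pic50_to_ic50(pic50)
    out$ad_random_forest[ok] <- ad$ad_model_1
    out$ad_extra_trees[ok] <- ad$ad_model_2
    out$ad_adaboost[ok] <- ad$ad_model_3
    out$ad_ensemble_score[ok] <- ad$ensemble_score
    out$ad_inside_ensemble[ok] <- ad$inside_ensemble
    out$ad_regression[ok] <- query_ad(bundle$ad_regression, xr)
  }
  dplyr::select(out, "compound_id", "input_smiles",
                standardized_smiles = "standard_smiles", "error",
                "class_probability", "class_label",
                "predicted_pic50", "predicted_ic50_nM",
                "ad_random_forest", "ad_extra_trees", "ad_adaboost",
                "ad_ensemble_score", "ad_inside_ensemble", "ad_regression")
}

#' Save / load a QSAR bundle
#'
#' The bundle is serialized with R's native serialization plus a
#' human-readable JSON manifest recording seeds, weights, grids and
#' descriptor subsets.
#'
#' @param bundle A `qsar_bundle`.
#' @param path Output `.rds` path.
#' @param manifest_path Optional JSON manifest path.
#' @return `path`, invisibly.
#' @export
save_qsar_bundle <- function(bundle, path, manifest_path = NULL) {
  stopifnot(inherits(bundle, "qsar_bundle"))
  saveRDS(bundle, path)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(bundle$manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname save_qsar_bundle
#' @export
load_qsar_bundle <- function(path) {
  bundle <- readRDS(path)
  stopifnot(inherits(bundle, "qsar_bundle"))
  bundle
}

#' Read a bare SMILES list
#'
#' Accepts one-SMILES-per-line `.txt` files or CSVs with a SMILES column
#' (and optionally an id column). Spreadsheet inputs should be exported to
#' CSV first (e.g. via \code{readxl} or a spreadsheet application).
#'
#' @param path Input path.
#' @param smiles_col SMILES column name for CSV input; default `"smiles"`.
#' @param id_col Optional id column name.
#' @return Tibble with `compound_id` and `smiles`.
#' @export
read_smiles_list <- function(path, smiles_col = "smiles",
                             id_col = "compound_id") {
  if (grepl("\\.csv$", path)) {
    raw <- readr::read_csv(path, show_col_types = FALSE)
    stopifnot(smiles_col %in% names(raw))
    ids <- if (id_col %in% names(raw)) as.character(raw[[id_col]])
           else sprintf("Q%04d", seq_len(nrow(raw)))
    tibble::tibble(compound_id = ids, smiles = as.character(raw[[smiles_col]]))
  } else {
    lines <- readr::read_lines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    tibble::tibble(compound_id = sprintf("Q%04d", seq_along(lines)),
                   smiles = lines)
  }
}
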