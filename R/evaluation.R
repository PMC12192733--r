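#' Confusion counts from label vectors
#'
#' @param truth,estimate Character/factor vectors of `"active"`/`"inactive"`
#'   (or any two levels; `positive` names the positive class).
#' @param positive Positive class label; default `"active"`.
#' @return A one-row tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, estimate, positive = "active") {
  stopifnot(length(truth) == length(estimate), length(truth) > 0)
  t_pos <- truth == positive
  e_pos <- estimate == positive
  tibble::tibble(
    tp = sum(t_pos & e_pos), tn = sum(!t_pos & !e_pos),
    fp = sum(!t_pos & e_pos), fn = sum(t_pos & !e_pos)
  )
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Binary classification metrics from confusion counts
#'
#' Computes accuracy, recall (sensitivity/TPR), precision (PPV), specificity
#' (TNR), false positive rate, false negative rate, Matthews correlation
#' coefficient (with the four-factor denominator), F1, and NPV. Metrics with
#' a zero denominator are reported as `NA` ("undefined"), never as 0, so
#' fold aggregation cannot average fabricated zeros.
#'
#' @param counts One-row tibble/list with `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]), or four separate non-negative integers.
#' @param tn,fp,fn Used when `counts` is given as the `tp` scalar.
#' @return One-row tibble of metrics.
#' @examples
#' classification_metrics(confusion_counts(
#'   c("active", "active", "inactive"), c("active", "inactive", "inactive")))
#' @export
classification_metrics <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (is.numeric(counts) && length(counts) == 1) {
    counts <- tibble::tibble(tp = counts, tn = tn, fp = fp, fn = fn)
  }
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  total <- tp + tn + fp + fn
  if (total == 0) stop("all-zero confusion counts")
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fn, tn + fp)))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  tibble::tibble(
    accuracy = (tp + tn) / total,
    recall = recall,
    precision = precision,
    specificity = specificity,
    fpr = if (is.na(specificity)) NA_real_ else 1 - specificity,
    fnr = if (is.na(recall)) NA_real_ else 1 - recall,
    mcc = mcc,
    f1 = f1,
    npv = safe_div(tn, tn + fn)
  )
}

#' Coefficient of determination
#'
#' R-squared as one minus the ratio of residual to total sum of squares
#' about the observed mean; can be negative for predictions worse than the
#' mean.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return A single numeric value.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 5))
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / ss_tot
}

f1_score <- function(truth, estimate, positive = "active") {
  classification_metrics(confusion_counts(truth, estimate, positive))$f1
}

# Stratified fold assignment: each class distributed round-robin across folds.
stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

unstratified_folds <- function(n, folds, seed) {
  with_seed(seed, {
    rep_len(seq_len(folds), n)[sample(n)]
  })
}

#' External cross-validation harness
#'
#' Partitions the data once into stratified folds, retrains the supplied
#' model builder on each fold's complement, scores the held-out fold, and
#' aggregates per-fold metrics as mean and standard deviation.
#'
#' @param builder `function(train_data, train_labels)` returning an object
#'   whose `predict(object, new_data)` yields class labels (classification)
#'   or numeric responses (regression).
#' @param data Feature tibble (id column ignored for fitting).
#' @param labels Response vector aligned to `data` rows.
#' @param task `"classification"` or `"regression"`.
#' @param folds Number of folds; default 10.
#' @param seed Integer seed for the partition.
#' @param id_col Id column name, dropped before fitting.
#' @return A `qsar_cv` object: list with `per_fold` (tibble, one metrics row
#'   per fold) and `summary` (mean and sd per metric).
#' @export
external_cv <- function(builder, data, labels,
                        task = c("classification", "regression"),
                        folds = 10, seed = 1, id_col = "compound_id") {
  task <- match.arg(task)
  stopifnot(folds >= 2, nrow(data) == length(labels))
  x <- data[, setdiff(names(data), id_col), drop = FALSE]
  fold <- if (task == "classification") {
    f <- stratified_folds(labels, folds, seed)
    counts <- table(labels)
    if (any(counts < folds)) stop("stratification error: a class has fewer members than folds")
    f
  } else unstratified_folds(nrow(x), folds, seed)
  per_fold <- purrr::map_dfr(seq_len(folds), function(k) {
    tr <- fold != k
    fit <- builder(x[tr, , drop = FALSE], labels[tr])
    pred <- predict(fit, x[!tr, , drop = FALSE])
    if (task == "classification") {
      dplyr::bind_cols(tibble::tibble(fold = k),
                       classification_metrics(
                         confusion_counts(labels[!tr], pred)))
    } else {
      tibble::tibble(fold = k, r2 = r_squared(labels[!tr], as.numeric(pred)))
    }
  })
  metric_cols <- setdiff(names(per_fold), "fold")
  summary <- tidyr::pivot_longer(per_fold, dplyr::all_of(metric_cols),
                                 names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop")
  structure(list(per_fold = per_fold, summary = summary, task = task,
                 folds = folds, seed = seed),
            class = "qsar_cv")
}

#' @export
print.qsar_cv <- function(x, ...) {
  cat(sprintf("%d-fold external cross-validation (%s)\n", x$folds, x$task))
  print(x$summary)
  invisible(x)
}

#' @method tidy qsar_cv
#' @export
tidy.qsar_cv <- function(x, ...) x$per_fold

#' @method glance qsar_cv
#' @export
glance.qsar_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(tibble::tibble(folds = x$folds, task = x$task), wide)
}

#' Write a cross-validation report as CSV (one row per fold + aggregate)
#'
#' @param cv A `qsar_cv` object.
#' @param path Output CSV path.
#' @return `cv`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  per_fold <- dplyr::mutate(cv$per_fold, fold = as.character(.data$fold))
  agg <- tidyr::pivot_wider(dplyr::select(cv$summary, "metric", "mean"),
                            names_from = "metric", values_from = "mean")
  agg <- dplyr::mutate(agg, fold = "mean", .before = 1)
  readr::write_csv(dplyr::bind_rows(per_fold, agg), path)
  invisible(cv)
}
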