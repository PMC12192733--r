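#' Fit a kNN-density applicability domain
#'
#' Implements a k-nearest-neighbour density applicability domain in the
#' style of Sahigara et al.: for each training compound, the mean Euclidean
#' distance to its k nearest training neighbours (self excluded) is
#' computed; the global reference width is a percentile (default median) of
#' these means; each compound's threshold is its own mean kNN distance
#' capped at the reference width, so compounds in dense regions carry
#' tighter thresholds. Thresholds are floored at a tiny positive fraction of
#' the reference width so exact duplicates still admit their own
#' neighbourhood.
#'
#' @param data Scaled feature tibble restricted to the model's descriptor
#'   subset (apply the fitted preprocessing first).
#' @param k Number of neighbours; default 5.
#' @param percentile Reference-width percentile of the mean-kNN-distance
#'   distribution; default 0.5 (median).
#' @param id_col Id column name, dropped.
#' @return A `qsar_ad` object.
#' @export
fit_ad <- function(data, k = 5, percentile = 0.5, id_col = "compound_id") {
  m <- as_feature_matrix(data, id_col = id_col)
  n <- nrow(m)
  if (k >= n) stop("k must be smaller than the number of training compounds")
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  mean_knn <- vapply(seq_len(n), function(i) {
    mean(sort(d[i, ])[seq_len(k)])
  }, double(1))
  ref <- stats::quantile(mean_knn, probs = percentile, names = FALSE)
  thresholds <- pmax(pmin(mean_knn, ref), 1e-8 * max(ref, 1e-8))
  structure(list(
    training_points = m, k = k, percentile = percentile,
    mean_knn_distance = mean_knn, reference_width = ref,
    thresholds = thresholds, columns = colnames(m)
  ), class = "qsar_ad")
}

#' Query an applicability domain
#'
#' A query compound is inside the domain when its distance to at least one
#' training compound does not exceed that compound's threshold.
#'
#' @param ad A `qsar_ad` model.
#' @param newdata Feature tibble with the model's columns, scaled by the
#'   same preprocessing model.
#' @param id_col Id column name, dropped.
#' @return Logical vector, one verdict per row.
#' @export
query_ad <- function(ad, newdata, id_col = "compound_id") {
  stopifnot(inherits(ad, "qsar_ad"))
  missing_cols <- setdiff(ad$columns, setdiff(names(newdata), id_col))
  if (length(missing_cols) > 0) {
    stop("dimension mismatch; missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  q <- as.matrix(newdata[, ad$columns, drop = FALSE])
  train <- ad$training_points
  vapply(seq_len(nrow(q)), function(i) {
    dd <- sqrt(colSums((t(train) - q[i, ])^2))
    any(dd <= ad$thresholds)
  }, logical(1))
}

#' @export
predict.qsar_ad <- function(object, newdata, ...) query_ad(object, newdata)

#' Ensemble applicability-domain verdict
#'
#' Each base model a compound falls inside contributes a reliability score
#' of 0.33; the compound is inside the ensemble domain when the summed
#' score exceeds 0.6, i.e. when at least two of the three models cover it.
#'
#' @param inside Logical vector of three per-model verdicts, or an n x 3
#'   logical matrix (rows = compounds).
#' @return Tibble with the three per-model flags, `ensemble_score` and
#'   `inside_ensemble`.
#' @examples
#' ensemble_ad(c(TRUE, TRUE, FALSE))
#' @export
ensemble_ad <- function(inside) {
  if (is.null(dim(inside))) inside <- matrix(inside, nrow = 1)
  inside <- as.matrix(inside)
  stopifnot(ncol(inside) == 3, is.logical(inside))
  score <- rowSums(inside) * 0.33
  tibble::tibble(
    ad_model_1 = inside[, 1], ad_model_2 = inside[, 2],
    ad_model_3 = inside[, 3],
    ensemble_score = score,
    inside_ensemble = score > 0.6)
}
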