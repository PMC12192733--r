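feature_cols <- function(data, id_col = "compound_id") {
  setdiff(names(data), id_col)
}

as_feature_matrix <- function(data, cols = NULL, id_col = "compound_id") {
  cols <- cols %||% feature_cols(data, id_col)
  as.matrix(data[, cols, drop = FALSE])
}

#' Drop constant and non-finite descriptor columns
#'
#' Removes every descriptor column that is constant over its non-missing
#' entries (including all-missing columns) or contains any non-finite value
#' (`Inf`, `-Inf`, `NaN`). Such columns cannot contribute to compound
#' differentiation.
#'
#' @param data Descriptor tibble (id column + numeric descriptor columns).
#' @param id_col Id column name, default `"compound_id"`.
#' @return The tibble with offending columns removed.
#' @export
drop_constant_infinite <- function(data, id_col = "compound_id") {
  stopifnot(nrow(data) >= 2)
  cols <- feature_cols(data, id_col)
  bad <- vapply(cols, function(cn) {
    x <- data[[cn]]
    if (any(is.nan(x) | is.infinite(x))) return(TRUE)
    obs <- x[!is.na(x)]   # NA = missing (allowed); NaN/Inf are not
    if (length(obs) == 0) return(TRUE)
    length(unique(obs)) <= 1
  }, logical(1))
  data[, c(intersect(id_col, names(data)), cols[!bad]), drop = FALSE]
}

#' Correlation filter over descriptor columns
#'
#' Computes pairwise Pearson correlations (on pairwise-complete observations)
#' and, for every pair with |r| above the threshold, removes one member. The
#' retained set is built greedily left-to-right in column order: a column is
#' kept unless it correlates above the threshold with an already-kept column.
#' Deterministic but order-dependent.
#'
#' @param data Descriptor tibble.
#' @param threshold Absolute Pearson correlation above which a pair is
#'   considered redundant; default 0.90.
#' @param id_col Id column name.
#' @return Character vector of retained descriptor column names.
#' @export
correlation_filter <- function(data, threshold = 0.90, id_col = "compound_id") {
  stopifnot(nrow(data) >= 2)
  cols <- feature_cols(data, id_col)
  if (length(cols) <= 1) return(cols)
  m <- as_feature_matrix(data, cols, id_col)
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  kept <- character(0)
  for (cn in cols) {
    if (length(kept) == 0 || all(abs(cm[cn, kept]) <= threshold)) {
      kept <- c(kept, cn)
    }
  }
  kept
}

knn_impute_matrix <- function(m, k = 3) {
  n <- nrow(m)
  out <- m
  miss_rows <- which(rowSums(is.na(m)) > 0)
  for (i in miss_rows) {
    miss_cols <- which(is.na(m[i, ]))
    # distances on mutually observed columns, normalized by count
    d <- rep(NA_real_, n)
    for (j in seq_len(n)) {
      if (j == i) next
      shared <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(shared)) next
      d[j] <- sqrt(mean((m[i, shared] - m[j, shared])^2))
    }
    for (cn in miss_cols) {
      donors <- which(!is.na(m[, cn]) & !is.na(d))
      if (length(donors) == 0) {
        stop("uninformative descriptor; run drop/filter first")
      }
      ord <- donors[order(d[donors], donors)]
      nn <- ord[seq_len(min(k, length(ord)))]
      out[i, cn] <- mean(m[nn, cn])
    }
  }
  out
}

#' k-nearest-neighbour imputation of missing descriptor cells
#'
#' Each missing cell is replaced by the unweighted mean of the column's
#' values over the k nearest rows (uniform weights), with row distances
#' computed on mutually observed columns (root mean squared difference, so
#' rows sharing different numbers of observed columns are comparable).
#' Observed cells are never modified.
#'
#' @param data Descriptor tibble (may contain `NA`s).
#' @param k Number of neighbours; default 3.
#' @param id_col Id column name.
#' @return The tibble with all `NA` cells imputed.
#' @export
impute_knn <- function(data, k = 3, id_col = "compound_id") {
  cols <- feature_cols(data, id_col)
  m <- as_feature_matrix(data, cols, id_col)
  if (any(colSums(!is.na(m)) == 0)) {
    stop("uninformative descriptor; run drop/filter first")
  }
  if (!anyNA(m)) return(data)
  imp <- knn_impute_matrix(m, k = k)
  out <- data
  out[, cols] <- tibble::as_tibble(imp)
  out
}

#' Fit and apply the preprocessing model
#'
#' Fits the full unsupervised reduction chain on a (training) descriptor
#' matrix — constant/non-finite removal, correlation filter, kNN imputation,
#' standard scaling (centre to mean 0, scale to unit variance, population-sd
#' convention) — and stores everything needed to re-apply the identical
#' transform to new compounds: the retained column list, the imputer's
#' training rows, and the per-column means and standard deviations.
#'
#' @param data Training descriptor tibble.
#' @param cor_threshold Correlation-filter threshold; default 0.90.
#' @param impute_k Neighbours for kNN imputation; default 3.
#' @param id_col Id column name.
#' @return A `qsar_preprocess` object; apply it with [apply_preprocess()] or
#'   `predict()`.
#' @export
fit_preprocess <- function(data, cor_threshold = 0.90, impute_k = 3,
                           id_col = "compound_id") {
  reduced <- drop_constant_infinite(data, id_col = id_col)
  kept <- correlation_filter(reduced, threshold = cor_threshold, id_col = id_col)
  reduced <- reduced[, c(intersect(id_col, names(reduced)), kept), drop = FALSE]
  raw <- as_feature_matrix(reduced, kept, id_col)
  complete <- impute_knn(reduced, k = impute_k, id_col = id_col)
  m <- as_feature_matrix(complete, kept, id_col)
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
  if (any(sd_pop <= 0)) stop("zero-variance column survived filtering")
  # the imputer keeps the RAW (pre-imputation) training rows: a training row
  # re-presented at apply time then reproduces its fit-time imputation (its
  # own raw twin shares the missing cells, so it is never a donor)
  structure(list(
    retained_columns = kept,
    imputer = list(train = raw, k = impute_k),
    center = mu, scale = sd_pop,
    id_col = id_col
  ), class = "qsar_preprocess")
}

#' Apply a fitted preprocessing model
#'
#' Subsets to the retained columns, imputes missing cells against the stored
#' training rows, and scales with the stored training statistics. Applying
#' the model to its own training matrix reproduces the fitted output.
#'
#' @param object A `qsar_preprocess` model.
#' @param data New descriptor tibble (must contain the retained columns).
#' @return Scaled tibble (id column + retained descriptor columns).
#' @export
apply_preprocess <- function(object, data) {
  stopifnot(inherits(object, "qsar_preprocess"))
  id_col <- object$id_col
  missing_cols <- setdiff(object$retained_columns, names(data))
  if (length(missing_cols) > 0) {
    stop("descriptor columns missing from input: ",
         paste(missing_cols, collapse = ", "))
  }
  m <- as_feature_matrix(data, object$retained_columns, id_col)
  if (anyNA(m)) {
    train <- object$imputer$train
    for (i in which(rowSums(is.na(m)) > 0)) {
      d <- rep(NA_real_, nrow(train))
      for (j in seq_len(nrow(train))) {
        shared <- !is.na(m[i, ]) & !is.na(train[j, ])
        if (any(shared)) d[j] <- sqrt(mean((m[i, shared] - train[j, shared])^2))
      }
      for (cn in which(is.na(m[i, ]))) {
        donors <- which(!is.na(train[, cn]) & !is.na(d))
        if (length(donors) == 0) stop("no imputation donors for column ", cn)
        ord <- donors[order(d[donors], donors)]
        nn <- ord[seq_len(min(object$imputer$k, length(ord)))]
        m[i, cn] <- mean(train[nn, cn])
      }
    }
  }
  scaled <- sweep(sweep(m, 2, object$center), 2, object$scale, "/")
  out <- tibble::as_tibble(scaled)
  if (id_col %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(!!id_col := data[[id_col]]), out)
  }
  out
}

#' @export
predict.qsar_preprocess <- function(object, newdata, ...) {
  apply_preprocess(object, newdata)
}

#' k-means cluster-stratified train/validation split
#'
#' Clusters the compounds in descriptor space with k-means, then assigns
#' members of each cluster to train/validation at the global fraction
#' (largest-remainder rounding within clusters), so every region of chemical
#' space is represented in both sets. Clusters with a single member go to the
#' training set.
#'
#' @param data Preprocessed descriptor tibble.
#' @param train_fraction Target training share; default 0.75.
#' @param n_clusters Number of k-means clusters; default
#'   `round(sqrt(n/2))` (at least 1).
#' @param seed Integer seed controlling both the clustering and the
#'   within-cluster assignment.
#' @param id_col Id column name.
#' @return A tibble with `compound_id`, `cluster`, and `set`
#'   (`"train"`/`"validation"`).
#' @export
cluster_stratified_split <- function(data, train_fraction = 0.75,
                                     n_clusters = NULL, seed = 1,
                                     id_col = "compound_id") {
  m <- as_feature_matrix(data, id_col = id_col)
  n <- nrow(m)
  stopifnot(n >= 2, train_fraction > 0, train_fraction < 1)
  n_clusters <- n_clusters %||% max(1L, round(sqrt(n / 2)))
  ids <- if (id_col %in% names(data)) as.character(data[[id_col]])
         else as.character(seq_len(n))
  with_seed(seed, {
    cl <- if (n_clusters == 1) rep(1L, n) else
      stats::kmeans(m, centers = n_clusters, nstart = 5, iter.max = 50)$cluster
    groups <- sort(unique(cl))
    sizes <- vapply(groups, function(g) sum(cl == g), integer(1))
    eligible <- sizes >= 2  # singleton clusters go wholesale to train
    quota <- sizes * train_fraction
    n_train_g <- floor(quota)
    target <- round(sum(quota[eligible]))
    # largest-remainder: hand the leftover compounds to the clusters with the
    # biggest fractional quotas (ties by cluster order)
    rem <- target - sum(n_train_g[eligible])
    if (rem > 0) {
      ord <- order(-(quota - n_train_g), seq_along(groups))
      ord <- ord[eligible[ord]][seq_len(rem)]
      n_train_g[ord] <- n_train_g[ord] + 1L
    }
    n_train_g <- pmax(1L, pmin(sizes - 1L, n_train_g))
    set <- character(n)
    for (gi in seq_along(groups)) {
      idx <- which(cl == groups[gi])
      if (!eligible[gi]) { set[idx] <- "train"; next }
      tr <- sample(idx, n_train_g[gi])
      set[tr] <- "train"; set[setdiff(idx, tr)] <- "validation"
    }
    tibble::tibble(compound_id = ids, cluster = cl, set = set)
  })
}
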