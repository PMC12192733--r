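# Shared fixtures built in code; kept tiny so the suite stays fast.

# Small preprocessed synthetic classification problem reused across tests.
fixture_classification <- function(n = 120, d = 12, n_informative = 4,
                                   seed = 11) {
  make_synthetic_classification(n, d, n_informative, effect_size = 1.5,
                                seed = seed)
}

# Brute-force metric recount straight from label vectors, independent of
# classification_metrics(): every quantity recomputed from first principles.
brute_force_metrics <- function(truth, pred) {
  tp <- sum(truth == "active" & pred == "active")
  tn <- sum(truth == "inactive" & pred == "inactive")
  fp <- sum(truth == "inactive" & pred == "active")
  fn <- sum(truth == "active" & pred == "inactive")
  den <- function(x) if (x == 0) NA_real_ else x
  list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    recall = tp / den(tp + fn),
    precision = tp / den(tp + fp),
    specificity = tn / den(tn + fp),
    fpr = fp / den(tn + fp),
    fnr = fn / den(tp + fn),
    mcc = {
      d <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tn + fp)
      if (d == 0) NA_real_ else (tp * tn - fp * fn) / d
    },
    f1 = {
      p <- tp / den(tp + fp); r <- tp / den(tp + fn)
      if (is.na(p) || is.na(r) || p + r == 0) NA_real_
      else 2 * p * r / (p + r)
    })
}

# Exhaustive kNN imputation oracle: per missing cell, rank all other rows by
# RMS distance over mutually observed columns and average the column values
# of the k nearest rows that observe it.
brute_force_knn_impute <- function(m, k = 3) {
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (!is.na(m[i, j])) next
      d <- sapply(seq_len(nrow(m)), function(r) {
        if (r == i) return(NA_real_)
        shared <- !is.na(m[i, ]) & !is.na(m[r, ])
        if (!any(shared)) return(NA_real_)
        sqrt(mean((m[i, shared] - m[r, shared])^2))
      })
      donors <- which(!is.na(m[, j]) & !is.na(d))
      ord <- donors[order(d[donors], donors)]
      nn <- ord[seq_len(min(k, length(ord)))]
      out[i, j] <- mean(m[nn, j])
    }
  }
  out
}
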