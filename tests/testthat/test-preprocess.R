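test_that("constant and non-finite columns are dropped", {
  d <- tibble::tibble(
    compound_id = letters[1:4],
    const = rep(1, 4),
    inf_col = c(1, Inf, 2, 3),
    nan_col = c(1, NaN, 2, 3),
    varying = c(0, 1, 0, 2),
    const_with_na = c(5, NA, 5, 5))
  out <- drop_constant_infinite(d)
  expect_equal(setdiff(names(out), "compound_id"), "varying")
})

test_that("correlation filter leaves no retained pair above threshold", {
  syn <- make_synthetic_classification(80, 15, 3, n_redundant = 5, seed = 3)
  kept <- correlation_filter(syn$data, threshold = 0.90)
  m <- as.matrix(syn$data[, kept])
  cm <- abs(stats::cor(m))
  diag(cm) <- 0
  expect_lte(max(cm), 0.90)
  # identical columns: exactly one survives
  d <- tibble::tibble(compound_id = letters[1:5],
                      a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
                      c = c(5, 1, 4, 2, 3))
  expect_equal(correlation_filter(d), c("a", "c"))
  # r = 0.5 pair: both survive
  d2 <- tibble::tibble(compound_id = letters[1:4],
                       x = c(1, 2, 3, 4), y = c(1, 3, 2, 4))
  expect_setequal(correlation_filter(d2), c("x", "y"))
})

test_that("kNN imputation matches the exhaustive brute-force oracle", {
  # toy example verifiable by hand: one missing cell among 4 rows
  m <- rbind(c(0, 0, 10), c(0.1, 0, 20), c(0, 0.1, 30), c(5, 5, NA))
  d <- tibble::as_tibble(as.data.frame(m)) |>
    dplyr::mutate(compound_id = letters[1:4], .before = 1)
  imp <- impute_knn(d, k = 3)
  expect_equal(imp$V3[4], mean(c(10, 20, 30)))
  # randomized matrices up to 20 x 10 against the oracle
  for (seed in 1:5) {
    syn <- withr::with_seed(seed, {
      mm <- matrix(rnorm(20 * 10), 20, 10)
      mm[sample(length(mm), 25)] <- NA
      mm
    })
    if (any(colSums(!is.na(syn)) == 0)) next
    dd <- tibble::as_tibble(as.data.frame(syn))
    got <- as.matrix(impute_knn(dd, k = 3, id_col = character(0)))
    want <- brute_force_knn_impute(syn, k = 3)
    expect_equal(got, want, ignore_attr = TRUE)
  }
  # observed cells never modified
  d_obs <- !is.na(m)
  expect_equal(as.matrix(imp[, -1])[d_obs], m[d_obs], ignore_attr = TRUE)
  # complete matrix returned unchanged
  full <- tibble::tibble(compound_id = c("a", "b"), x = c(1, 2), y = c(3, 4))
  expect_identical(impute_knn(full), full)
})

test_that("fitted scaler centres and scales with stored statistics", {
  d <- tibble::tibble(compound_id = letters[1:3], x = c(1, 2, 3),
                      y = c(10, 30, 20))
  prep <- fit_preprocess(d)
  scaled <- apply_preprocess(prep, d)
  # population-sd convention: {1,2,3} -> +-1.2247
  expect_equal(scaled$x, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(mean(scaled$y), 0, tolerance = 1e-10)
  expect_equal(mean(scaled$y^2), 1, tolerance = 1e-10)
  # apply is stateless reuse of training statistics, not refitting
  shifted <- dplyr::mutate(d, x = x + 100)
  expect_equal(apply_preprocess(prep, shifted)$x,
               scaled$x + 100 / prep$scale[["x"]])
  # translation-invariant: a constant-shifted training column scales the same
  prep2 <- fit_preprocess(dplyr::mutate(d, x = x + 7))
  expect_equal(apply_preprocess(prep2, dplyr::mutate(d, x = x + 7))$x,
               scaled$x)
})

test_that("preprocessing model reapplies identically to its training data", {
  syn <- make_synthetic_classification(60, 10, 3, n_redundant = 2,
                                       missing_frac = 0.05, seed = 9)
  prep <- fit_preprocess(syn$data)
  a <- apply_preprocess(prep, syn$data)
  b <- apply_preprocess(prep, syn$data)
  expect_identical(a, b)
  cols <- setdiff(names(a), "compound_id")
  expect_true(all(abs(colMeans(as.matrix(a[, cols]))) < 1e-10))
  expect_true(all(abs(colMeans(as.matrix(a[, cols])^2) - 1) < 1e-10))
})

test_that("cluster-stratified split hits the global fraction per cluster", {
  syn <- make_synthetic_classification(100, 5, 2, seed = 21)
  sp <- cluster_stratified_split(syn$data, train_fraction = 0.75,
                                 n_clusters = 4, seed = 33)
  expect_equal(sort(unique(sp$set)), c("train", "validation"))
  expect_equal(sum(sp$set == "train"), 75)
  counts <- table(sp$cluster, sp$set)
  # every cluster with >= 2 members contributes to both sets
  for (g in rownames(counts)) {
    if (sum(counts[g, ]) >= 4) {
      expect_gt(counts[g, "train"], 0)
      expect_gt(counts[g, "validation"], 0)
    }
    # per-cluster share within one compound of the 75% target
    expect_lte(abs(counts[g, "train"] - 0.75 * sum(counts[g, ])), 1)
  }
  # reproducible under the same seed, different under another
  sp2 <- cluster_stratified_split(syn$data, train_fraction = 0.75,
                                  n_clusters = 4, seed = 33)
  expect_identical(sp, sp2)
  sp3 <- cluster_stratified_split(syn$data, train_fraction = 0.75,
                                  n_clusters = 4, seed = 34)
  expect_false(identical(sp$set, sp3$set))
  # single cluster degenerates to a plain random split
  sp1 <- cluster_stratified_split(syn$data, n_clusters = 1, seed = 5)
  expect_equal(sum(sp1$set == "train"), 75)
  # two separated blobs each contribute to both sets
  blobs <- withr::with_seed(8, tibble::tibble(
    compound_id = sprintf("b%03d", 1:60),
    x = c(rnorm(30), rnorm(30, 12)), y = c(rnorm(30), rnorm(30, 12))))
  spb <- cluster_stratified_split(blobs, n_clusters = 2, seed = 2)
  tb <- table(spb$cluster, spb$set)
  expect_true(all(tb > 0))
})
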