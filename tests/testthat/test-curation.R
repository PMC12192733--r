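test_that("pIC50 transform and its inverse round-trip exactly", {
  expect_equal(to_pic50(1), 9)
  expect_equal(to_pic50(1000), 6)
  expect_equal(to_pic50(50), -log10(5e-8))
  x <- c(0.012, 1, 37.5, 50, 1e6)
  expect_equal(pic50_to_ic50(to_pic50(x)), x)
  expect_error(to_pic50(0), "invalid potency")
  expect_error(to_pic50(-5), "invalid potency")
})

test_that("activity labelling includes the 50 nM boundary", {
  expect_equal(label_activity(50), "active")
  expect_equal(label_activity(50.1), "inactive")
  expect_equal(label_activity(0.012), "active")
  expect_error(label_activity(-1), "invalid potency")
  # labelling commutes with the pIC50 round-trip
  x <- exp(seq(log(0.01), log(1e5), length.out = 25))
  expect_equal(label_activity(pic50_to_ic50(to_pic50(x))), label_activity(x))
})

test_that("standardization strips salts and waters and canonicalizes", {
  d <- standardize_structures(tibble::tibble(
    smiles = c("CCO", "CC(=O)[O-].[Na+].O", "OCC", "C(((", "C1CC")))
  expect_true(is.na(d$reject_reason[1]))
  # salt + water: only the acetate fragment survives
  expect_false(grepl("Na", d$standard_smiles[2]))
  expect_false(grepl("\\.", d$standard_smiles[2]))
  # canonical key is atom-order invariant
  expect_equal(d$structure_key[1], d$structure_key[3])
  # malformed strings rejected, not dropped
  expect_equal(d$reject_reason[4], "invalid structure")
  expect_equal(d$reject_reason[5], "invalid structure")
  expect_equal(nrow(d), 5)
})

test_that("duplicate resolution applies the geometric-mean / CV rule", {
  base <- tibble::tibble(
    compound_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    structure_key = c("A", "A", "B", "B", "C", "C"),
    standard_smiles = c("A", "A", "B", "B", "C", "C"),
    ic50 = c(100, 110, 10, 1000, 50, 50))
  res <- resolve_duplicates(base, task = "regression")
  kept <- res$entries
  # concordant pair {100, 110}: sample sd/mean ~ 0.067 < 0.2, geometric mean
  expect_equal(kept$ic50[kept$structure_key == "A"], sqrt(100 * 110))
  # discordant pair {10, 1000}: sd/mean ~ 1.39 >= 0.2, both rejected
  expect_false("B" %in% kept$structure_key)
  expect_setequal(res$rejections$compound_id, c("b1", "b2"))
  expect_equal(unique(res$rejections$reason), "discordant duplicates")
  # identical values collapse to one entry
  expect_equal(kept$ic50[kept$structure_key == "C"], 50)
  expect_equal(sum(kept$structure_key == "C"), 1)
})

test_that("duplicate resolution is idempotent and conserves records", {
  withr::with_seed(5, {
    keys <- sample(LETTERS[1:8], 30, replace = TRUE)
    d <- tibble::tibble(
      compound_id = sprintf("c%02d", 1:30),
      structure_key = keys, standard_smiles = keys,
      ic50 = stats::rlnorm(30, log(100), 1.5))
  })
  res <- resolve_duplicates(d, task = "regression")
  # conservation: every input id is kept (possibly merged) or rejected
  kept_keys <- res$entries$structure_key
  accounted <- d$compound_id %in% res$rejections$compound_id |
    d$structure_key %in% kept_keys
  expect_true(all(accounted))
  # geometric mean of a merged group lies within the group's range
  for (k in kept_keys) {
    vals <- d$ic50[d$structure_key == k]
    expect_gte(res$entries$ic50[res$entries$structure_key == k] + 1e-12, min(vals))
    expect_lte(res$entries$ic50[res$entries$structure_key == k] - 1e-12, max(vals))
  }
  # idempotence: re-resolving the resolved entries changes nothing
  again <- resolve_duplicates(res$entries, task = "regression")
  expect_equal(again$entries$ic50, res$entries$ic50)
  expect_equal(nrow(again$rejections), 0)
})

test_that("classification dedup rejects conflicting labels", {
  d <- tibble::tibble(
    compound_id = c("x1", "x2"), structure_key = c("X", "X"),
    standard_smiles = c("X", "X"), ic50 = c(10, 2000))
  res <- resolve_duplicates(d, task = "classification")
  expect_equal(nrow(res$entries), 0)
  expect_equal(unique(res$rejections$reason), "conflicting labels")
})

test_that("full curation of the toy set behaves as planted", {
  toy <- toy_molecule_set()
  cls <- suppressWarnings(curate_activities(toy, "classification"))
  rej <- curation_rejections(cls)
  # invalid SMILES surfaced with a reason
  expect_true("TOY032" %in% rej$compound_id)
  expect_equal(rej$reason[rej$compound_id == "TOY032"], "invalid structure")
  # the aspirin duplicate pair written in two atom orders collapses
  expect_equal(sum(cls$compound_id %in% c("TOY001", "TOY026")), 1)
  # discordant pair rejected under conflicting binary labels
  expect_false(any(c("TOY029", "TOY030") %in% cls$compound_id))
  # censored record admitted for classification, excluded from regression
  expect_true("TOY031" %in% cls$compound_id)
  reg <- suppressWarnings(curate_activities(toy, "regression"))
  expect_false("TOY031" %in% reg$compound_id)
  expect_true("pic50" %in% names(reg))
  expect_equal(reg$pic50, to_pic50(reg$ic50))
  # water-containing entry standardized to the bare phenol
  expect_equal(cls$standard_smiles[cls$compound_id == "TOY028"], "Oc1ccccc1")
  # every record accounted for exactly once
  expect_equal(nrow(cls) + nrow(rej) +
                 sum(cls$n_merged - 1, na.rm = TRUE), nrow(toy))
})
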