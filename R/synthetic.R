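#' Synthetic classification dataset with planted signal
#'
#' Draws standard-normal features, optionally adds a correlated block
#' (near-duplicates of the first informative columns, to exercise the
#' correlation filter) and a fraction of missing cells (to exercise
#' imputation), and generates binary labels from a logistic link on the
#' informative columns.
#'
#' @param n Rows (compounds).
#' @param d Feature columns (before the correlated block).
#' @param n_informative Number of label-driving columns.
#' @param effect_size Logistic coefficient magnitude on informative
#'   columns; 0 makes labels independent of features.
#' @param class_balance Target P(active) via the intercept; default 0.5.
#' @param n_redundant Extra columns highly correlated with the first
#'   informative ones; default 0.
#' @param missing_frac Fraction of cells set to `NA`; default 0.
#' @param seed Integer seed; identical parameters and seed regenerate the
#'   identical dataset.
#' @return List with `data` (tibble: `compound_id` + features), `labels`
#'   (`"active"`/`"inactive"`), `informative_columns`, and
#'   `generation_params`.
#' @export
make_synthetic_classification <- function(n, d, n_informative,
                                          effect_size = 1,
                                          class_balance = 0.5,
                                          n_redundant = 0,
                                          missing_frac = 0, seed = 1) {
  stopifnot(n_informative <= d, n >= 2, missing_frac >= 0, missing_frac < 1)
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * d), n, d)
    colnames(x) <- sprintf("X%03d", seq_len(d))
    informative <- colnames(x)[seq_len(n_informative)]
    beta <- rep(0, d)
    beta[seq_len(n_informative)] <- effect_size *
      rep_len(c(1, -1), n_informative)
    eta <- as.numeric(x %*% beta) + stats::qlogis(class_balance)
    labels <- ifelse(stats::runif(n) < stats::plogis(eta),
                     "active", "inactive")
    if (n_redundant > 0) {
      src <- rep_len(seq_len(max(1, n_informative)), n_redundant)
      red <- x[, src, drop = FALSE] +
        matrix(stats::rnorm(n * n_redundant, sd = 0.01), n, n_redundant)
      colnames(red) <- sprintf("R%03d", seq_len(n_redundant))
      x <- cbind(x, red)
    }
    if (missing_frac > 0) {
      holes <- which(stats::runif(length(x)) < missing_frac)
      x[holes] <- NA_real_
    }
    list(
      data = dplyr::bind_cols(
        tibble::tibble(compound_id = sprintf("cmp%04d", seq_len(n))),
        tibble::as_tibble(x)),
      labels = labels,
      informative_columns = informative,
      generation_params = list(n = n, d = d, n_informative = n_informative,
                               effect_size = effect_size,
                               class_balance = class_balance,
                               n_redundant = n_redundant,
                               missing_frac = missing_frac, seed = seed))
  })
}

#' Synthetic regression dataset with planted signal
#'
#' Continuous response = linear combination of the informative columns plus
#' Gaussian noise. The oracle R-squared ceiling is
#' var(signal) / (var(signal) + noise_sd^2).
#'
#' @param n,d,n_informative As in [make_synthetic_classification()].
#' @param coef_scale Coefficient magnitude on informative columns.
#' @param noise_sd Gaussian noise standard deviation.
#' @param missing_frac,seed As above.
#' @return List with `data`, `response`, `informative_columns`,
#'   `r2_ceiling`, and `generation_params`.
#' @export
make_synthetic_regression <- function(n, d, n_informative, coef_scale = 1,
                                      noise_sd = 1, missing_frac = 0,
                                      seed = 1) {
  stopifnot(n_informative <= d, n >= 2)
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * d), n, d)
    colnames(x) <- sprintf("X%03d", seq_len(d))
    informative <- colnames(x)[seq_len(n_informative)]
    beta <- rep(0, d)
    beta[seq_len(n_informative)] <- coef_scale * rep_len(c(1, -1), n_informative)
    signal <- as.numeric(x %*% beta)
    y <- signal + stats::rnorm(n, sd = noise_sd)
    signal_var <- sum(beta^2)   # features are iid standard normal
    if (missing_frac > 0) {
      holes <- which(stats::runif(length(x)) < missing_frac)
      x[holes] <- NA_real_
    }
    list(
      data = dplyr::bind_cols(
        tibble::tibble(compound_id = sprintf("cmp%04d", seq_len(n))),
        tibble::as_tibble(x)),
      response = y,
      informative_columns = informative,
      r2_ceiling = signal_var / (signal_var + noise_sd^2),
      generation_params = list(n = n, d = d, n_informative = n_informative,
                               coef_scale = coef_scale, noise_sd = noise_sd,
                               missing_frac = missing_frac, seed = seed))
  })
}

#' Hand-curated toy molecule set
#'
#' A fixed set of ~30 small drug-like molecules with synthetic IC50
#' assignments spanning 1-10,000 nM, built to exercise the full
#' curate-train-predict path without any download. Deliberately includes a
#' duplicate structure written in two SMILES notations, a sodium-salt form,
#' a water-containing entry, a discordant duplicate pair, and one invalid
#' SMILES. The IC50 values are synthetic labels for plumbing tests, not
#' measured potencies.
#'
#' @return Activity tibble with `compound_id`, `smiles`, `ic50` (nM),
#'   `relation`.
#' @export
toy_molecule_set <- function() {
  tibble::tribble(
    ~compound_id, ~smiles,                                            ~ic50, ~relation,
    "TOY001", "CC(=O)Oc1ccccc1C(=O)O",                                  12,  "=",
    "TOY002", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",                            850,  "=",
    "TOY003", "CC(=O)Nc1ccc(O)cc1",                                    3200, "=",
    "TOY004", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",                              45, "=",
    "TOY005", "OC(=O)c1ccccc1O",                                        2100, "=",
    "TOY006", "c1ccc2c(c1)cccc2O",                                       610, "=",
    "TOY007", "CCN(CC)CCNC(=O)c1ccc(N)cc1",                               28, "=",
    "TOY008", "COc1ccc2cc(ccc2c1)C(C)C(=O)O",                             18, "=",
    "TOY009", "Clc1ccccc1C(=O)Nc1ccccc1",                                950, "=",
    "TOY010", "CC(C)NCC(O)COc1ccccc1",                                    75, "=",
    "TOY011", "Nc1ccc(cc1)S(=O)(=O)N",                                  4800, "=",
    "TOY012", "CN1CCC[C@H]1c1cccnc1",                                    130, "=",
    "TOY013", "OCC(O)C(O)C(O)C(O)CO",                                   9900, "=",
    "TOY014", "CC(=O)NCCc1c[nH]c2ccccc12",                                39, "=",
    "TOY015", "COc1cc2c(cc1OC)CCN(C)C2",                                 220, "=",
    "TOY016", "Oc1ccc(cc1)C(=O)OCC",                                    1500, "=",
    "TOY017", "CC(N)Cc1ccccc1",                                          380, "=",
    "TOY018", "NC(=O)c1ccc(O)cc1",                                      5600, "=",
    "TOY019", "CN(C)CCOC(c1ccccc1)c1ccccc1",                              52, "=",
    "TOY020", "CC(C)(C)NCC(O)c1ccc(O)c(O)c1",                             33, "=",
    "TOY021", "O=C(O)Cc1ccccc1Nc1c(Cl)cccc1Cl",                            8, "=",
    "TOY022", "CCOC(=O)c1ccccc1N",                                       720, "=",
    "TOY023", "CSc1ccc(cc1)C(=O)C1CC1",                                  460, "=",
    "TOY024", "O=c1[nH]cnc2[nH]cnc12",                                  8700, "=",
    "TOY025", "CC12CCC3c4ccc(O)cc4CCC3C1CCC2O",                           21, "=",
    # duplicate of TOY001 in a different atom ordering, concordant value
    "TOY026", "OC(=O)c1ccccc1OC(C)=O",                                    13, "=",
    # sodium salt: organic anion must survive, counter-ion dropped
    "TOY027", "CC(C)Cc1ccc(cc1)C(C)C(=O)[O-].[Na+]",                      47, "=",
    # co-crystallized water: stripped during standardization
    "TOY028", "Oc1ccccc1.O",                                            1800, "=",
    # discordant duplicate pair: both rejected for regression
    "TOY029", "CN1CCN(CC1)c1ccccc1",                                      10, "=",
    "TOY030", "CN1CCN(CC1)c1ccccc1",                                    2000, "=",
    # censored measurement: admitted for classification only
    "TOY031", "Cc1ccccc1NC(=O)c1ccccc1",                                5000, ">",
    # planted invalid SMILES
    "TOY032", "C1CC",                                                     99, "=",
  )
}
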