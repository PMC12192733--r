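#' Transform IC50 (nM) to pIC50
#'
#' pIC50 is the negative decadic logarithm of the IC50 expressed in molar
#' units, the standard potency scale in medicinal chemistry: 1 nM corresponds
#' to pIC50 = 9, 1 uM to pIC50 = 6.
#'
#' @param ic50_nM Positive numeric vector of IC50 values in nanomolar.
#' @return Numeric vector of pIC50 values (dimensionless).
#' @examples
#' to_pic50(c(1, 50, 1000))
#' @export
to_pic50 <- function(ic50_nM) {
  if (any(!is.finite(ic50_nM) | ic50_nM <= 0)) {
    stop("invalid potency: IC50 must be a positive finite value in nM")
  }
  -log10(ic50_nM * 1e-9)
}

#' Transform pIC50 back to IC50 in nM
#'
#' Exact inverse of [to_pic50()]: IC50 (nM) = 10^(9 - pIC50).
#'
#' @param pic50 Numeric vector of pIC50 values.
#' @return IC50 values in nanomolar.
#' @export
pic50_to_ic50 <- function(pic50) {
  10^(9 - pic50)
}

#' Label compounds active/inactive by the 50 nM potency rule
#'
#' A compound is labelled `"active"` when its IC50 is at or below the
#' threshold (default 50 nM, a stringent lead-likeness cutoff for
#' high-affinity enzyme inhibitors), `"inactive"` otherwise. The boundary
#' value itself is active.
#'
#' @param ic50_nM Positive numeric vector, IC50 in nanomolar.
#' @param threshold_nM Activity threshold in nM; default 50.
#' @return Character vector of `"active"` / `"inactive"`.
#' @examples
#' label_activity(c(50, 50.1, 0.012))
#' @export
label_activity <- function(ic50_nM, threshold_nM = 50) {
  if (any(!is.finite(ic50_nM) | ic50_nM <= 0)) {
    stop("invalid potency: IC50 must be a positive finite value in nM")
  }
  ifelse(ic50_nM <= threshold_nM, "active", "inactive")
}

# Balanced-delimiter sanity check: Open Babel accepts some malformed SMILES
# (dangling branch parentheses) by silently truncating; reject those up front.
smiles_delimiters_balanced <- function(smiles) {
  vapply(smiles, function(s) {
    chars <- strsplit(s, "")[[1]]
    depth_p <- cumsum((chars == "(") - (chars == ")"))
    depth_b <- cumsum((chars == "[") - (chars == "]"))
    !any(depth_p < 0) && !any(depth_b < 0) &&
      utils::tail(depth_p, 1) == 0 && utils::tail(depth_b, 1) == 0
  }, logical(1), USE.NAMES = FALSE)
}

ob_canonical <- function(smiles) {
  out <- character(length(smiles))
  for (i in seq_along(smiles)) {
    res <- tryCatch(
      suppressWarnings(
        ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles[i], "\tq"))
      ),
      error = function(e) ""
    )
    out[i] <- sub("\t.*$", "", sub("\n.*$", "", res))
  }
  out
}

# Heavy-atom count of a single-fragment SMILES, via its molecular formula.
fragment_heavy_atoms <- function(frag_smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(frag_smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0) return(0L)
  nrow(ChemmineR::atomblock(sdf[[1]]))
}

standardize_one <- function(smiles) {
  if (is.na(smiles) || !nzchar(trimws(smiles))) {
    return(list(ok = FALSE, reason = "invalid structure"))
  }
  smiles <- trimws(smiles)
  if (!smiles_delimiters_balanced(smiles)) {
    return(list(ok = FALSE, reason = "invalid structure"))
  }
  can <- ob_canonical(smiles)
  if (!nzchar(can)) {
    return(list(ok = FALSE, reason = "invalid structure"))
  }
  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  # Drop waters always; keep the largest carbon-containing (organic) fragment.
  is_water <- frags %in% c("O", "[OH2]", "[H]O[H]", "HOH")
  frags <- frags[!is_water]
  if (length(frags) == 0) {
    return(list(ok = FALSE, reason = "no organic fragment"))
  }
  organic <- grepl("c|C", frags) & !grepl("^\\[C[al]", frags)  # excl. Ca/Cl-only ions
  pool <- if (any(organic)) frags[organic] else frags
  if (length(pool) > 1) {
    sizes <- vapply(pool, fragment_heavy_atoms, integer(1))
    keep <- pool[which.max(sizes)]
  } else {
    keep <- pool[1]
  }
  key <- ob_canonical(keep)
  if (!nzchar(key)) {
    return(list(ok = FALSE, reason = "invalid structure"))
  }
  list(ok = TRUE, standard_smiles = key, structure_key = key)
}

#' Standardize structures in an activity or SMILES table
#'
#' Canonicalizes each SMILES with Open Babel, removes water molecules and
#' counter-ion/salt fragments (keeping the largest organic fragment), and
#' derives a canonical structure key that is stable across input atom
#' orderings. Unparseable strings are flagged rather than dropped, so the
#' caller can inspect or log them.
#'
#' @param data A data frame with a SMILES column.
#' @param smiles_col Name of the SMILES column (string); default `"smiles"`.
#' @return The input tibble with columns `standard_smiles`, `structure_key`
#'   (NA where rejected), and `reject_reason` (NA where accepted).
#' @examples
#' \donttest{
#' tibble::tibble(smiles = c("OCC", "CC(=O)[O-].[Na+].O")) |>
#'   standardize_structures()
#' }
#' @export
standardize_structures <- function(data, smiles_col = "smiles") {
  stopifnot(is.data.frame(data), smiles_col %in% names(data))
  res <- purrr::map(as.character(data[[smiles_col]]), standardize_one)
  dplyr::mutate(
    tibble::as_tibble(data),
    standard_smiles = purrr::map_chr(res, ~ .x$standard_smiles %||% NA_character_),
    structure_key   = purrr::map_chr(res, ~ .x$structure_key %||% NA_character_),
    reject_reason   = purrr::map_chr(res, ~ .x$reason %||% NA_character_)
  )
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Resolve duplicate measurements for the same structure
#'
#' Records sharing a canonical structure key are merged. Identical response
#' values collapse to a single entry. For regression, groups whose IC50
#' coefficient of variation (sd/mean) is below `cv_threshold` are replaced by
#' their geometric mean; discordant groups (CV at or above the threshold) are
#' rejected outright. For classification, groups whose members disagree on
#' the binary activity label are rejected.
#'
#' @param data A standardized activity tibble with columns `compound_id`,
#'   `structure_key`, `ic50` (nM) and, for classification, a pre-computed or
#'   derivable label (the 50 nM rule is applied internally).
#' @param task `"classification"` or `"regression"`.
#' @param cv_threshold Discordance threshold on sd/mean; default 0.2.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param threshold_nM Activity threshold passed to [label_activity()].
#' @return A list with `entries` (one row per retained structure) and
#'   `rejections` (compound_id + reason).
#' @export
resolve_duplicates <- function(data, task = c("classification", "regression"),
                               cv_threshold = 0.2, sd_type = c("sample", "population"),
                               threshold_nM = 50) {
  task <- match.arg(task)
  sd_type <- match.arg(sd_type)
  if (nrow(data) == 0) {
    return(list(
      entries = tibble::tibble(compound_id = character(), structure_key = character(),
                               standard_smiles = character(), ic50 = double()),
      rejections = tibble::tibble(compound_id = character(), reason = character())
    ))
  }
  sdfun <- if (sd_type == "sample") stats::sd else function(x) {
    sqrt(mean((x - mean(x))^2))
  }
  groups <- split(seq_len(nrow(data)), data$structure_key)
  keep <- list(); rej <- list()
  for (g in groups) {
    d <- data[g, ]
    ic <- d$ic50
    if (task == "classification") {
      labs <- label_activity(ic, threshold_nM)
      if (length(unique(labs)) > 1) {
        rej[[length(rej) + 1]] <- tibble::tibble(
          compound_id = d$compound_id, reason = "conflicting labels")
        next
      }
      keep[[length(keep) + 1]] <- d[1, ] |>
        dplyr::mutate(ic50 = ic[1], label = labs[1],
                      n_merged = nrow(d))
    } else {
      if (length(unique(ic)) == 1) {
        keep[[length(keep) + 1]] <- d[1, ] |>
          dplyr::mutate(ic50 = ic[1], n_merged = nrow(d))
        next
      }
      cv <- sdfun(ic) / mean(ic)
      if (cv < cv_threshold) {
        keep[[length(keep) + 1]] <- d[1, ] |>
          dplyr::mutate(ic50 = geometric_mean(ic), n_merged = nrow(d))
      } else {
        rej[[length(rej) + 1]] <- tibble::tibble(
          compound_id = d$compound_id, reason = "discordant duplicates")
      }
    }
  }
  entries <- if (length(keep)) dplyr::bind_rows(keep) else
    data[0, , drop = FALSE]
  rejections <- if (length(rej)) dplyr::bind_rows(rej) else
    tibble::tibble(compound_id = character(), reason = character())
  # restore input order of first appearance
  if (nrow(entries) > 0) {
    first_idx <- vapply(entries$structure_key,
                        function(k) min(which(data$structure_key == k)), integer(1))
    entries <- entries[order(first_idx), , drop = FALSE]
  }
  list(entries = tibble::as_tibble(entries), rejections = rejections)
}

#' Curate an activity table into a modelling-ready dataset
#'
#' Full curation chain: structure standardization (salt/water stripping,
#' canonicalization), relation-qualifier filtering (regression admits only
#' exact `"="` measurements; classification admits all qualifiers),
#' duplicate resolution, and labelling — the binary 50 nM rule for
#' classification, the pIC50 transform for regression.
#'
#' @param data Activity tibble with columns for compound id, SMILES, IC50
#'   value (nM) and relation qualifier.
#' @param task `"classification"` or `"regression"`.
#' @param id_col,smiles_col,value_col,relation_col Column names in `data`.
#' @param cv_threshold,sd_type,threshold_nM See [resolve_duplicates()].
#' @return A tibble of curated entries (`compound_id`, `standard_smiles`,
#'   `structure_key`, `ic50`, and `label` or `pic50`), with the rejection log
#'   attached as attribute `"rejections"` (see [curation_rejections()]).
#' @export
curate_activities <- function(data, task = c("classification", "regression"),
                              id_col = "compound_id", smiles_col = "smiles",
                              value_col = "ic50", relation_col = "relation",
                              cv_threshold = 0.2, sd_type = "sample",
                              threshold_nM = 50) {
  task <- match.arg(task)
  stopifnot(all(c(id_col, smiles_col, value_col) %in% names(data)))
  df <- tibble::tibble(
    compound_id = as.character(data[[id_col]]),
    smiles = as.character(data[[smiles_col]]),
    ic50 = as.numeric(data[[value_col]]),
    relation = if (relation_col %in% names(data))
      as.character(data[[relation_col]]) else "="
  )
  rejections <- tibble::tibble(compound_id = character(), reason = character())

  bad_value <- !is.finite(df$ic50) | df$ic50 <= 0
  if (any(bad_value)) {
    rejections <- dplyr::bind_rows(rejections, tibble::tibble(
      compound_id = df$compound_id[bad_value], reason = "invalid potency"))
    df <- df[!bad_value, , drop = FALSE]
  }
  if (task == "regression") {
    not_eq <- df$relation != "="
    if (any(not_eq)) {
      rejections <- dplyr::bind_rows(rejections, tibble::tibble(
        compound_id = df$compound_id[not_eq], reason = "non-exact measurement"))
      df <- df[!not_eq, , drop = FALSE]
    }
  }
  std <- standardize_structures(df, smiles_col = "smiles")
  bad_struct <- !is.na(std$reject_reason)
  if (any(bad_struct)) {
    rejections <- dplyr::bind_rows(rejections, tibble::tibble(
      compound_id = std$compound_id[bad_struct],
      reason = std$reject_reason[bad_struct]))
  }
  std <- std[!bad_struct, , drop = FALSE]
  res <- resolve_duplicates(std, task = task, cv_threshold = cv_threshold,
                            sd_type = sd_type, threshold_nM = threshold_nM)
  rejections <- dplyr::bind_rows(rejections, res$rejections)
  out <- res$entries
  if (nrow(out) > 0) {
    if (task == "classification") {
      out$label <- label_activity(out$ic50, threshold_nM)
    } else {
      out$pic50 <- to_pic50(out$ic50)
    }
    out <- dplyr::select(out, dplyr::any_of(c(
      "compound_id", "standard_smiles", "structure_key", "ic50",
      "label", "pic50", "n_merged")))
  }
  attr(out, "rejections") <- rejections
  class(out) <- c("qsar_curated", class(out))
  out
}

#' Rejection log of a curated dataset
#'
#' @param curated Result of [curate_activities()].
#' @return Tibble with `compound_id` and `reason` for every rejected record.
#' @export
curation_rejections <- function(curated) {
  attr(curated, "rejections") %||%
    tibble::tibble(compound_id = character(), reason = character())
}

#' Read an activity table from CSV/TSV
#'
#' Thin wrapper over [readr::read_delim()] with a configurable column
#' mapping, returning the canonical column names used by
#' [curate_activities()].
#'
#' @param path File path (`.csv` or `.tsv`/`.txt`, delimiter inferred).
#' @param id_col,smiles_col,value_col,relation_col Source column names.
#' @return Tibble with columns `compound_id`, `smiles`, `ic50`, `relation`.
#' @export
read_activity_table <- function(path, id_col = "compound_id",
                                smiles_col = "smiles", value_col = "ic50",
                                relation_col = "relation") {
  delim <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  stopifnot(all(c(id_col, smiles_col, value_col) %in% names(raw)))
  tibble::tibble(
    compound_id = as.character(raw[[id_col]]),
    smiles = as.character(raw[[smiles_col]]),
    ic50 = as.numeric(raw[[value_col]]),
    relation = if (relation_col %in% names(raw))
      as.character(raw[[relation_col]]) else "="
  )
}

#' Write a curated dataset (and its rejection log) to CSV
#'
#' @param curated Result of [curate_activities()].
#' @param path Output CSV path for the curated entries.
#' @param rejections_path Optional path for the rejection log CSV.
#' @return `curated`, invisibly.
#' @export
write_curated <- function(curated, path, rejections_path = NULL) {
  readr::write_csv(tibble::as_tibble(curated), path)
  if (!is.null(rejections_path)) {
    readr::write_csv(curation_rejections(curated), rejections_path)
  }
  invisible(curated)
}
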