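#' Descriptor category registry
#'
#' The 20 category labels used to organize descriptor columns. Every
#' descriptor column produced by a provider maps to exactly one of these
#' labels; which labels are populated depends on the provider (the built-in
#' Open Babel/ChemmineR backend covers the 2D families only).
#'
#' @return A tibble with a single `category` column of 20 labels.
#' @export
descriptor_categories <- function() {
  tibble::tibble(category = c(
    "Autocorrelations", "Functional Groups",
    "Bidimensional", "Connectivity indexes",
    "Topological charge", "Information indexes",
    "Atom centered", "Molecular properties",
    "Constitutionals", "Rdkit 3D",
    "CPSA (Charged Partial Surface Area)", "Type MOE",
    "Edge Adjacency", "Topological",
    "Electro topological estate", "Burden Eigenvalues",
    "Physicochemical", "Eigenvalues",
    "Getaway", "Walk Path Counts"
  ))
}

# SMARTS fragment panel: name -> pattern -> category
smarts_panel <- function() {
  tibble::tribble(
    ~descriptor,    ~smarts,                      ~category,
    "nCH3",         "[CX4H3]",                    "Atom centered",
    "nCH2",         "[CX4H2]",                    "Atom centered",
    "nAromC",       "[cX3]",                      "Atom centered",
    "nAromN",       "[nX3,nX2]",                  "Atom centered",
    "nOH",          "[OX2H]",                     "Atom centered",
    "nThioether",   "[SX2]",                      "Atom centered",
    "nHalogen",     "[F,Cl,Br,I]",                "Atom centered",
    "nCarbonyl",    "[CX3]=[OX1]",                "Atom centered",
    "nAmide",       "[NX3][CX3]=[OX1]",           "Atom centered",
    "nSulfonyl",    "[SX4](=O)(=O)",              "Atom centered",
    "nNitrile",     "[CX2]#[NX1]",                "Atom centered",
    "nBenzene",     "c1ccccc1",                   "Topological",
    "nAtomRing5",   "[r5]",                       "Topological",
    "nAtomRing6",   "[r6]",                       "Topological",
    "nAtomFused",   "[R2]",                       "Topological",
    "cntNC",        "[#7]~[#6]",                  "Bidimensional",
    "cntOC",        "[#8]~[#6]",                  "Bidimensional",
    "cntNN",        "[#7]~[#7]",                  "Bidimensional",
    "nRotB",        "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]", "Molecular properties"
  )
}

element_panel <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")

chemmine_descriptor_names <- function() {
  prop <- c("MW", "LogP", "MR", "TPSA", "HBA1", "HBA2", "HBD")
  elem <- paste0("n", element_panel)
  const <- c("nAtomHeavy", "nBond", "nBondS", "nBondD", "nBondT",
             "nRing", "nAromRing")
  fct <- c("RNH2", "R2NH", "R3N", "ROPO3", "ROH", "RCHO", "RCOR",
           "RCOOH", "RCOOR", "ROR", "RCCH", "RCN")
  c(prop, elem, const, fct, smarts_panel()$descriptor)
}

chemmine_category_map <- function() {
  prop_cat <- tibble::tibble(
    descriptor = c("MW", "LogP", "MR", "TPSA", "HBA1", "HBA2", "HBD"),
    category = c(rep("Physicochemical", 4), rep("Molecular properties", 3)))
  elem_cat <- tibble::tibble(
    descriptor = paste0("n", element_panel),
    category = "Constitutionals")
  const_cat <- tibble::tibble(
    descriptor = c("nAtomHeavy", "nBond", "nBondS", "nBondD", "nBondT",
                   "nRing", "nAromRing"),
    category = "Constitutionals")
  fct_cat <- tibble::tibble(
    descriptor = c("RNH2", "R2NH", "R3N", "ROPO3", "ROH", "RCHO", "RCOR",
                   "RCOOH", "RCOOR", "ROR", "RCCH", "RCN"),
    category = "Functional Groups")
  dplyr::bind_rows(prop_cat, elem_cat, const_cat, fct_cat,
                   dplyr::select(smarts_panel(), "descriptor", "category"))
}

chemmine_compute_one <- function(smiles) {
  nms <- chemmine_descriptor_names()
  out <- stats::setNames(rep(NA_real_, length(nms)), nms)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0) return(out)
  mol <- sdf[[1]]
  try({
    p <- ChemmineR::propOB(sdf)
    out["MW"] <- p$MW; out["LogP"] <- p$logP; out["MR"] <- p$MR
    out["TPSA"] <- p$TPSA; out["HBA1"] <- p$HBA1; out["HBA2"] <- p$HBA2
    out["HBD"] <- p$HBD
  }, silent = TRUE)
  try({
    ab <- ChemmineR::atomblock(mol)
    elems <- gsub("_.*$", "", rownames(ab))
    for (e in element_panel) out[paste0("n", e)] <- sum(elems == e)
    out["nAtomHeavy"] <- sum(elems != "H")
  }, silent = TRUE)
  try({
    bb <- ChemmineR::bondblock(mol)
    ord <- if (nrow(bb) > 0) bb[, 3] else integer(0)
    out["nBond"] <- length(ord)
    out["nBondS"] <- sum(ord == 1); out["nBondD"] <- sum(ord == 2)
    out["nBondT"] <- sum(ord == 3)
  }, silent = TRUE)
  try({
    r <- ChemmineR::rings(mol, type = "count", arom = TRUE)
    out["nRing"] <- unname(r["RINGS"]); out["nAromRing"] <- unname(r["AROMATIC"])
  }, silent = TRUE)
  try({
    g <- ChemmineR::groups(sdf, groups = "fctgroup")
    for (col in colnames(g)) if (col %in% nms) out[col] <- as.numeric(g[1, col])
  }, silent = TRUE)
  panel <- smarts_panel()
  for (i in seq_len(nrow(panel))) {
    cnt <- tryCatch(
      suppressWarnings(
        ChemmineR::smartsSearchOB(sdf, panel$smarts[i], uniqueMatches = TRUE)),
      error = function(e) NA_real_)
    out[panel$descriptor[i]] <- as.numeric(cnt[1])
  }
  out
}

.provider_registry <- new.env(parent = emptyenv())

#' Register a descriptor provider
#'
#' A provider is a function taking a character vector of standardized SMILES
#' and returning a list with `values` (tibble, one row per structure, named
#' numeric descriptor columns; `NA` for individual failures) and
#' `categories` (tibble mapping `descriptor` to a `category` from
#' [descriptor_categories()]).
#'
#' @param id Provider identifier (string).
#' @param fun Provider function.
#' @return `id`, invisibly.
#' @export
register_descriptor_provider <- function(id, fun) {
  stopifnot(is.character(id), length(id) == 1, is.function(fun))
  assign(id, fun, envir = .provider_registry)
  invisible(id)
}

#' List registered descriptor providers
#' @return Character vector of provider ids.
#' @export
descriptor_providers <- function() ls(.provider_registry)

chemmine_provider <- function(smiles) {
  rows <- purrr::map(smiles, chemmine_compute_one)
  values <- tibble::as_tibble(do.call(rbind, rows))
  list(values = values, categories = chemmine_category_map())
}

register_builtin_providers <- function() {
  register_descriptor_provider("chemmine", chemmine_provider)
}

#' Compute a molecular descriptor matrix
#'
#' Computes named numeric descriptors for each structure through a pluggable
#' provider (default: the Open Babel/ChemmineR 2D backend, covering
#' physicochemical properties, constitutional counts, functional groups,
#' atom-centered and topological fragment counts). Individual descriptor
#' failures yield `NA` cells; the computation never aborts on a single
#' structure. Output is deterministic: recomputation on identical input is
#' identical.
#'
#' @param data Data frame with id and standardized-SMILES columns, e.g. the
#'   output of [curate_activities()].
#' @param smiles_col Column holding standardized SMILES.
#' @param id_col Column holding compound ids.
#' @param provider Provider id (see [descriptor_providers()]).
#' @return Tibble `compound_id` + one column per descriptor, with the
#'   descriptor-to-category map attached as attribute `"category_map"`
#'   (see [descriptor_category_map()]).
#' @export
compute_descriptors <- function(data, smiles_col = "standard_smiles",
                                id_col = "compound_id",
                                provider = "chemmine") {
  stopifnot(is.data.frame(data), smiles_col %in% names(data),
            id_col %in% names(data))
  if (!provider %in% descriptor_providers()) {
    stop("unknown descriptor provider: ", provider)
  }
  fun <- get(provider, envir = .provider_registry)
  res <- fun(as.character(data[[smiles_col]]))
  stopifnot(!anyDuplicated(names(res$values)))
  stopifnot(all(names(res$values) %in% res$categories$descriptor))
  stopifnot(all(res$categories$category %in% descriptor_categories()$category))
  out <- dplyr::bind_cols(
    tibble::tibble(compound_id = as.character(data[[id_col]])),
    res$values)
  attr(out, "category_map") <- res$categories
  out
}

#' Category map of a descriptor matrix
#'
#' @param descriptors Result of [compute_descriptors()].
#' @return Tibble mapping `descriptor` to `category`.
#' @export
descriptor_category_map <- function(descriptors) {
  attr(descriptors, "category_map")
}

#' Write a descriptor matrix and its category map to CSV
#'
#' @param descriptors Result of [compute_descriptors()].
#' @param path Output CSV for the wide matrix.
#' @param category_path Optional sidecar CSV for the category map.
#' @return `descriptors`, invisibly.
#' @export
write_descriptors <- function(descriptors, path, category_path = NULL) {
  readr::write_csv(tibble::as_tibble(descriptors), path)
  if (!is.null(category_path)) {
    readr::write_csv(descriptor_category_map(descriptors), category_path)
  }
  invisible(descriptors)
}
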