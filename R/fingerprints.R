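# Fingerprint-class registry, the built-in SMARTS substructure-count
# backend, and Lipinski rule-of-five properties.
#
# Only the substructure / substructure-count classes have a native backend
# (the SMARTS set shipped in inst/extdata/subfp_smarts.csv). The other ten
# classes are external-only: their bit vectors are ingested from
# PaDEL-dialect CSVs via read_descriptor_csv().

#' Fingerprint class registry
#'
#' The twelve fingerprint descriptor classes used by the workflow, with
#' their advertised bit widths. Three classes are occurrence counts (the
#' "count"-suffixed ones); the rest are presence/absence bits. Only the
#' substructure pair has a built-in backend; the others are ingested from
#' external descriptor CSVs.
#'
#' Note: the advertised MACCS width (116) is internally inconsistent with
#' the classes' 16,092-bit total, which requires the conventional 166 MACCS
#' keys. The registry records the advertised value as printed and makes no
#' silent correction.
#'
#' @return A tibble with columns `name`, `n_bits`, `mode`
#'   ("binary"/"count") and `source` ("builtin"/"external").
#' @export
fingerprint_registry <- function() {
  reg <- tibble::tribble(
    ~name,                ~n_bits, ~mode,
    "CDK",                1024L,   "binary",
    "CDK extended",       1024L,   "binary",
    "CDK graph only",     1024L,   "binary",
    "E-state",            79L,     "binary",
    "MACCS",              116L,    "binary",
    "PubChem",            881L,    "binary",
    "Substructure",       307L,    "binary",
    "Substructure count", 307L,    "count",
    "Klekota-Roth",       4860L,   "binary",
    "Klekota-Roth count", 4860L,   "count",
    "2D atom pairs",      780L,    "binary",
    "2D atom pair count", 780L,    "count"
  )
  reg$source <- ifelse(reg$name %in% c("Substructure", "Substructure count"),
                       "builtin", "external")
  reg
}

#' Built-in SMARTS substructure patterns
#'
#' Loads the shipped SMARTS registry: a curated subset of the substructure
#' fingerprint dictionary covering the twenty top-ranked anti-sickling
#' substructures (conjugated double bond, aryl chloride, Michael acceptor,
#' vinylogous carbonyl family, ...). Patterns are this package's own SMARTS
#' renderings of those named functional groups, not a byte-for-byte copy of
#' any external dictionary.
#'
#' @param path Optional path to an alternative registry CSV with columns
#'   `code`, `smarts`, `description`.
#' @return Tibble with columns `code`, `smarts`, `description`.
#' @export
subfp_patterns <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "subfp_smarts.csv", package = "csarpipe")
  }
  pats <- readr::read_csv(path, col_types = "ccc", progress = FALSE)
  stopifnot(all(c("code", "smarts", "description") %in% names(pats)))
  if (anyDuplicated(pats$code)) {
    stop("duplicate pattern codes in SMARTS registry", call. = FALSE)
  }
  pats
}

#' Count SMARTS substructure matches per compound
#'
#' Cell (i, j) is the number of distinct matches (deduplicated by atom set)
#' of pattern j in molecule i. With `binarize = TRUE` the counts collapse to
#' presence/absence, i.e. the binary substructure fingerprint on the same
#' pattern set.
#'
#' @param compounds Compound tibble with parseable SMILES.
#' @param patterns Pattern tibble as from [subfp_patterns()].
#' @param binarize Return 0/1 presence instead of counts.
#' @return Descriptor tibble (first column `id`, one column per pattern
#'   code) with attributes `mode` ("count"/"binary") and
#'   `fingerprint_class`.
#' @export
compute_substructure_counts <- function(compounds, patterns = subfp_patterns(),
                                        binarize = FALSE) {
  smi <- if ("smiles_canonical" %in% names(compounds) &&
             !anyNA(compounds$smiles_canonical)) {
    compounds$smiles_canonical
  } else {
    compounds$smiles
  }
  can <- canonical_smiles(smi)
  if (anyNA(can)) {
    stop("unparseable SMILES for id(s): ",
         paste(compounds$id[is.na(can)], collapse = ", "), call. = FALSE)
  }
  sdf <- ChemmineR::smiles2sdf(stats::setNames(can, compounds$id))
  counts <- matrix(0L, nrow = nrow(compounds), ncol = nrow(patterns),
                   dimnames = list(NULL, patterns$code))
  for (j in seq_len(nrow(patterns))) {
    hits <- tryCatch(
      ChemmineR::smartsSearchOB(sdf, patterns$smarts[j], uniqueMatches = TRUE),
      error = function(e) stop("SMARTS pattern '", patterns$code[j],
                               "' failed to parse: ", conditionMessage(e),
                               call. = FALSE)
    )
    counts[, j] <- as.integer(hits)
  }
  if (binarize) counts <- (counts > 0L) + 0L
  out <- dplyr::bind_cols(tibble::tibble(id = compounds$id),
                          tibble::as_tibble(counts))
  attr(out, "mode") <- if (binarize) "binary" else "count"
  attr(out, "fingerprint_class") <-
    if (binarize) "Substructure" else "Substructure count"
  out
}

#' Lipinski rule-of-five profile
#'
#' Computes molecular weight, octanol-water partition coefficient (a
#' Ghose-Crippen-style atomic contribution logP as implemented by the
#' OpenBabel backend), hydrogen-bond donor and acceptor counts, and the
#' rule-of-five verdict: MW < 500, AlogP < 5, donors <= 5, acceptors <= 10.
#'
#' @param compounds Compound tibble with parseable SMILES.
#' @return Tibble with columns `id`, `mw`, `alogp`, `n_hbdon`, `n_hbacc`,
#'   `ro5_pass`.
#' @export
compute_lipinski <- function(compounds) {
  smi <- if ("smiles_canonical" %in% names(compounds) &&
             !anyNA(compounds$smiles_canonical)) {
    compounds$smiles_canonical
  } else {
    compounds$smiles
  }
  can <- canonical_smiles(smi)
  if (anyNA(can)) {
    stop("unparseable SMILES for id(s): ",
         paste(compounds$id[is.na(can)], collapse = ", "), call. = FALSE)
  }
  props <- with_obmols(can, function(m) {
    p <- ChemmineOB::prop_OB(m)
    c(mw = p$MW, alogp = p$logP, n_hbdon = p$HBD, n_hbacc = p$HBA1)
  })
  props <- do.call(rbind, props)
  tibble::tibble(
    id = compounds$id,
    mw = props[, "mw"],
    alogp = props[, "alogp"],
    n_hbdon = as.integer(props[, "n_hbdon"]),
    n_hbacc = as.integer(props[, "n_hbacc"]),
    ro5_pass = props[, "mw"] < 500 & props[, "alogp"] < 5 &
      props[, "n_hbdon"] <= 5 & props[, "n_hbacc"] <= 10
  )
}
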