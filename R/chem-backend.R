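# OpenBabel-backed chemistry primitives shared by the I/O and fingerprint
# layers. All SMILES handling in the package funnels through these two
# helpers so that canonical forms are comparable everywhere.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES. Unparseable strings yield
#' `NA` rather than an error, so callers can collect rejects.
#'
#' @param smiles Character vector of SMILES strings.
#' @param standardize If `TRUE`, apply the package's standardization recipe
#'   before canonicalization: keep only the largest fragment (stripping
#'   salts/solvents) and neutralize charges where a neutral form exists.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "CCO"))  # both "CCO"
canonical_smiles <- function(smiles, standardize = FALSE) {
  stopifnot(is.character(smiles))
  # "r" keeps the largest contiguous fragment; "neutralize" removes formal
  # charges where a neutral form exists
  opts <- if (standardize) {
    data.frame(names = c("r", "neutralize"), args = c("", ""))
  } else {
    data.frame(names = character(0), args = character(0))
  }
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = s, options = opts),
      error = function(e) ""
    )
    out <- sub("[\t\n ].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Apply `fn(obmol)` to each molecule of a SMILES vector, one result per
# molecule. Parsing each molecule separately keeps a single bad SMILES from
# poisoning the batch; callers screen parseability beforehand.
with_obmols <- function(smiles, fn) {
  lapply(smiles, function(s) {
    res <- ChemmineOB::forEachMol("SMILES", s, identity)
    fn(res)
  })
}
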