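# Compound and descriptor table I/O.
#
# A compound table is an ordinary tibble with (at least) the columns
#   id, smiles, smiles_canonical, solubility_ratio, label, chemotype
# where `label` is "active"/"inactive" or NA. Row order is meaningful
# (first occurrence wins on deduplication) and is preserved by every verb.

compound_label_levels <- c("active", "inactive")

#' Read a compound CSV
#'
#' Reads a comma-separated compound table (UTF-8, header row mandatory) and
#' canonicalizes each SMILES on ingest. Rows whose SMILES cannot be parsed
#' are reported in the `rejects` attribute -- never silently dropped.
#'
#' @param path Path to a CSV file.
#' @param dialect Named character vector mapping the canonical column roles
#'   (`id`, `smiles`, `solubility_ratio`, `label`, `chemotype`) to the
#'   column names used in the file. Only `id` and `smiles` are mandatory.
#' @return A tibble of compounds (one row per parseable input row) with a
#'   `rejects` attribute: a tibble of the rejected rows and reasons.
#' @export
read_compound_csv <- function(path,
                              dialect = c(id = "id", smiles = "smiles",
                                          solubility_ratio = "solubility_ratio",
                                          label = "label",
                                          chemotype = "chemotype")) {
  if (!file.exists(path)) {
    stop("compound file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (role in c("id", "smiles")) {
    if (!dialect[[role]] %in% names(raw)) {
      stop("mandatory column '", dialect[[role]], "' (role: ", role,
           ") missing from ", path, call. = FALSE)
    }
  }
  df <- tibble::tibble(
    id = as.character(raw[[dialect[["id"]]]]),
    smiles = as.character(raw[[dialect[["smiles"]]]])
  )
  opt <- function(role, default) {
    nm <- dialect[role]
    if (!is.na(nm) && nm %in% names(raw)) raw[[nm]] else default
  }
  df$solubility_ratio <- as.numeric(opt("solubility_ratio", NA_real_))
  df$label <- as.character(opt("label", NA_character_))
  df$chemotype <- as.character(opt("chemotype", NA_character_))

  df$smiles_canonical <- canonical_smiles(df$smiles)
  bad <- is.na(df$smiles_canonical)
  rejects <- dplyr::mutate(df[bad, c("id", "smiles")],
                           reason = "unparseable SMILES")
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected (unparseable SMILES); see attr(., 'rejects')",
            call. = FALSE)
  }
  out <- df[!bad, c("id", "smiles", "smiles_canonical", "solubility_ratio",
                    "label", "chemotype")]
  if (anyDuplicated(out$id)) {
    stop("duplicate compound ids in ", path, ": ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "),
         call. = FALSE)
  }
  attr(out, "rejects") <- rejects
  out
}

#' Standardize and deduplicate a compound table
#'
#' Applies the standardization recipe (largest fragment, charge
#' neutralization, canonical SMILES) and collapses records that share a
#' standardized canonical SMILES. The first occurrence is kept; the merge
#' log mapping dropped ids to kept ids is attached as the `merge_log`
#' attribute. Duplicates whose activity conflicts under `rule` (one active,
#' one inactive -- an activity-cliff duplicate) are a hard error.
#'
#' @param compounds Compound tibble (see [read_compound_csv()]).
#' @param rule Label rule used to detect label conflicts among duplicates;
#'   see [label_rule()].
#' @return Deduplicated compound tibble with a `merge_log` attribute
#'   (tibble with columns `dropped_id`, `kept_id`).
#' @export
standardize_compounds <- function(compounds, rule = label_rule()) {
  std <- canonical_smiles(compounds$smiles, standardize = TRUE)
  if (anyNA(std)) {
    stop("unparseable SMILES for id(s): ",
         paste(compounds$id[is.na(std)], collapse = ", "), call. = FALSE)
  }
  compounds$smiles_canonical <- std

  # label used only for conflict detection: explicit label if present,
  # otherwise derived from the ratio under `rule`
  eff_label <- compounds$label
  derivable <- is.na(eff_label) & !is.na(compounds$solubility_ratio)
  eff_label[derivable] <-
    classify_ratio(compounds$solubility_ratio[derivable], rule)

  keep_idx <- !duplicated(std)
  first_of <- match(std, std[keep_idx])
  log <- tibble::tibble(
    dropped_id = compounds$id[!keep_idx],
    kept_id = compounds$id[keep_idx][first_of[!keep_idx]]
  )
  for (i in which(!keep_idx)) {
    j <- which(keep_idx)[first_of[i]]
    li <- eff_label[i]; lj <- eff_label[j]
    if (!is.na(li) && !is.na(lj) && li != lj) {
      stop("activity-cliff duplicate: '", compounds$id[j], "' (", lj,
           ") and '", compounds$id[i], "' (", li,
           ") standardize to the same structure", call. = FALSE)
    }
  }
  out <- compounds[keep_idx, ]
  attr(out, "merge_log") <- log
  out
}

#' Construct a solubility-ratio labeling rule
#'
#' Compounds are labeled from their HbS solubility ratio (with-drug over
#' drug-free control): ratios at or above the threshold are active. The
#' default threshold of 1.06 is the level reported as clinically relevant
#' for reduced sickling severity.
#'
#' @param threshold Positive ratio threshold (default 1.06).
#' @param active_if_geq If `TRUE` (default) a ratio exactly equal to the
#'   threshold is labeled active; if `FALSE`, strictly greater is required.
#' @return A `csar_label_rule` object.
#' @export
label_rule <- function(threshold = 1.06, active_if_geq = TRUE) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  structure(list(threshold = threshold, active_if_geq = isTRUE(active_if_geq)),
            class = "csar_label_rule")
}

classify_ratio <- function(ratio, rule) {
  hit <- if (rule$active_if_geq) ratio >= rule$threshold else ratio > rule$threshold
  ifelse(hit, "active", "inactive")
}

#' Label compounds by solubility ratio
#'
#' Deterministically assigns `label` from `solubility_ratio` under `rule`.
#' Idempotent: re-applying the same rule never changes a label.
#'
#' @param compounds Compound tibble; every row must have a solubility ratio.
#' @param rule A [label_rule()].
#' @return The tibble with `label` filled in and a `counts` attribute
#'   (named integer vector: n_active, n_inactive, n_total).
#' @export
apply_label_rule <- function(compounds, rule = label_rule()) {
  miss <- is.na(compounds$solubility_ratio)
  if (any(miss)) {
    stop("missing solubility_ratio for id(s): ",
         paste(compounds$id[miss], collapse = ", "), call. = FALSE)
  }
  compounds$label <- classify_ratio(compounds$solubility_ratio, rule)
  attr(compounds, "counts") <- c(
    n_active = sum(compounds$label == "active"),
    n_inactive = sum(compounds$label == "inactive"),
    n_total = nrow(compounds)
  )
  compounds
}

#' Read a descriptor CSV (PaDEL dialect)
#'
#' First column holds compound names; every remaining column must be fully
#' numeric. Non-numeric cells are an error naming the offending row/column;
#' duplicated compound names are an error. Column order is preserved.
#'
#' @param path Path to a CSV file.
#' @return A tibble whose first column is `id` and whose remaining columns
#'   are numeric descriptors.
#' @export
read_descriptor_csv <- function(path) {
  if (!file.exists(path)) stop("descriptor file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(readr::problems(raw)) > 0) {
    stop("malformed (ragged?) descriptor CSV: ", path, call. = FALSE)
  }
  if (ncol(raw) < 2) stop("descriptor CSV needs a name column plus data: ", path,
                          call. = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate compound names in descriptor CSV: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vals <- raw[-1]
  for (j in seq_along(vals)) {
    conv <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(conv) & !is.na(vals[[j]]) | is.na(vals[[j]]))
    if (length(bad) > 0) {
      stop("non-numeric cell in descriptor CSV at row ", bad[1],
           ", column '", names(vals)[j], "'", call. = FALSE)
    }
    vals[[j]] <- conv
  }
  dplyr::bind_cols(tibble::tibble(id = ids), vals)
}

#' Write a descriptor table as PaDEL-dialect CSV
#'
#' Inverse of [read_descriptor_csv()]: first column `Name`, remaining
#' columns numeric. Round-trips integer counts bit-exactly and reals to
#' full double precision.
#'
#' @param descriptors Descriptor tibble (first column `id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(descriptors, path) {
  out <- descriptors
  names(out)[1] <- "Name"
  readr::write_csv(out, path)
  invisible(path)
}

# ids + labels of a compound tibble as a plain named character vector
compound_labels <- function(compounds) {
  stats::setNames(compounds$label, compounds$id)
}
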