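# Descriptor filtering, class balancing, stratified splitting, resampling
# plans and cross-validation fold construction.

#' Drop near-constant descriptor columns
#'
#' Keeps exactly the columns whose sample standard deviation (n-1
#' denominator) is strictly greater than `sd_cutoff`; column order is
#' preserved. Dropped column names are attached as the `dropped` attribute.
#'
#' @param descriptors Descriptor tibble (first column `id`).
#' @param sd_cutoff Non-negative SD cutoff; default 0.1.
#' @return Filtered descriptor tibble.
#' @export
filter_near_constant <- function(descriptors, sd_cutoff = 0.1) {
  stopifnot(sd_cutoff >= 0, nrow(descriptors) > 0)
  vals <- descriptors[-1]
  sds <- vapply(vals, stats::sd, numeric(1))
  keep <- sds > sd_cutoff
  if (!any(keep)) {
    warning("all descriptor columns dropped by SD filter", call. = FALSE)
  }
  out <- dplyr::bind_cols(descriptors[1], vals[, keep, drop = FALSE])
  attr(out, "dropped") <- names(vals)[!keep]
  attr(out, "mode") <- attr(descriptors, "mode")
  attr(out, "fingerprint_class") <- attr(descriptors, "fingerprint_class")
  out
}

#' Balance classes by random undersampling
#'
#' Randomly selects (without replacement) a majority-class subset of the
#' minority-class size; all minority records are retained. Original row
#' order is preserved. Reproducible from `seed`.
#'
#' @param compounds Labeled compound tibble.
#' @param seed Integer seed for the selection.
#' @return Balanced compound tibble.
#' @export
undersample_random <- function(compounds, seed) {
  tab <- table(factor(compounds$label, levels = compound_label_levels))
  if (any(tab == 0)) stop("both classes must be present", call. = FALSE)
  if (tab[1] == tab[2]) {
    message("classes already balanced; returning input unchanged")
    return(compounds)
  }
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(compound_label_levels, minority)
  maj_idx <- which(compounds$label == majority)
  pick <- withr::with_seed(seed, sample(maj_idx, min(tab)))
  keep <- sort(c(which(compounds$label == minority), pick))
  compounds[keep, ]
}

#' Kennard-Stone representative subset
#'
#' Classic max-min selection on Euclidean distances: the first two picks
#' realize the maximum pairwise distance; each subsequent pick maximizes
#' its minimum distance to the already-selected set. Ties are broken by
#' lowest row index, making the procedure fully deterministic.
#'
#' @param x Numeric matrix (rows = candidates).
#' @param k Number of rows to select, `2 <= k <= nrow(x)`.
#' @return Integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(k >= 1, k <= n)
  if (n < 2) return(seq_len(n))
  d <- as.matrix(stats::dist(x))
  # farthest pair, lexicographically smallest on ties
  best <- c(1L, 2L); bestd <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > bestd) { bestd <- d[i, j]; best <- c(i, j) }
    }
  }
  if (k == 1) return(best[1])
  sel <- best
  mind <- pmin(d[, sel[1]], d[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < k) {
    nxt <- unname(which.max(mind))  # first (lowest index) wins on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
    mind[nxt] <- -Inf
  }
  unname(sel)
}

#' Balance classes by Kennard-Stone undersampling
#'
#' Selects the `k` most space-spanning majority-class compounds in
#' descriptor space via [kennard_stone()]; all minority records are kept.
#'
#' @param compounds Labeled compound tibble.
#' @param descriptors Descriptor tibble covering at least the majority
#'   class ids.
#' @param k Majority subset size; defaults to the minority class size.
#' @return Balanced compound tibble (original row order).
#' @export
undersample_kennard_stone <- function(compounds, descriptors, k = NULL) {
  tab <- table(factor(compounds$label, levels = compound_label_levels))
  if (any(tab == 0)) stop("both classes must be present", call. = FALSE)
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(compound_label_levels, minority)
  if (is.null(k)) k <- as.integer(min(tab))
  maj_ids <- compounds$id[compounds$label == majority]
  if (k > length(maj_ids)) {
    stop("k (", k, ") exceeds majority class size (", length(maj_ids), ")",
         call. = FALSE)
  }
  rows <- match(maj_ids, descriptors$id)
  if (anyNA(rows)) stop("descriptor rows missing for majority class ids",
                        call. = FALSE)
  sel <- kennard_stone(as.matrix(descriptors[rows, -1]), k)
  keep_ids <- c(compounds$id[compounds$label == minority], maj_ids[sel])
  compounds[compounds$id %in% keep_ids, ]
}

#' Stratified internal/external split
#'
#' Splits a balanced compound set into internal (training) and external
#' (held-out) subsets, stratified by class. The per-class internal count is
#' `round(ratio * n_class)`. The default ratio of 0.75 reproduces the
#' study-design cardinalities for the 64-compound balanced set: 48 internal
#' (24 per class) and 16 external (8 per class).
#'
#' @param compounds Balanced, labeled compound tibble.
#' @param ratio Internal fraction per class (default 0.75).
#' @param seed Integer seed.
#' @return A `csar_split` object: list with `internal_ids`, `external_ids`,
#'   `seed`, `ratio`.
#' @export
split_internal_external <- function(compounds, ratio = 0.75, seed) {
  stopifnot(ratio > 0, ratio <= 1)
  classes <- split(compounds$id, compounds$label)
  internal <- character(0)
  withr::with_seed(seed, {
    for (cl in names(classes)) {
      ids <- classes[[cl]]
      n_int <- round(ratio * length(ids))
      if (n_int < 1) stop("class '", cl, "' too small for stratified split",
                          call. = FALSE)
      internal <- c(internal, sample(ids, n_int))
    }
  })
  external <- setdiff(compounds$id, internal)
  if (length(external) == 0) {
    warning("external set is empty", call. = FALSE)
  }
  structure(list(internal_ids = compounds$id[compounds$id %in% internal],
                 external_ids = compounds$id[compounds$id %in% external],
                 seed = seed, ratio = ratio),
            class = "csar_split")
}

#' Resampling plan: repeated stratified splits
#'
#' Generates `n_iter` independent internal/external splits, each with its
#' own derived seed, emulating repeated reshuffle-and-restratify rounds.
#'
#' @param compounds Balanced, labeled compound tibble.
#' @param n_iter Number of iterations (default 100).
#' @param seed Master seed; per-iteration seeds are derived from it.
#' @param ratio Passed to [split_internal_external()].
#' @return List of `csar_split` objects with an `iteration` element each.
#' @export
make_resampling_plan <- function(compounds, n_iter = 100, seed, ratio = 0.75) {
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_iter))
  purrr::imap(as.list(sub_seeds), function(s, i) {
    plan <- split_internal_external(compounds, ratio = ratio, seed = s)
    plan$iteration <- i
    plan
  })
}

#' Stratified k-fold cross-validation scheme
#'
#' Builds `repeats` independent stratified partitions of the internal set
#' into `k` folds. Within each repeat, fold sizes are as equal as possible
#' overall and per class (to +/-1): leftover compounds are assigned to the
#' currently smallest folds.
#'
#' @param internal_ids Character vector of internal-set ids.
#' @param labels Named character vector of labels for those ids.
#' @param k Folds per repeat (default 5).
#' @param repeats Number of reshuffled repeats (default 3).
#' @param seed Integer seed.
#' @return A `csar_cv` object: list with `k`, `repeats`, `folds` (a tibble
#'   with columns `id`, `repeat_`, `fold`).
#' @export
make_cv_scheme <- function(internal_ids, labels, k = 5, repeats = 3, seed) {
  n <- length(internal_ids)
  if (k > n) stop("k (", k, ") exceeds number of ids (", n, ")", call. = FALSE)
  labels <- labels[internal_ids]
  assign_repeat <- function() {
    fold_of <- stats::setNames(integer(n), internal_ids)
    fold_sizes <- integer(k)
    for (cl in unique(labels)) {
      ids <- sample(internal_ids[labels == cl])
      base <- length(ids) %/% k
      extra <- length(ids) %% k
      # folds currently smallest get the leftovers (ties -> lowest index)
      fills <- rep(base, k)
      if (extra > 0) {
        ord <- order(fold_sizes, seq_len(k))[seq_len(extra)]
        fills[ord] <- fills[ord] + 1L
      }
      at <- 1L
      for (f in seq_len(k)) {
        if (fills[f] > 0) {
          fold_of[ids[at:(at + fills[f] - 1L)]] <- f
          at <- at + fills[f]
        }
      }
      fold_sizes <- fold_sizes + fills
    }
    fold_of
  }
  folds <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(repeats), function(r) {
      fo <- assign_repeat()
      tibble::tibble(id = names(fo), repeat_ = r, fold = unname(fo))
    })
  })
  structure(list(k = k, repeats = repeats, seed = seed, folds = folds),
            class = "csar_cv")
}

#' Serialize a split plan or CV scheme to JSON
#'
#' @param x A `csar_split`, list of them, or `csar_cv` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
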