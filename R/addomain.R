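# Applicability domain via a PCA bounding box: autoscale the training
# descriptors, project onto the leading principal components, and declare
# the axis-aligned [min, max] box of the training scores to be the domain.

#' Fit a PCA bounding-box applicability domain
#'
#' Columns are autoscaled (mean 0, SD 1; constant columns dropped), PCA is
#' fitted on the training block only, and the per-component [min, max]
#' bounds of the training scores define the box. Every training point lies
#' inside its own box by construction.
#'
#' @param train_descriptors Descriptor tibble (first column `id`) of the
#'   training compounds.
#' @param n_pc Number of leading components defining the box (default 2).
#' @return A `csar_ad` object: list with `center`, `scale`, `rotation`,
#'   `bounds` (n_pc x 2), `n_pc`, `columns`, and the training `scores`.
#' @export
fit_ad <- function(train_descriptors, n_pc = 2) {
  x <- as.matrix(train_descriptors[-1])
  if (nrow(x) < 2) stop("need at least two training compounds", call. = FALSE)
  keep <- apply(x, 2, stats::sd) > 0
  x <- x[, keep, drop = FALSE]
  if (ncol(x) < n_pc) {
    stop("fewer non-degenerate dimensions (", ncol(x), ") than n_pc (", n_pc,
         ")", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  bounds <- cbind(min = apply(scores, 2, min), max = apply(scores, 2, max))
  structure(list(center = pc$center, scale = pc$scale,
                 rotation = pc$rotation[, seq_len(n_pc), drop = FALSE],
                 bounds = bounds, n_pc = n_pc, columns = colnames(x),
                 scores = tibble::tibble(id = train_descriptors$id,
                                         tibble::as_tibble(scores))),
            class = "csar_ad")
}

#' Check compounds against a fitted applicability domain
#'
#' Projects query compounds into the training PC space; a compound is
#' inside the domain iff every component score lies within the training
#' [min, max] bounds (inclusive).
#'
#' @param model A `csar_ad` object from [fit_ad()].
#' @param query_descriptors Descriptor tibble whose columns cover the
#'   training columns.
#' @return Tibble with `id`, the PC scores, and logical `inside`.
#' @export
check_ad <- function(model, query_descriptors) {
  missing_cols <- setdiff(model$columns, names(query_descriptors))
  if (length(missing_cols) > 0) {
    stop("query descriptors missing training column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(query_descriptors[model$columns])
  scores <- scale(x, center = model$center, scale = model$scale) %*%
    model$rotation
  inside <- rep(TRUE, nrow(scores))
  for (j in seq_len(model$n_pc)) {
    inside <- inside & scores[, j] >= model$bounds[j, "min"] &
      scores[, j] <= model$bounds[j, "max"]
  }
  dplyr::bind_cols(tibble::tibble(id = query_descriptors$id),
                   tibble::as_tibble(scores),
                   tibble::tibble(inside = inside))
}

#' @export
print.csar_ad <- function(x, ...) {
  cat(sprintf("PCA bounding-box applicability domain: %d PCs over %d columns\n",
              x$n_pc, length(x$columns)))
  print(x$bounds)
  invisible(x)
}

#' @rdname fit_ad
#' @param x A `csar_ad` object.
#' @param ... Unused.
#' @method tidy csar_ad
#' @export
tidy.csar_ad <- function(x, ...) x$scores

#' Scores plot with the applicability-domain box
#'
#' Training scores (and optionally query scores) on the first two
#' components, with the bounding box overlaid.
#'
#' @param object A `csar_ad` object.
#' @param query Optional result of [check_ad()] to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot csar_ad
#' @export
autoplot.csar_ad <- function(object, query = NULL, ...) {
  b <- object$bounds
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::annotate("rect", xmin = b[1, "min"], xmax = b[1, "max"],
                      ymin = b[2, "min"], ymax = b[2, "max"],
                      alpha = 0.08, fill = "steelblue", color = "steelblue") +
    ggplot2::geom_point(color = "grey30") +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
  if (!is.null(query)) {
    p <- p + ggplot2::geom_point(data = query,
                                 ggplot2::aes(color = .data$inside))
  }
  p
}
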