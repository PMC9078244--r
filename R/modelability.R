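# Dataset modelability: MODI, the class-averaged fraction of compounds
# whose first nearest neighbor in descriptor space shares their class.
# A binary dataset with MODI > 0.65 is considered modelable; activity-cliff
# pairs (near neighbors with opposite classes) depress the index.

#' Pairwise Euclidean distances between descriptor rows
#'
#' @param descriptors Descriptor tibble (first column `id`) with no
#'   missing values.
#' @param normalize If `TRUE`, divide all distances by the mean
#'   off-diagonal distance. MODI is invariant to any such scalar
#'   normalization (a strictly monotone rescale preserves nearest
#'   neighbors), so this only matters for reporting distances themselves.
#' @return Symmetric distance matrix with ids as dimnames and a
#'   `normalized` attribute.
#' @export
euclidean_distances <- function(descriptors, normalize = FALSE) {
  x <- as.matrix(descriptors[-1])
  if (anyNA(x)) stop("descriptor matrix contains missing values", call. = FALSE)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(descriptors$id, descriptors$id)
  if (nrow(d) == 1) warning("single compound: 1x1 zero distance matrix",
                            call. = FALSE)
  if (normalize && nrow(d) > 1) {
    dbar <- mean(d[upper.tri(d)])
    if (dbar > 0) d <- d / dbar
  }
  attr(d, "normalized") <- normalize
  d
}

#' First nearest neighbor of each compound
#'
#' For every id, the distinct id minimizing the distance; ties at equal
#' distance are broken by lowest row index.
#'
#' @param d Distance matrix as from [euclidean_distances()].
#' @return Named character vector mapping each id to its neighbor's id.
#' @export
first_nearest_neighbor <- function(d) {
  n <- nrow(d)
  if (n < 2) stop("need at least two compounds", call. = FALSE)
  ids <- rownames(d)
  nn <- vapply(seq_len(n), function(i) {
    row <- d[i, ]
    row[i] <- Inf
    ids[which.min(row)]
  }, character(1))
  stats::setNames(nn, ids)
}

#' MODI: dataset modelability index
#'
#' For each class, the fraction of its compounds whose first nearest
#' neighbor (Euclidean distance in descriptor space) belongs to the same
#' class; MODI is the unweighted mean of those fractions over classes.
#' Datasets with MODI above the threshold (default 0.65) are flagged
#' modelable.
#'
#' @param descriptors Descriptor tibble (first column `id`).
#' @param labels Named character vector (or factor) of class labels,
#'   indexed by id; every class needs at least two members for its
#'   fraction to be meaningful.
#' @param threshold Modelability threshold (default 0.65).
#' @return A `csar_modi` object: list with `modi`, `threshold`,
#'   `modelable` and the per-class concordance tibble `per_class`
#'   (columns `label`, `n_same`, `n_total`).
#' @export
modi <- function(descriptors, labels, threshold = 0.65) {
  labels <- labels[descriptors$id]
  if (anyNA(labels)) stop("labels missing for some descriptor ids", call. = FALSE)
  tab <- table(labels)
  if (any(tab < 1) || length(tab) < 2) {
    stop("every class needs at least one member and >= 2 classes", call. = FALSE)
  }
  d <- euclidean_distances(descriptors)
  nn <- first_nearest_neighbor(d)
  same <- labels[names(nn)] == labels[nn]
  per_class <- tibble::tibble(
    label = names(tab),
    n_same = vapply(names(tab), function(cl) sum(same[labels == cl]), integer(1)),
    n_total = as.integer(tab)
  )
  m <- mean(per_class$n_same / per_class$n_total)
  structure(list(modi = m, threshold = threshold, modelable = m > threshold,
                 per_class = per_class),
            class = "csar_modi")
}

#' @export
print.csar_modi <- function(x, ...) {
  cat(sprintf("MODI = %.4f (threshold %.2f): %s\n", x$modi, x$threshold,
              if (x$modelable) "modelable" else "NOT modelable"))
  print(x$per_class)
  invisible(x)
}

#' @rdname modi
#' @param x A `csar_modi` object.
#' @param ... Unused.
#' @method tidy csar_modi
#' @export
tidy.csar_modi <- function(x, ...) {
  dplyr::mutate(x$per_class, concordance = n_same / n_total)
}

#' @rdname modi
#' @method glance csar_modi
#' @export
glance.csar_modi <- function(x, ...) {
  tibble::tibble(modi = x$modi, threshold = x$threshold,
                 modelable = x$modelable,
                 n_classes = nrow(x$per_class))
}
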