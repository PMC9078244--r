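# Descriptor importance: mean decrease of the Gini index (MDGI) aggregated
# over an ensemble of random forests that vary the feature-subsampling
# parameter m_try, so the ranking is not hostage to a single m_try choice.

#' MDGI importance over an m_try ensemble
#'
#' Fits one random forest per `m_try` value (tree count fixed, default
#' 100), extracts each model's mean decrease of the Gini index, averages
#' across the ensemble, and ranks descriptors by the ensemble mean
#' (rank 1 = largest; ties broken by descriptor code, lexicographically).
#'
#' @param descriptors Filtered descriptor tibble (first column `id`).
#' @param compounds Labeled compound tibble.
#' @param mtry_values Ensemble of m_try values; defaults to the eleven
#'   values `{2,3,5,7,9,11,13,15,17,19,20}`. Values exceeding the feature
#'   count are skipped with a warning.
#' @param n_tree Trees per model (default 100).
#' @param seed Integer seed; the table is bit-reproducible given it.
#' @return A `csar_importance` tibble: columns `descriptor`, `mean_mdgi`,
#'   `rank`, plus a `per_model` attribute (descriptor x m_try MDGI matrix).
#' @export
mdgi_ensemble <- function(descriptors, compounds,
                          mtry_values = c(2, 3, 5, 7, 9, 11, 13, 15, 17, 19, 20),
                          n_tree = 100, seed = 1) {
  x <- rf_matrix(descriptors, compounds$id)
  y <- label_factor(compounds$label)
  p <- ncol(x)
  usable <- mtry_values[mtry_values <= p]
  if (length(usable) < length(mtry_values)) {
    warning("skipping m_try value(s) > ", p, " features: ",
            paste(setdiff(mtry_values, usable), collapse = ", "),
            call. = FALSE)
  }
  per_model <- vapply(usable, function(m) {
    fit <- withr::with_seed(seed + m, randomForest::randomForest(
      x = x, y = y, ntree = n_tree, mtry = m, importance = FALSE))
    fit$importance[, "MeanDecreaseGini"]
  }, numeric(p))
  colnames(per_model) <- paste0("mtry_", usable)
  mean_mdgi <- rowMeans(per_model)
  ord <- order(-mean_mdgi, names(mean_mdgi))
  out <- tibble::tibble(
    descriptor = names(mean_mdgi)[ord],
    mean_mdgi = unname(mean_mdgi[ord]),
    rank = seq_along(ord)
  )
  attr(out, "per_model") <- per_model[ord, , drop = FALSE]
  class(out) <- c("csar_importance", class(out))
  out
}

#' Top-k slice of an importance table
#'
#' @param tbl A `csar_importance` tibble.
#' @param k Number of top-ranked descriptors (default 20).
#' @param patterns Optional pattern tibble ([subfp_patterns()]); when
#'   given, descriptions are joined in by descriptor code.
#' @return The first `k` rows by rank (with `description` if joined).
#' @export
top_k <- function(tbl, k = 20, patterns = NULL) {
  if (k > nrow(tbl)) stop("k (", k, ") exceeds table size (", nrow(tbl), ")",
                          call. = FALSE)
  out <- tbl[order(tbl$rank)[seq_len(k)], ]
  if (!is.null(patterns)) {
    out <- dplyr::left_join(out,
                            dplyr::select(patterns, descriptor = "code",
                                          "description"),
                            by = "descriptor")
  }
  out
}

#' Bar chart of top descriptor importances
#'
#' @param importance A `csar_importance` tibble.
#' @param k Number of descriptors to display.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, k = min(20, nrow(importance))) {
  top <- top_k(importance, k)
  ggplot2::ggplot(top, ggplot2::aes(
    x = .data$mean_mdgi,
    y = stats::reorder(.data$descriptor, .data$mean_mdgi))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean decrease of Gini index (ensemble mean)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
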