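# Class-comparison statistics for descriptors and Lipinski properties:
# six-number summaries, a normality gate, and two-sample tests with the
# conventional star annotation.

#' Six-number summary
#'
#' Minimum, first quartile, median, mean, third quartile and maximum.
#' Quartiles use linear interpolation (quantile type 7).
#'
#' @param values Non-empty numeric vector.
#' @return One-row tibble: `min`, `q1`, `median`, `mean`, `q3`, `max`.
#' @export
six_number_summary <- function(values) {
  if (length(values) == 0) stop("empty vector", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(min = min(values), q1 = q[1], median = q[2],
                 mean = mean(values), q3 = q[3], max = max(values))
}

stars_for <- function(p) {
  dplyr::case_when(p <= 1e-4 ~ "***", p <= 1e-3 ~ "**", p <= 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Compare a feature between activity classes
#'
#' Gates on normality per class (Kolmogorov-Smirnov against a normal with
#' the sample mean and SD -- the classic usage, with its Lilliefors caveat);
#' if both classes pass at `alpha_normality` a two-sample t-test is used,
#' otherwise the two-sided Mann-Whitney U test (normal approximation with
#' tie correction). Significance stars: `*` p <= 0.05, `**` p <= 0.001,
#' `***` p <= 0.0001 (most extreme applicable).
#'
#' @param values_active,values_inactive Numeric vectors, length >= 3 each.
#' @param alpha_normality Normality-gate level (default 0.05).
#' @param feature Optional feature name carried into the result.
#' @param test `"auto"` (default) applies the normality gate;
#'   `"mann_whitney_u"` or `"t_test"` forces that test.
#' @return One-row tibble: `feature`, `test` ("mann_whitney_u"/"t_test"),
#'   `p_value`, `stars`, `degenerate` flag, and per-class summaries in the
#'   list-column `summaries`.
#' @export
compare_classes <- function(values_active, values_inactive,
                            alpha_normality = 0.05, feature = NA_character_,
                            test = c("auto", "mann_whitney_u", "t_test")) {
  test <- match.arg(test)
  stopifnot(length(values_active) >= 3, length(values_inactive) >= 3)
  norm_p <- function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate: certainly not normal
    suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value)
  }
  if (test == "auto") {
    both_normal <- norm_p(values_active) > alpha_normality &&
      norm_p(values_inactive) > alpha_normality
    test <- if (both_normal) "t_test" else "mann_whitney_u"
  }
  degenerate <- length(unique(c(values_active, values_inactive))) == 1
  if (degenerate) {
    test <- "mann_whitney_u"; p <- 1
  } else if (test == "t_test") {
    p <- stats::t.test(values_active, values_inactive)$p.value
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(values_active, values_inactive,
                         exact = FALSE, correct = TRUE)$p.value)
  }
  tibble::tibble(
    feature = feature, test = test, p_value = p, stars = stars_for(p),
    degenerate = degenerate,
    summaries = list(dplyr::bind_rows(
      dplyr::mutate(six_number_summary(values_active), label = "active"),
      dplyr::mutate(six_number_summary(values_inactive), label = "inactive")
    ))
  )
}

#' Class comparison across all descriptor columns
#'
#' Maps [compare_classes()] over every descriptor column, returning one
#' tidy row per feature. No multiple-testing correction is applied (each
#' feature is reported at its nominal p), by design.
#'
#' @param descriptors Descriptor tibble (first column `id`).
#' @param compounds Labeled compound tibble.
#' @param alpha_normality Normality-gate level.
#' @return Tibble of per-feature test results.
#' @export
compare_features <- function(descriptors, compounds, alpha_normality = 0.05) {
  labels <- compound_labels(compounds)[descriptors$id]
  purrr::map_dfr(names(descriptors)[-1], function(f) {
    v <- descriptors[[f]]
    compare_classes(v[labels == "active"], v[labels == "inactive"],
                    alpha_normality = alpha_normality, feature = f)
  })
}

#' Per-class box plots with significance stars
#'
#' @param descriptors Descriptor tibble.
#' @param compounds Labeled compound tibble.
#' @param features Character vector of descriptor columns to plot.
#' @param alpha_normality Passed to [compare_features()].
#' @return A ggplot object (one facet per feature, star annotation above).
#' @export
plot_class_boxes <- function(descriptors, compounds, features,
                             alpha_normality = 0.05) {
  stopifnot(all(features %in% names(descriptors)))
  labels <- compound_labels(compounds)[descriptors$id]
  long <- descriptors |>
    dplyr::select(dplyr::all_of(c("id", features))) |>
    dplyr::mutate(label = labels) |>
    tidyr::pivot_longer(dplyr::all_of(features),
                        names_to = "feature", values_to = "value")
  res <- compare_features(descriptors[c("id", features)], compounds,
                          alpha_normality)
  ann <- long |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(y = max(.data$value), .groups = "drop") |>
    dplyr::left_join(dplyr::select(res, "feature", "stars"), by = "feature")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                     fill = .data$label)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::geom_text(data = ann, inherit.aes = FALSE,
                       ggplot2::aes(x = 1.5, y = .data$y, label = .data$stars),
                       vjust = -0.4) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "descriptor value") +
    ggplot2::theme_minimal()
}
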