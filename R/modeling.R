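# Random-forest CSAR models: tuning, confusion-matrix metrics, ROC/AUC and
# the full resampled evaluation protocol (train / repeated CV / external /
# decoy contexts).

rf_matrix <- function(descriptors, ids) {
  rows <- match(ids, descriptors$id)
  if (anyNA(rows)) stop("descriptor rows missing for some ids", call. = FALSE)
  x <- as.matrix(descriptors[rows, -1])
  rownames(x) <- ids
  x
}

label_factor <- function(labels) {
  factor(labels, levels = compound_label_levels)
}

fit_rf <- function(x, y, n_tree, m_try, seed) {
  withr::with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = n_tree, mtry = m_try, importance = FALSE))
}

oob_error <- function(x, y, n_tree, m_try, seed) {
  fit <- fit_rf(x, y, n_tree, m_try, seed)
  mean(fit$predicted != y)
}

#' Tune and train a random-forest CSAR model
#'
#' Two-step tuning mirroring the study protocol: the tree count is chosen
#' by stratified 10-fold cross-validated accuracy over the grid
#' `n_tree in {100, 200, ..., 1000}` (smallest value within one SD of the
#' best mean accuracy); the feature-subsampling size `m_try` is then chosen
#' by a stepwise out-of-bag search equivalent to the classic tuneRF
#' procedure: start at `floor(sqrt(p))`, step by a factor of 2 in both
#' directions, stop when the relative OOB improvement falls below 5%.
#'
#' @param descriptors Descriptor tibble (first column `id`).
#' @param compounds Labeled compound tibble (training rows).
#' @param n_tree_grid Candidate tree counts.
#' @param tuning_cv_folds Folds for the n_tree tuning CV (default 10).
#' @param step_factor,improve tuneRF-equivalent m_try search parameters.
#' @param seed Integer seed; the whole selection is deterministic given it.
#' @return A `csar_rf` object: list with the fitted `model`, selected
#'   `n_tree`, `m_try`, the selection `trace` (tibbles), `seed` and the
#'   training feature names.
#' @export
tune_and_train <- function(descriptors, compounds,
                           n_tree_grid = seq(100, 1000, by = 100),
                           tuning_cv_folds = 10,
                           step_factor = 2, improve = 0.05, seed = 1) {
  y <- label_factor(compounds$label)
  if (nlevels(droplevels(y)) < 2) stop("training labels are single-class",
                                       call. = FALSE)
  x <- rf_matrix(descriptors, compounds$id)
  p <- ncol(x)

  cv <- make_cv_scheme(compounds$id, compound_labels(compounds),
                       k = min(tuning_cv_folds, nrow(x)), repeats = 1,
                       seed = seed)
  folds <- cv$folds
  m_try0 <- max(1L, floor(sqrt(p)))
  ntree_trace <- purrr::map_dfr(n_tree_grid, function(nt) {
    accs <- vapply(seq_len(cv$k), function(f) {
      test_ids <- folds$id[folds$fold == f]
      train_ids <- setdiff(compounds$id, test_ids)
      fit <- fit_rf(x[train_ids, , drop = FALSE],
                    y[match(train_ids, compounds$id)],
                    nt, m_try0, seed + nt + f)
      mean(stats::predict(fit, x[test_ids, , drop = FALSE]) ==
             y[match(test_ids, compounds$id)])
    }, numeric(1))
    tibble::tibble(n_tree = nt, cv_accuracy = mean(accs), cv_sd = stats::sd(accs))
  })
  best <- which.max(ntree_trace$cv_accuracy)
  floor_acc <- ntree_trace$cv_accuracy[best] - ntree_trace$cv_sd[best]
  n_tree <- min(ntree_trace$n_tree[ntree_trace$cv_accuracy >= floor_acc])

  mtry_trace <- tune_mtry(x, y, n_tree = n_tree, m_try_start = m_try0,
                          step_factor = step_factor, improve = improve,
                          seed = seed)
  m_try <- mtry_trace$m_try[which.min(mtry_trace$oob_error)]

  model <- fit_rf(x, y, n_tree, m_try, seed)
  structure(list(model = model, n_tree = n_tree, m_try = m_try,
                 trace = list(n_tree = ntree_trace, m_try = mtry_trace),
                 seed = seed, features = colnames(x)),
            class = "csar_rf")
}

# Stepwise OOB m_try search (tuneRF-equivalent), returned as its trace so
# tests can replay it by hand. Steps outward from m_try_start by
# step_factor while the relative OOB improvement over the current best is
# at least `improve`.
tune_mtry <- function(x, y, n_tree, m_try_start, step_factor = 2,
                      improve = 0.05, seed = 1) {
  p <- ncol(x)
  evaluated <- new.env()
  eval_mtry <- function(m) {
    key <- as.character(m)
    if (is.null(evaluated[[key]])) {
      evaluated[[key]] <- oob_error(x, y, n_tree, m, seed + m)
    }
    evaluated[[key]]
  }
  trace <- tibble::tibble(m_try = m_try_start,
                          oob_error = eval_mtry(m_try_start),
                          direction = "start")
  for (dir in c("left", "right")) {
    best_err <- min(trace$oob_error)
    m <- m_try_start
    repeat {
      m_next <- if (dir == "left") max(1L, floor(m / step_factor))
                else min(p, ceiling(m * step_factor))
      if (m_next == m) break
      err <- eval_mtry(m_next)
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        m_try = m_next, oob_error = err, direction = dir))
      rel_improve <- (best_err - err) / max(best_err, .Machine$double.eps)
      if (rel_improve < improve) break
      best_err <- err
      m <- m_next
      if (m == 1L || m == p) break
    }
  }
  trace
}

#' @export
print.csar_rf <- function(x, ...) {
  cat(sprintf("CSAR random forest: n_tree = %d, m_try = %d, %d features\n",
              x$n_tree, x$m_try, length(x$features)))
  invisible(x)
}

#' @rdname tune_and_train
#' @param x A `csar_rf` object.
#' @param ... Unused.
#' @method glance csar_rf
#' @export
glance.csar_rf <- function(x, ...) {
  tibble::tibble(n_tree = x$n_tree, m_try = x$m_try,
                 n_features = length(x$features),
                 oob_error = mean(x$model$predicted != x$model$y))
}

#' Confusion counts for binary predictions
#'
#' @param labels,predictions Vectors of "active"/"inactive" of equal
#'   length; "active" is the positive class.
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  lab <- label_factor(labels); pred <- label_factor(predictions)
  c(tp = sum(lab == "active" & pred == "active"),
    tn = sum(lab == "inactive" & pred == "inactive"),
    fp = sum(lab == "inactive" & pred == "active"),
    fn = sum(lab == "active" & pred == "inactive"))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity, specificity and the Matthews correlation
#' coefficient in their standard forms:
#' `Ac = (TP+TN)/(TP+TN+FP+FN)`, `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A zero MCC denominator (degenerate margin) returns MCC = 0 by
#' convention.
#'
#' @param cm Named counts as from [confusion()].
#' @return One-row tibble with columns `ac`, `sn`, `sp`, `mcc`.
#' @export
classification_metrics <- function(cm) {
  tp <- as.numeric(cm[["tp"]]); tn <- as.numeric(cm[["tn"]])
  fp <- as.numeric(cm[["fp"]]); fn <- as.numeric(cm[["fn"]])
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  tibble::tibble(
    ac = (tp + tn) / total,
    sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    mcc = if (denom > 0) (tp * tn - fp * fn) / denom else 0
  )
}

#' Area under the ROC curve
#'
#' Rank-based (midrank tie handling) AUC, equal to the normalized
#' Mann-Whitney U statistic and to the trapezoidal area under the ROC
#' curve. 1.0 for perfect separation, 0.5 for uninformative scores.
#'
#' @param labels "active"/"inactive" vector; "active" is positive.
#' @param scores Numeric scores (e.g. active-class vote fractions).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  lab <- label_factor(labels)
  n1 <- sum(lab == "active"); n0 <- sum(lab == "inactive")
  if (n1 == 0 || n0 == 0) stop("AUC undefined for single-class labels",
                               call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[lab == "active"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

active_votes <- function(model, x) {
  stats::predict(model, x, type = "prob")[, "active"]
}

evaluate_block <- function(model, x, labels, context, auc = TRUE) {
  pred <- as.character(stats::predict(model, x))
  met <- classification_metrics(confusion(labels, pred))
  met$auc <- if (auc && length(unique(labels)) == 2) {
    roc_auc(labels, active_votes(model, x))
  } else NA_real_
  met$context <- context
  met
}

#' Run the full resampled evaluation protocol
#'
#' For each split in the resampling plan: (optionally tune and) train a
#' random forest on the internal set; evaluate on the training set itself,
#' under stratified repeated k-fold cross-validation (pooling the held-out
#' predictions of all folds and repeats into one per-iteration confusion
#' matrix), on the external set, and on the decoy block (all decoys being
#' truly inactive, decoy accuracy equals decoy specificity). Metrics are
#' aggregated as mean +/- SD (n-1) over iterations.
#'
#' @param descriptors Filtered descriptor tibble for the balanced set.
#' @param compounds Balanced, labeled compound tibble.
#' @param plan List of splits from [make_resampling_plan()].
#' @param decoys Optional decoy descriptor tibble (same columns); omitted
#'   from the report (with a message) when `NULL`.
#' @param cv_k,cv_repeats CV geometry (default 5-fold, 3 repeats).
#' @param tune `"per_iteration"` re-runs the full tuning protocol inside
#'   every iteration (the default), `"once"` tunes on the first iteration
#'   and reuses the configuration, `"none"` uses `n_tree`/`m_try` as given.
#' @param n_tree,m_try Fixed configuration for `tune = "none"` (`m_try =
#'   NULL` means `floor(sqrt(p))`).
#' @param seed Integer seed.
#' @return A `csar_eval` object: list with `per_iteration` (tibble of
#'   metrics per iteration and context) and `aggregate` (mean/SD tibble).
#' @export
run_protocol <- function(descriptors, compounds, plan, decoys = NULL,
                         cv_k = 5, cv_repeats = 3,
                         tune = c("per_iteration", "once", "none"),
                         n_tree = 100, m_try = NULL, seed = 1) {
  tune <- match.arg(tune)
  labels <- compound_labels(compounds)
  if (!is.null(decoys) &&
      !identical(names(decoys)[-1], names(descriptors)[-1])) {
    stop("decoy descriptor columns do not match the training matrix",
         call. = FALSE)
  }
  if (is.null(decoys)) message("no decoys supplied; decoy context omitted")
  p <- ncol(descriptors) - 1
  if (is.null(m_try)) m_try <- max(1L, floor(sqrt(p)))
  cfg <- list(n_tree = n_tree, m_try = m_try)

  rows <- purrr::map_dfr(plan, function(split) {
    it <- split$iteration %||% 1L
    int <- compounds[compounds$id %in% split$internal_ids, ]
    ext <- compounds[compounds$id %in% split$external_ids, ]
    it_seed <- split$seed %% .Machine$integer.max

    if (tune == "per_iteration" || (tune == "once" && it == 1L)) {
      fitted <- tune_and_train(descriptors, int, seed = it_seed)
      cfg <<- list(n_tree = fitted$n_tree, m_try = fitted$m_try)
      model <- fitted$model
    } else {
      model <- fit_rf(rf_matrix(descriptors, int$id), label_factor(int$label),
                      cfg$n_tree, cfg$m_try, it_seed)
    }

    x_int <- rf_matrix(descriptors, int$id)
    out <- evaluate_block(model, x_int, int$label, "train")

    cv <- make_cv_scheme(int$id, labels, k = cv_k, repeats = cv_repeats,
                         seed = it_seed + 1)
    held <- purrr::pmap_dfr(
      expand.grid(r = seq_len(cv_repeats), f = seq_len(cv_k)),
      function(r, f) {
        test_ids <- cv$folds$id[cv$folds$repeat_ == r & cv$folds$fold == f]
        train_ids <- setdiff(int$id, test_ids)
        fit <- fit_rf(x_int[train_ids, , drop = FALSE],
                      label_factor(labels[train_ids]),
                      cfg$n_tree, cfg$m_try, it_seed + 10 * r + f)
        tibble::tibble(
          id = test_ids,
          label = labels[test_ids],
          pred = as.character(stats::predict(fit, x_int[test_ids, , drop = FALSE])),
          vote = active_votes(fit, x_int[test_ids, , drop = FALSE]))
      })
    cv_met <- classification_metrics(confusion(held$label, held$pred))
    cv_met$auc <- roc_auc(held$label, held$vote)
    cv_met$context <- "cv"
    out <- dplyr::bind_rows(out, cv_met)

    if (nrow(ext) > 0) {
      out <- dplyr::bind_rows(
        out, evaluate_block(model, rf_matrix(descriptors, ext$id),
                            ext$label, "external"))
    }
    if (!is.null(decoys)) {
      x_dec <- as.matrix(decoys[-1])
      pred <- as.character(stats::predict(model, x_dec))
      cm <- confusion(rep("inactive", nrow(x_dec)), pred)
      out <- dplyr::bind_rows(out, tibble::tibble(
        ac = (cm[["tn"]]) / nrow(x_dec), sn = NA_real_,
        sp = (cm[["tn"]]) / nrow(x_dec), mcc = NA_real_, auc = NA_real_,
        context = "decoy"))
    }
    out$iteration <- it
    out$n_tree <- cfg$n_tree
    out$m_try <- cfg$m_try
    out
  })

  aggregate <- rows |>
    tidyr::pivot_longer(c("ac", "sn", "sp", "mcc", "auc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$context, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n_iter = dplyr::n(), .groups = "drop")
  structure(list(per_iteration = rows, aggregate = aggregate),
            class = "csar_eval")
}

#' @export
print.csar_eval <- function(x, ...) {
  cat("CSAR evaluation over", length(unique(x$per_iteration$iteration)),
      "iteration(s)\n")
  print(summary_table(x))
  invisible(x)
}

#' @rdname run_protocol
#' @param x A `csar_eval` object.
#' @param ... Unused.
#' @method tidy csar_eval
#' @export
tidy.csar_eval <- function(x, ...) x$per_iteration

#' @rdname run_protocol
#' @method glance csar_eval
#' @export
glance.csar_eval <- function(x, ...) x$aggregate

#' Performance summary table (accuracy-style percentages)
#'
#' One row per evaluation context with `mean +/- SD` strings, Ac/Sn/Sp as
#' percentages, matching the conventional performance-summary layout.
#'
#' @param eval A `csar_eval` object.
#' @return A tibble with one formatted column per metric.
#' @export
summary_table <- function(eval) {
  fmt <- function(m, s, pct) {
    ifelse(pct, sprintf("%.2f ± %.2f", 100 * m, 100 * s),
           sprintf("%.2f ± %.2f", m, s))
  }
  eval$aggregate |>
    dplyr::mutate(cell = fmt(.data$mean, .data$sd,
                             .data$metric %in% c("ac", "sn", "sp"))) |>
    dplyr::select("context", "metric", "cell") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "cell")
}
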