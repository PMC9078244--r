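# End-to-end orchestration: label -> filter -> MODI gate -> balance ->
# resample -> train/evaluate (incl. decoys) -> importance -> class stats ->
# applicability domain. Each stage is the exported verb; this wrapper only
# wires them together, records seeds, and enforces the modelability gate.

#' Run the full CSAR workflow
#'
#' Executes the whole pipeline on a labeled compound table and descriptor
#' matrix (or on freshly generated synthetic data when neither is given).
#' Aborts if the dataset's MODI does not exceed the modelability threshold,
#' unless `force = TRUE`.
#'
#' @param compounds Labeled compound tibble; `NULL` generates synthetic
#'   data from `synth` (and decoys from `decoy`).
#' @param descriptors Descriptor tibble aligned to `compounds`.
#' @param decoys Optional decoy descriptor tibble.
#' @param sampler `"random"` (modeling default) or `"kennard_stone"` (the
#'   applicability-domain analysis default is always Kennard-Stone).
#' @param n_iter Resampling iterations (default 100).
#' @param cv_k,cv_repeats CV geometry (default 5 x 3).
#' @param tune Tuning policy for [run_protocol()].
#' @param sd_cutoff SD filter cutoff (default 0.1).
#' @param modi_threshold Modelability gate (default 0.65).
#' @param force Proceed past a failing MODI gate.
#' @param importance_k Top-k cut for the importance table (default 20).
#' @param n_pc Applicability-domain components (default 2).
#' @param seed Master seed; stage seeds are derived from it.
#' @param synth,decoy Configs used when `compounds` is `NULL`.
#' @param out_dir Optional directory; when given, CSV/JSON reports are
#'   written there.
#' @return A `csar_run` bundle: list with the filtered descriptors, MODI,
#'   balanced set, evaluation report, importance table, per-feature class
#'   statistics, AD model and verdicts, the final fitted model, and the
#'   stage seeds.
#' @export
csar_run <- function(compounds = NULL, descriptors = NULL, decoys = NULL,
                     sampler = c("random", "kennard_stone"),
                     n_iter = 100, cv_k = 5, cv_repeats = 3,
                     tune = "per_iteration",
                     sd_cutoff = 0.1, modi_threshold = 0.65, force = FALSE,
                     importance_k = 20, n_pc = 2, seed = 1,
                     synth = synth_config(seed = seed),
                     decoy = decoy_config(seed = seed + 1),
                     out_dir = NULL) {
  sampler <- match.arg(sampler)
  truth <- NULL
  if (is.null(compounds)) {
    ds <- generate_dataset(synth)
    compounds <- ds$compounds
    descriptors <- ds$descriptors
    truth <- ds$truth
    if (is.null(decoys)) decoys <- generate_decoys(ds, decoy)$descriptors
  }
  if (is.null(descriptors)) stop("descriptors are required", call. = FALSE)
  if (anyNA(compounds$label)) compounds <- apply_label_rule(compounds)

  seeds <- list(balance = seed + 11L, plan = seed + 23L, ad_split = seed + 37L)

  filtered <- filter_near_constant(descriptors, sd_cutoff)
  if (!is.null(decoys)) decoys <- decoys[names(filtered)]

  gate <- modi(filtered, compound_labels(compounds), threshold = modi_threshold)
  if (!gate$modelable && !force) {
    stop("modelability gate: MODI = ", round(gate$modi, 3), " <= ",
         modi_threshold, "; dataset is not considered modelable ",
         "(use force = TRUE to proceed)", call. = FALSE)
  }

  balanced <- if (sampler == "random") {
    undersample_random(compounds, seed = seeds$balance)
  } else {
    undersample_kennard_stone(compounds, filtered)
  }
  plan <- make_resampling_plan(balanced, n_iter = n_iter, seed = seeds$plan)
  evaluation <- run_protocol(filtered, balanced, plan, decoys = decoys,
                             cv_k = cv_k, cv_repeats = cv_repeats,
                             tune = tune, seed = seed)

  importance <- mdgi_ensemble(filtered, balanced, seed = seed)
  top <- top_k(importance, min(importance_k, nrow(importance)))
  stats_tbl <- compare_features(filtered[c("id", top$descriptor)], compounds)

  # AD uses the Kennard-Stone balanced set and a Kennard-Stone split
  ad_balanced <- undersample_kennard_stone(compounds, filtered)
  ad_rows <- match(ad_balanced$id, filtered$id)
  n_train <- round(0.75 * nrow(ad_balanced))
  ks_sel <- kennard_stone(as.matrix(filtered[ad_rows, -1]), n_train)
  ad_train_ids <- ad_balanced$id[ks_sel]
  ad_test_ids <- setdiff(ad_balanced$id, ad_train_ids)
  ad_model <- fit_ad(filtered[filtered$id %in% ad_train_ids, ], n_pc = n_pc)
  ad_check <- check_ad(ad_model, filtered[filtered$id %in% ad_test_ids, ])

  final_cfg <- evaluation$per_iteration[1, c("n_tree", "m_try")]
  final_model <- fit_rf(rf_matrix(filtered, balanced$id),
                        label_factor(balanced$label),
                        final_cfg$n_tree, final_cfg$m_try, seed)

  bundle <- structure(list(
    compounds = compounds, descriptors = filtered, modi = gate,
    balanced = balanced, plan = plan, evaluation = evaluation,
    importance = importance, top = top, stats = stats_tbl,
    ad_model = ad_model, ad_check = ad_check,
    model = final_model,
    config = list(sampler = sampler, n_iter = n_iter, cv_k = cv_k,
                  cv_repeats = cv_repeats, tune = tune,
                  sd_cutoff = sd_cutoff, modi_threshold = modi_threshold,
                  n_pc = n_pc, seed = seed, seeds = seeds),
    truth = truth
  ), class = "csar_run")

  if (!is.null(out_dir)) write_run_reports(bundle, out_dir)
  bundle
}

#' @export
print.csar_run <- function(x, ...) {
  cat("CSAR pipeline run\n")
  cat(sprintf("  compounds: %d (%d active / %d inactive)\n",
              nrow(x$compounds), sum(x$compounds$label == "active"),
              sum(x$compounds$label == "inactive")))
  cat(sprintf("  MODI: %.3f (%s)\n", x$modi$modi,
              if (x$modi$modelable) "modelable" else "forced past gate"))
  print(summary_table(x$evaluation))
  invisible(x)
}

write_run_reports <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$evaluation$per_iteration,
                   file.path(out_dir, "metrics_per_iteration.csv"))
  readr::write_csv(bundle$evaluation$aggregate,
                   file.path(out_dir, "metrics_aggregate.csv"))
  readr::write_csv(tibble::as_tibble(bundle$top),
                   file.path(out_dir, "importance_top.csv"))
  readr::write_csv(dplyr::select(bundle$stats, -"summaries"),
                   file.path(out_dir, "class_stats.csv"))
  readr::write_csv(bundle$ad_check, file.path(out_dir, "ad_verdicts.csv"))
  jsonlite::write_json(
    list(modi = glance(bundle$modi), config = bundle$config[
      setdiff(names(bundle$config), "seeds")]),
    file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Predict activity of new compounds with a pipeline bundle
#'
#' Predicts the activity class (with active-class vote fraction) of query
#' compounds and flags whether each lies inside the applicability domain.
#' Queries can be given as a descriptor tibble matching the model's
#' feature columns, or as SMILES (computed through the built-in
#' substructure-count backend, valid only when the bundle was trained on
#' that backend's columns).
#'
#' @param bundle A `csar_run` object.
#' @param descriptors Query descriptor tibble, or `NULL` if `smiles` given.
#' @param smiles Character vector of query SMILES.
#' @return Tibble with `id`, `prediction`, `vote_active`, `ad_inside`.
#' @export
csar_predict <- function(bundle, descriptors = NULL, smiles = NULL) {
  if (is.null(descriptors)) {
    if (is.null(smiles)) stop("supply descriptors or smiles", call. = FALSE)
    q <- tibble::tibble(id = paste0("query", seq_along(smiles)),
                        smiles = smiles)
    counts <- compute_substructure_counts(q)
    missing_cols <- setdiff(names(bundle$descriptors)[-1], names(counts)[-1])
    if (length(missing_cols) > 0) {
      stop("model was trained on descriptor columns the built-in ",
           "substructure backend cannot compute: ",
           paste(utils::head(missing_cols, 5), collapse = ", "),
           "; supply an external descriptor CSV instead", call. = FALSE)
    }
    descriptors <- counts[c("id", names(bundle$descriptors)[-1])]
  }
  x <- as.matrix(descriptors[names(bundle$descriptors)[-1]])
  rownames(x) <- descriptors$id
  pred <- as.character(stats::predict(bundle$model, x))
  vote <- stats::predict(bundle$model, x, type = "prob")[, "active"]
  ad <- check_ad(bundle$ad_model, descriptors)
  tibble::tibble(id = descriptors$id, prediction = pred,
                 vote_active = unname(vote),
                 ad_inside = ad$inside[match(descriptors$id, ad$id)])
}
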