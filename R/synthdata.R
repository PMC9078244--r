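# Synthetic compound sets with a planted class signal, plus
# property-matched decoys, so every pipeline stage can be exercised
# without any external download. Count-valued descriptors are Poisson
# draws (the workflow's winning descriptor class is count-valued); decoys
# are descriptor-level emulations of property-matched presumed inactives,
# not fabricated molecules.

#' Synthetic dataset configuration
#'
#' Defaults emulate the study conditions: 32 active / 83 inactive
#' compounds (a 1:2.6 imbalance), solubility ratios straddling the 1.06
#' labeling threshold, 45 count-valued descriptor columns of which 10 are
#' class-informative.
#'
#' @param n_active,n_inactive Class sizes (defaults 32, 83).
#' @param n_features,n_informative Descriptor geometry (defaults 45, 10).
#' @param lambda_active,lambda_inactive Poisson means of informative
#'   columns in the two classes (defaults 3, 1).
#' @param lambda_noise Poisson mean of uninformative columns (default 1).
#' @param ratio_active,ratio_inactive Uniform solubility-ratio ranges per
#'   class; the active range starts at the 1.06 threshold.
#' @param bernoulli If `TRUE`, draw presence/absence bits instead of
#'   counts (probabilities `1 - exp(-lambda)`).
#' @param seed Integer seed.
#' @return A `csar_synth_config` list.
#' @export
synth_config <- function(n_active = 32, n_inactive = 83,
                         n_features = 45, n_informative = 10,
                         lambda_active = 3, lambda_inactive = 1,
                         lambda_noise = 1,
                         ratio_active = c(1.06, 1.30),
                         ratio_inactive = c(0.85, 1.059),
                         bernoulli = FALSE, seed = 1) {
  stopifnot(n_informative <= n_features,
            lambda_active >= 0, lambda_inactive >= 0, lambda_noise >= 0,
            ratio_active[1] >= 1.06, ratio_inactive[2] < 1.06)
  structure(as.list(environment()), class = "csar_synth_config")
}

#' Generate a synthetic compound set with planted signal
#'
#' Informative descriptor columns are Poisson with class-specific means;
#' noise columns share one mean across classes. Solubility ratios are
#' uniform within the class range, so labels derived via the default
#' [label_rule()] reproduce the configured class sizes exactly. Synthetic
#' Lipinski-like properties (MW, AlogP, HBD, HBA) are drawn per compound
#' for decoy matching. Fully seed-reproducible.
#'
#' @param cfg A [synth_config()].
#' @return List with `compounds` (tibble incl. labels and synthetic
#'   properties), `descriptors` (count tibble), and `truth` (informative
#'   column names and the config).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  n <- cfg$n_active + cfg$n_inactive
  withr::with_seed(cfg$seed, {
    informative <- sort(sample(cfg$n_features, cfg$n_informative))
    feature_names <- sprintf("FPC%03d", seq_len(cfg$n_features))
    lab <- rep(c("active", "inactive"), c(cfg$n_active, cfg$n_inactive))
    draw <- function(lambda, m) {
      if (cfg$bernoulli) stats::rbinom(m, 1, 1 - exp(-lambda))
      else stats::rpois(m, lambda)
    }
    x <- matrix(0L, nrow = n, ncol = cfg$n_features,
                dimnames = list(NULL, feature_names))
    for (j in seq_len(cfg$n_features)) {
      if (j %in% informative) {
        x[lab == "active", j] <- draw(cfg$lambda_active, cfg$n_active)
        x[lab == "inactive", j] <- draw(cfg$lambda_inactive, cfg$n_inactive)
      } else {
        x[, j] <- draw(cfg$lambda_noise, n)
      }
    }
    ratio <- numeric(n)
    ratio[lab == "active"] <- stats::runif(cfg$n_active, cfg$ratio_active[1],
                                           cfg$ratio_active[2])
    ratio[lab == "inactive"] <- stats::runif(cfg$n_inactive,
                                             cfg$ratio_inactive[1],
                                             cfg$ratio_inactive[2])
    ids <- sprintf("syn%03d", seq_len(n))
    compounds <- tibble::tibble(
      id = ids,
      # distinct linear alkanes: valid, unique SMILES for plumbing tests
      smiles = vapply(seq_len(n), function(i) strrep("C", i + 1), character(1)),
      smiles_canonical = NA_character_,
      solubility_ratio = ratio,
      label = NA_character_,
      chemotype = NA_character_,
      mw = stats::runif(n, 200, 400),
      alogp = stats::runif(n, -2.5, 4),
      n_hbdon = sample(0:5, n, replace = TRUE),
      n_hbacc = sample(0:10, n, replace = TRUE)
    )
    compounds <- apply_label_rule(compounds)
    descriptors <- dplyr::bind_cols(tibble::tibble(id = ids),
                                    tibble::as_tibble(x))
    attr(descriptors, "mode") <- if (cfg$bernoulli) "binary" else "count"
    attr(descriptors, "fingerprint_class") <- "synthetic count"
    list(compounds = compounds, descriptors = descriptors,
         truth = list(informative = feature_names[informative], config = cfg))
  })
}

#' Decoy generation configuration
#'
#' @param per_active Decoys per active template (default 50).
#' @param tol_mw,tol_alogp Fractional tolerances on MW and AlogP
#'   (default 0.10).
#' @param tol_counts Absolute tolerance on HBD/HBA counts (default 1).
#' @param seed Integer seed.
#' @return A `csar_decoy_config` list.
#' @export
decoy_config <- function(per_active = 50, tol_mw = 0.10, tol_alogp = 0.10,
                         tol_counts = 1, seed = 1) {
  stopifnot(per_active >= 1)
  structure(as.list(environment()), class = "csar_decoy_config")
}

#' Generate property-matched decoys
#'
#' Emulates a property-matched decoy set at desk scale: for each active
#' template, `per_active` decoys whose MW/AlogP lie within a fractional
#' tolerance and whose donor/acceptor counts lie within an absolute
#' tolerance of the template's. Decoy descriptor rows are drawn from the
#' inactive-class distribution (informative columns at the inactive mean,
#' noise columns at the noise mean); all decoys are labeled inactive. No
#' SMILES is fabricated for decoys.
#'
#' @param dataset A [generate_dataset()] result.
#' @param cfg A [decoy_config()].
#' @return List with `compounds` (decoy property tibble, labels all
#'   inactive, `template_id` column) and `descriptors`.
#' @export
generate_decoys <- function(dataset, cfg = decoy_config()) {
  actives <- dataset$compounds[dataset$compounds$label == "active", ]
  if (nrow(actives) == 0) stop("no active templates", call. = FALSE)
  scfg <- dataset$truth$config
  feature_names <- names(dataset$descriptors)[-1]
  informative <- feature_names %in% dataset$truth$informative
  n_dec <- nrow(actives) * cfg$per_active
  withr::with_seed(cfg$seed, {
    template <- actives[rep(seq_len(nrow(actives)), each = cfg$per_active), ]
    jit <- function(v, tol) v * stats::runif(n_dec, 1 - tol, 1 + tol)
    jit_int <- function(v, tol) {
      pmax(0L, v + sample(seq(-tol, tol), n_dec, replace = TRUE))
    }
    compounds <- tibble::tibble(
      id = sprintf("decoy%05d", seq_len(n_dec)),
      template_id = template$id,
      solubility_ratio = NA_real_,
      label = "inactive",
      mw = jit(template$mw, cfg$tol_mw),
      alogp = jit(template$alogp, cfg$tol_alogp),
      n_hbdon = jit_int(template$n_hbdon, cfg$tol_counts),
      n_hbacc = jit_int(template$n_hbacc, cfg$tol_counts)
    )
    x <- matrix(0L, nrow = n_dec, ncol = length(feature_names),
                dimnames = list(NULL, feature_names))
    for (j in seq_along(feature_names)) {
      lambda <- if (informative[j]) scfg$lambda_inactive else scfg$lambda_noise
      x[, j] <- if (scfg$bernoulli) stats::rbinom(n_dec, 1, 1 - exp(-lambda))
                else stats::rpois(n_dec, lambda)
    }
    descriptors <- dplyr::bind_cols(tibble::tibble(id = compounds$id),
                                    tibble::as_tibble(x))
    list(compounds = compounds, descriptors = descriptors)
  })
}
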