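test_that("confusion counts partition the instances", {
  lab <- rep(c("active", "inactive"), each = 8)
  expect_equal(confusion(lab, lab), c(tp = 8L, tn = 8L, fp = 0L, fn = 0L))
  expect_equal(confusion(lab, rep("active", 16)),
               c(tp = 8L, tn = 0L, fp = 8L, fn = 0L))
  # fixed vector against a hand tally
  pred <- c("active", "inactive", "active", "inactive", "active",
            "inactive", "active", "active",
            "inactive", "active", "inactive", "inactive", "active",
            "inactive", "inactive", "active")
  cm <- confusion(lab, pred)
  expect_equal(cm, c(tp = 5L, tn = 5L, fp = 3L, fn = 3L))
  expect_equal(sum(cm), 16)
  expect_error(confusion(lab, pred[-1]), "length")
})

test_that("metrics reproduce hand arithmetic and closed-form anchors", {
  perfect <- classification_metrics(c(tp = 8, tn = 8, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(ac = 1, sn = 1, sp = 1, mcc = 1))
  inverted <- classification_metrics(c(tp = 0, tn = 0, fp = 8, fn = 8))
  expect_equal(inverted$mcc, -1)

  m <- classification_metrics(c(tp = 20, tn = 18, fp = 6, fn = 4))
  expect_equal(m$ac, 38 / 48)
  expect_equal(m$sn, 20 / 24)
  expect_equal(m$sp, 18 / 24)
  expect_equal(m$mcc, (20 * 18 - 6 * 4) / sqrt(26 * 24 * 24 * 22))

  # degenerate margin: MCC defined as 0
  expect_equal(classification_metrics(c(tp = 5, tn = 0, fp = 3, fn = 0))$mcc, 0)
  expect_error(classification_metrics(c(tp = 0, tn = 0, fp = 0, fn = 0)),
               "empty")
})

test_that("on balanced sets accuracy equals the Sn/Sp midpoint", {
  set.seed(12)
  for (i in 1:20) {
    lab <- rep(c("active", "inactive"), each = 12)
    pred <- sample(c("active", "inactive"), 24, replace = TRUE)
    m <- classification_metrics(confusion(lab, pred))
    expect_equal(m$ac, (m$sn + m$sp) / 2)
  }
})

test_that("MCC is invariant under class relabeling", {
  set.seed(13)
  lab <- sample(c("active", "inactive"), 30, replace = TRUE)
  pred <- sample(c("active", "inactive"), 30, replace = TRUE)
  flip <- function(v) ifelse(v == "active", "inactive", "active")
  m1 <- classification_metrics(confusion(lab, pred))
  m2 <- classification_metrics(confusion(flip(lab), flip(pred)))
  expect_equal(m1$mcc, m2$mcc)
})

test_that("AUC matches pair counting, anchors and an independent package", {
  lab <- rep(c("active", "inactive"), each = 4)
  expect_equal(roc_auc(lab, c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1)), 1.0)
  expect_equal(roc_auc(lab, rep(0.5, 8)), 0.5)

  lab6 <- c("active", "active", "inactive", "active", "inactive", "inactive")
  s6 <- c(0.9, 0.4, 0.35, 0.8, 0.6, 0.2)
  expect_equal(roc_auc(lab6, s6), oracle_auc(lab6, s6))

  set.seed(14)
  for (i in 1:10) {
    lab <- sample(c("active", "inactive"), 20, replace = TRUE)
    if (length(unique(lab)) < 2) next
    s <- round(runif(20), 1)  # ties likely
    expect_equal(roc_auc(lab, s), oracle_auc(lab, s))
    # monotone transform invariance
    expect_equal(roc_auc(lab, exp(3 * s)), roc_auc(lab, s))
  }
  skip_if_not_installed("pROC")
  set.seed(15)
  lab <- rep(c("active", "inactive"), each = 10)
  s <- runif(20)
  expect_equal(roc_auc(lab, s),
               as.numeric(pROC::auc(pROC::roc(
                 response = lab, predictor = s, levels = c("inactive", "active"),
                 direction = "<", quiet = TRUE))))
  expect_error(roc_auc(rep("active", 4), runif(4)), "single-class")
})

make_separable <- function(n_per_class = 16, p = 6, delta = 6, seed = 21) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rpois(n_per_class * p, 1), ncol = p),
               matrix(rpois(n_per_class * p, 1) + delta, ncol = p))
    labels <- rep(c("active", "inactive"), each = n_per_class)
    list(desc = desc_tbl(x, sprintf("c%02d", seq_len(2 * n_per_class))),
         compounds = fake_compounds(labels,
                                    sprintf("c%02d", seq_len(2 * n_per_class))))
  })
}

test_that("tuning searches the stated grid and nails separable data", {
  expect_equal(eval(formals(tune_and_train)$n_tree_grid), seq(100, 1000, 100))
  d <- make_separable()
  fit <- tune_and_train(d$desc, d$compounds, n_tree_grid = c(100, 200),
                        tuning_cv_folds = 3, seed = 2)
  expect_s3_class(fit, "csar_rf")
  pred <- predict(fit$model, as.matrix(d$desc[-1]))
  expect_equal(mean(pred == d$compounds$label), 1.0)
  expect_true(all(c("n_tree", "m_try") %in% names(fit$trace)))

  mono <- d$compounds; mono$label <- "active"
  expect_error(tune_and_train(d$desc, mono), "single-class")
})

test_that("the m_try search replays as a hand-stepped tuneRF trace", {
  d <- make_separable(n_per_class = 12, p = 9, delta = 2, seed = 33)
  x <- as.matrix(d$desc[-1]); rownames(x) <- d$desc$id
  y <- factor(d$compounds$label, levels = c("active", "inactive"))
  trace <- csarpipe:::tune_mtry(x, y, n_tree = 100, m_try_start = 3, seed = 4)
  # start point is floor(sqrt(p)) as passed
  expect_equal(trace$m_try[1], 3)
  expect_equal(trace$direction[1], "start")
  # replay the stepping rule from the recorded errors alone
  err <- setNames(trace$oob_error, trace$m_try)
  for (dir in c("left", "right")) {
    visited <- trace$m_try[trace$direction == dir]
    best <- err[["3"]]; m <- 3
    expected <- integer(0)
    repeat {
      m_next <- if (dir == "left") max(1, floor(m / 2)) else min(9, ceiling(m * 2))
      if (m_next == m) break
      expected <- c(expected, m_next)
      e <- err[[as.character(m_next)]]
      if ((best - e) / max(best, .Machine$double.eps) < 0.05) break
      best <- e; m <- m_next
      if (m == 1 || m == 9) break
    }
    expect_equal(visited, expected)
  }
  # selection is the argmin of the trace
  fitted_m <- trace$m_try[which.min(trace$oob_error)]
  expect_equal(err[[as.character(fitted_m)]], min(trace$oob_error))
})

test_that("the resampled protocol emits per-iteration and aggregate rows", {
  d <- make_separable(n_per_class = 16, p = 6, delta = 4, seed = 51)
  plan <- make_resampling_plan(d$compounds, n_iter = 3, seed = 61)
  decoys <- withr::with_seed(71, desc_tbl(matrix(rpois(20 * 6, 1) + 4,
                                                 ncol = 6),
                                          ids = sprintf("d%02d", 1:20)))
  names(decoys) <- names(d$desc)
  ev <- run_protocol(d$desc, d$compounds, plan, decoys = decoys,
                     tune = "none", n_tree = 100, seed = 81)
  per <- tidy(ev)
  expect_equal(sort(unique(per$context)),
               c("cv", "decoy", "external", "train"))
  expect_equal(nrow(per), 3 * 4)  # 3 iterations x 4 contexts
  agg <- glance(ev)
  expect_true(all(agg$n_iter == 3))
  # decoys are all truly inactive: accuracy == specificity
  dec <- per[per$context == "decoy", ]
  expect_equal(dec$ac, dec$sp)
  # aggregate mean recomputable from per-iteration rows
  cv_ac <- agg$mean[agg$context == "cv" & agg$metric == "ac"]
  expect_equal(cv_ac, mean(per$ac[per$context == "cv"]))

  expect_message(
    run_protocol(d$desc, d$compounds, plan[1], tune = "none", seed = 1),
    "decoy context omitted")
  bad_decoys <- decoys; names(bad_decoys)[2] <- "wrong"
  expect_error(run_protocol(d$desc, d$compounds, plan, decoys = bad_decoys,
                            tune = "none"), "decoy descriptor columns")
})

test_that("label-permutation null centers CV MCC on zero", {
  d <- make_separable(n_per_class = 32, p = 8, delta = 5, seed = 91)
  mccs <- vapply(1:50, function(i) {
    shuffled <- d$compounds
    shuffled$label <- withr::with_seed(1000 + i, sample(shuffled$label))
    plan <- make_resampling_plan(shuffled, n_iter = 1, seed = 2000 + i)
    ev <- run_protocol(d$desc, shuffled, plan, tune = "none", n_tree = 100,
                       cv_repeats = 1, seed = 3000 + i)
    per <- ev$per_iteration
    per$mcc[per$context == "cv"]
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.1)
})
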