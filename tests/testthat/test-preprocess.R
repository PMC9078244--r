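test_that("SD filter keeps exactly the columns above the cutoff", {
  m <- desc_tbl(cbind(constant = rep(2, 4),
                      spread = c(0, 0, 0, 1),     # sample SD 0.5
                      tiny = c(0, 0.01, 0, 0.01)))
  names(m)[-1] <- c("constant", "spread", "tiny")
  out <- filter_near_constant(m)
  expect_equal(names(out)[-1], "spread")
  expect_setequal(attr(out, "dropped"), c("constant", "tiny"))
  # idempotent and never widening
  expect_equal(names(filter_near_constant(out)), names(out))

  # SD exactly at the cutoff is dropped (strict >); sd(c(-.1,0,.1)) == 0.1
  m2 <- desc_tbl(cbind(at_cutoff = c(-0.1, 0, 0.1), wide = c(0, 5, 10)))
  names(m2)[-1] <- c("at_cutoff", "wide")
  expect_equal(names(filter_near_constant(m2))[-1], "wide")

  expect_warning(filter_near_constant(desc_tbl(cbind(k = rep(1, 3)))),
                 "all descriptor columns dropped")
})

test_that("random undersampling balances to the minority count", {
  labels <- rep(c("active", "inactive"), c(32, 83))
  cs <- fake_compounds(labels, ids = sprintf("c%03d", 1:115))
  bal <- undersample_random(cs, seed = 11)
  expect_equal(nrow(bal), 64)
  expect_equal(as.integer(table(bal$label)["active"]), 32L)
  expect_equal(as.integer(table(bal$label)["inactive"]), 32L)
  expect_true(all(cs$id[cs$label == "active"] %in% bal$id))
  # reproducible from seed; generically different across seeds
  expect_identical(bal$id, undersample_random(cs, seed = 11)$id)
  expect_false(identical(bal$id, undersample_random(cs, seed = 12)$id))

  small <- fake_compounds(rep(c("active", "inactive"), each = 5))
  expect_message(same <- undersample_random(small, seed = 1), "balanced")
  expect_identical(same$id, small$id)
})

test_that("Kennard-Stone picks the spanning subset deterministically", {
  # 1-D: the max-distance pair
  expect_equal(sort(kennard_stone(matrix(c(0, 1, 10)), 2)), c(1, 3))
  # k == n is the identity
  x <- matrix(rnorm(12), ncol = 2)
  expect_equal(sort(kennard_stone(x, 6)), 1:6)
  # 20 random 2-D points, k = 8, against the exhaustive greedy oracle
  set.seed(42)
  x20 <- matrix(rnorm(40), ncol = 2)
  expect_equal(kennard_stone(x20, 8), oracle_kennard_stone(x20, 8))
})

test_that("Kennard-Stone equals the brute-force oracle on many instances", {
  set.seed(99)
  for (rep in 1:12) {
    n <- sample(5:50, 1)
    p <- sample(2:6, 1)
    k <- sample(2:n, 1)
    x <- matrix(rnorm(n * p), ncol = p)
    expect_equal(kennard_stone(x, k), oracle_kennard_stone(x, k))
  }
})

test_that("Kennard-Stone undersampling keeps minority and spans majority", {
  labels <- rep(c("active", "inactive"), c(5, 12))
  cs <- fake_compounds(labels, ids = sprintf("c%02d", 1:17))
  set.seed(3)
  desc <- desc_tbl(matrix(rnorm(17 * 3), ncol = 3), ids = cs$id)
  bal <- undersample_kennard_stone(cs, desc)
  expect_equal(as.integer(table(bal$label)), c(5L, 5L))
  expect_true(all(cs$id[1:5] %in% bal$id))
  expect_error(undersample_kennard_stone(cs, desc, k = 13), "exceeds")
})

test_that("stratified split reproduces the study cardinalities", {
  cs <- fake_compounds(rep(c("active", "inactive"), each = 32),
                       ids = sprintf("c%02d", 1:64))
  sp <- split_internal_external(cs, seed = 5)
  expect_equal(length(sp$internal_ids), 48)
  expect_equal(length(sp$external_ids), 16)
  lab <- setNames(cs$label, cs$id)
  expect_equal(as.integer(table(lab[sp$internal_ids])), c(24L, 24L))
  expect_equal(as.integer(table(lab[sp$external_ids])), c(8L, 8L))
  # partition: no overlap, no loss
  expect_setequal(c(sp$internal_ids, sp$external_ids), cs$id)

  cs10 <- fake_compounds(rep(c("active", "inactive"), each = 5))
  sp10 <- split_internal_external(cs10, seed = 2)
  expect_equal(length(sp10$internal_ids), 8)
  expect_equal(length(sp10$external_ids), 2)

  expect_warning(split_internal_external(cs10, ratio = 1, seed = 1), "empty")
})

test_that("resampling plans are valid partitions and seed-stable", {
  cs <- fake_compounds(rep(c("active", "inactive"), each = 16))
  plan <- make_resampling_plan(cs, n_iter = 5, seed = 77)
  expect_length(plan, 5)
  for (sp in plan) {
    expect_setequal(c(sp$internal_ids, sp$external_ids), cs$id)
    expect_length(intersect(sp$internal_ids, sp$external_ids), 0)
  }
  expect_identical(plan, make_resampling_plan(cs, n_iter = 5, seed = 77))
  expect_false(identical(plan[[1]]$internal_ids, plan[[2]]$internal_ids))
  expect_length(make_resampling_plan(cs, n_iter = 1, seed = 1), 1)
})

test_that("CV folds are stratified partitions with balanced sizes", {
  ids <- sprintf("c%02d", 1:48)
  labels <- setNames(rep(c("active", "inactive"), each = 24), ids)
  cv <- make_cv_scheme(ids, labels, k = 5, repeats = 3, seed = 9)
  expect_equal(nrow(cv$folds), 48 * 3)
  for (r in 1:3) {
    fr <- cv$folds[cv$folds$repeat_ == r, ]
    expect_setequal(fr$id, ids)                       # union == internal set
    expect_equal(sort(as.integer(table(fr$fold)), decreasing = TRUE),
                 sort(c(10, 10, 10, 9, 9), decreasing = TRUE))
    # stratification to +/-1 per class per fold
    per <- table(fr$fold, labels[fr$id])
    expect_true(all(abs(per - 24 / 5) <= 1))
  }
  # 3 repeats x 5 folds = 15 test sets
  expect_equal(nrow(unique(cv$folds[c("repeat_", "fold")])), 15)

  loo <- make_cv_scheme(ids[1:6], labels[1:6], k = 6, repeats = 1, seed = 1)
  expect_equal(sort(as.integer(table(loo$folds$fold))), rep(1L, 6))
  expect_error(make_cv_scheme(ids[1:4], labels, k = 5, repeats = 1, seed = 1),
               "exceeds")
})
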