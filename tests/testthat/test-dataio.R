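write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("compound CSV ingest keeps valid rows and reports rejects", {
  path <- write_csv_fixture(c("id,smiles,solubility_ratio",
                              "a,CCO,1.10", "b,c1ccccc1,0.95", "c,CC(=O)O,1.07"))
  cs <- read_compound_csv(path)
  expect_equal(nrow(cs), 3)
  expect_equal(nrow(attr(cs, "rejects")), 0)
  expect_false(anyNA(cs$smiles_canonical))

  bad <- write_csv_fixture(c("id,smiles,solubility_ratio",
                             "a,CCO,1.10", "b,C1CC,0.95", "c,CC,1.00"))
  expect_warning(cs2 <- read_compound_csv(bad), "rejected")
  expect_equal(nrow(cs2), 2)
  rej <- attr(cs2, "rejects")
  expect_equal(rej$id, "b")
  expect_match(rej$reason, "SMILES")

  empty <- write_csv_fixture("id,smiles,solubility_ratio")
  expect_equal(nrow(read_compound_csv(empty)), 0)
})

test_that("mandatory columns and duplicate ids are enforced", {
  nosmiles <- write_csv_fixture(c("id,ratio", "a,1.2"))
  expect_error(read_compound_csv(nosmiles), "mandatory column")
  dup <- write_csv_fixture(c("id,smiles", "a,CCO", "a,CCC"))
  expect_error(read_compound_csv(dup), "duplicate")
})

test_that("column dialect maps arbitrary headers onto roles", {
  path <- write_csv_fixture(c("cmpd,structure,sr", "x1,CCO,1.2"))
  cs <- read_compound_csv(path, dialect = c(id = "cmpd", smiles = "structure",
                                            solubility_ratio = "sr"))
  expect_equal(cs$id, "x1")
  expect_equal(cs$solubility_ratio, 1.2)
})

test_that("standardization collapses equivalent notations and logs merges", {
  cs <- fake_compounds(rep(NA_character_, 2), ids = c("a", "b"))
  cs$smiles <- c("CCO", "OCC")
  out <- standardize_compounds(cs)
  expect_equal(nrow(out), 1)
  expect_equal(out$id, "a")
  expect_equal(attr(out, "merge_log")$dropped_id, "b")

  # 5 records, two duplicated pairs -> 3 kept, merge log of 2;
  # cross-checked by a brute-force pairwise canonical comparison
  cs5 <- fake_compounds(rep(NA_character_, 5), ids = letters[1:5])
  cs5$smiles <- c("CCO", "c1ccccc1", "OCC", "C1=CC=CC=C1", "CCN")
  out5 <- standardize_compounds(cs5)
  can <- canonical_smiles(cs5$smiles, standardize = TRUE)
  n_unique_oracle <- 0
  for (i in seq_along(can)) {
    if (!any(can[seq_len(i - 1)] == can[i])) n_unique_oracle <- n_unique_oracle + 1
  }
  expect_equal(nrow(out5), n_unique_oracle)
  expect_equal(nrow(out5), 3)
  expect_equal(nrow(attr(out5, "merge_log")), 2)

  # idempotence
  again <- standardize_compounds(out5)
  expect_equal(again$id, out5$id)
  expect_equal(nrow(attr(again, "merge_log")), 0)
})

test_that("salt stripping and charge neutralization unify forms", {
  cs <- fake_compounds(rep(NA_character_, 2), ids = c("acid", "na_salt"))
  cs$smiles <- c("CC(=O)O", "CC(=O)[O-].[Na+]")
  out <- standardize_compounds(cs)
  expect_equal(nrow(out), 1)
})

test_that("activity-cliff duplicates are a hard error", {
  cs <- fake_compounds(rep(NA_character_, 2), ids = c("a", "b"))
  cs$smiles <- c("CCO", "OCC")
  cs$solubility_ratio <- c(1.20, 0.95)
  expect_error(standardize_compounds(cs), "activity-cliff")
})

test_that("labeling follows the threshold rule, boundary inclusive", {
  cs <- fake_compounds(rep(NA_character_, 4))
  cs$solubility_ratio <- c(0.90, 1.00, 1.06, 1.22)
  out <- apply_label_rule(cs)
  expect_equal(out$label, c("inactive", "inactive", "active", "active"))
  expect_equal(unname(attr(out, "counts")["n_active"]), 2L)

  cs1 <- fake_compounds(NA_character_)
  cs1$solubility_ratio <- 1.0599
  expect_equal(apply_label_rule(cs1)$label, "inactive")

  # idempotence: re-applying never changes a label
  expect_identical(apply_label_rule(out)$label, out$label)

  # exclusive boundary variant
  strict <- label_rule(active_if_geq = FALSE)
  cs1$solubility_ratio <- 1.06
  expect_equal(apply_label_rule(cs1, strict)$label, "inactive")

  cs1$solubility_ratio <- NA_real_
  expect_error(apply_label_rule(cs1), "missing solubility_ratio")
})

test_that("descriptor CSV round-trips and rejects malformed cells", {
  m <- desc_tbl(matrix(c(0L, 1L, 3L, 2L, 5L, 8L, 0.25, 1.5, -2.125,
                         1e-7, 2.5, 3.75, 0, 1, 0), nrow = 3),
                ids = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_csv(m, path)
  back <- read_descriptor_csv(path)
  expect_equal(names(back), names(m))
  expect_equal(as.matrix(back[-1]), as.matrix(m[-1]))

  na_cell <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Name,f1,f2", "a,1,2", "b,NA,3"), na_cell)
  expect_error(read_descriptor_csv(na_cell), "row 2.*column 'f1'")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Name,f1", "a,1", "a,2"), dup)
  expect_error(read_descriptor_csv(dup), "duplicate")
})
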