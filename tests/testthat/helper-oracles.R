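# Independent brute-force oracles: deliberately naive double loops,
# sharing no code with the implementation they check.

# O(n^2 m) nearest-neighbor MODI
oracle_modi <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  nn <- integer(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((x[i, ] - x[j, ])^2))
      if (dij < best) { best <- dij; nn[i] <- j }
    }
  }
  mean(vapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    mean(labels[nn[idx]] == cl)
  }, numeric(1)))
}

# O(k n^2) greedy Kennard-Stone, recomputing all distances each step
oracle_kennard_stone <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  best <- c(1L, 2L); bd <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d(i, j) > bd) { bd <- d(i, j); best <- c(i, j) }
    }
  }
  sel <- best
  while (length(sel) < k) {
    rem <- setdiff(seq_len(n), sel)
    mind <- vapply(rem, function(r) min(vapply(sel, function(s) d(r, s),
                                               numeric(1))), numeric(1))
    sel <- c(sel, rem[which.max(mind)])
  }
  sel
}

# AUC by exhaustive concordant/discordant pair counting
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == "active"]
  neg <- scores[labels == "inactive"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# small helper: descriptor tibble from a matrix
desc_tbl <- function(x, ids = sprintf("c%02d", seq_len(nrow(x)))) {
  x <- as.matrix(x)
  colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(x))
}

# labeled compound tibble without chemistry, for model-layer tests
fake_compounds <- function(labels, ids = sprintf("c%02d", seq_along(labels))) {
  tibble::tibble(id = ids, smiles = NA_character_,
                 smiles_canonical = NA_character_,
                 solubility_ratio = NA_real_, label = labels,
                 chemotype = NA_character_)
}
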