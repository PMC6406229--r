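# Independent oracles and fixture builders shared across the suite.
# Oracle code deliberately shares nothing with the implementation path:
# the kappa oracle works from the K x K contingency table, the weight
# oracle recomputes log / z-score / logistic stepwise.

# Textbook weighted Cohen's kappa (disagreement form) from the 4x4
# contingency table of two raters: q_o = sum_ij p_ij v_ij,
# q_e = sum_ij p_i. p_.j v_ij, kappa = 1 - q_o / q_e.
textbook_weighted_kappa <- function(k, l, v) {
  n <- length(k)
  p <- matrix(0, 4, 4)
  for (i in seq_len(n)) p[k[i], l[i]] <- p[k[i], l[i]] + 1 / n
  row_m <- rowSums(p)
  col_m <- colSums(p)
  q_o <- 0
  q_e <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      q_o <- q_o + p[i, j] * v[i, j]
      q_e <- q_e + row_m[i] * col_m[j] * v[i, j]
    }
  }
  list(q_o = q_o, q_e = q_e, kappa = 1 - q_o / q_e)
}

# Brute-force chance disagreement: explicit double loop over all 16
# category pairs with item-weighted marginals accumulated one item at a
# time.
brute_force_chance <- function(responses, key, weights, v) {
  p1 <- rep(0, 4)
  p2 <- rep(0, 4)
  for (n in seq_along(key)) {
    p1[key[n]] <- p1[key[n]] + weights[n]
    p2[responses[n]] <- p2[responses[n]] + weights[n]
  }
  total <- 0
  for (i in 1:4) {
    for (j in 1:4) total <- total + p1[i] * p2[j] * v[i, j]
  }
  total
}

# Stepwise recomputation of logistic item weights (log, z-score with the
# sample sd, logistic), one scalar at a time.
stepwise_weights <- function(counts, slope = 1, center = 0) {
  lc <- vapply(counts, log, numeric(1))
  m <- sum(lc) / length(lc)
  s <- sqrt(sum((lc - m)^2) / (length(lc) - 1))
  vapply(lc, function(x) {
    z <- (x - m) / s
    1 / (1 + exp(-slope * (z - center)))
  }, numeric(1))
}

# Write a frequency table file from word/count vectors; returns the path.
write_freq_file <- function(lines, dir = tempdir()) {
  path <- tempfile("vocab", tmpdir = dir, fileext = ".tsv")
  writeLines(lines, path)
  path
}

# A small deterministic synthetic corpus shared by instrument-level tests.
fixture_vocab <- function(n = 1000, seed = 11) {
  generate_vocabulary(n, zipf_exponent = 1, seed = seed)
}

fixture_instrument <- function(vocab = fixture_vocab(), seed = 7) {
  weighted <- compute_item_weights(vocab)
  part <- partition_tiers(weighted, 10)
  chain <- build_chain(vocab$word)
  build_instrument(part, chain, vocab$word, seed = seed)
}

# Random named response vector over an instrument's items.
random_sheet <- function(key) {
  stats::setNames(sample.int(4L, length(key), replace = TRUE), names(key))
}
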