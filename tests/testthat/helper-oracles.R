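# Independent brute-force oracles, deliberately naive and separate from the
# package's vectorised implementations.

oracle_raw_moment <- function(m, j, k) {
  acc <- 0
  for (a in seq_len(nrow(m))) {
    for (b in seq_len(ncol(m))) {
      acc <- acc + a^j * b^k * m[a, b]
    }
  }
  acc
}

oracle_central_moment <- function(m, j, k) {
  m00 <- oracle_raw_moment(m, 0, 0)
  abar <- oracle_raw_moment(m, 1, 0) / m00
  bbar <- oracle_raw_moment(m, 0, 1) / m00
  acc <- 0
  for (a in seq_len(nrow(m))) {
    for (b in seq_len(ncol(m))) {
      acc <- acc + (a - abar)^j * (b - bbar)^k * m[a, b]
    }
  }
  acc
}

moment_order_pairs <- function() {
  list(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(0, 2),
       c(2, 0), c(1, 2), c(2, 1), c(3, 0), c(0, 3))
}

# Direct transcription of the incidence rule: signed offsets of every
# occurrence of y relative to the first occurrence of x.
oracle_prim <- function(residues, order) {
  n <- nchar(residues)
  tokens <- vapply(seq_len(n - order + 1L),
                   function(p) substr(residues, p, p + order - 1L), "")
  syms <- enhancerRF:::all_kmers(order)
  m <- matrix(0, length(syms), length(syms), dimnames = list(syms, syms))
  for (x in syms) {
    fx <- which(tokens == x)[1]
    if (is.na(fx)) next
    for (y in syms) {
      for (p in which(tokens == y)) {
        m[x, y] <- m[x, y] + (p - fx)
      }
    }
  }
  m
}

# AUC as the Mann-Whitney pair statistic over all positive-negative pairs.
oracle_auc <- function(truth_pos, scores) {
  ps <- scores[truth_pos]
  ns <- scores[!truth_pos]
  tot <- 0
  for (p in ps) {
    for (q in ns) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(ps) * length(ns))
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
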