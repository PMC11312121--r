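# Independent brute-force oracles, shared across test files. They must stay
# free of any package internals they are used to verify.

# Per-pixel 8-neighbour LBP with explicit loops.
lbp_oracle <- function(m) {
  n <- nrow(m); w <- ncol(m)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  out <- matrix(0L, n - 2, w - 2)
  for (r in 2:(n - 1)) for (cc in 2:(w - 1)) {
    code <- 0L
    for (i in seq_along(offs)) {
      if (m[r + offs[[i]][1], cc + offs[[i]][2]] >= m[r, cc])
        code <- code + as.integer(2^(i - 1))
    }
    out[r - 1, cc - 1] <- code
  }
  out
}

# Pairwise AUC: P(score_pos > score_neg) + 0.5 P(tie) over all pairs.
auc_bruteforce <- function(scores, truths) {
  pos <- scores[truths == "non_valid"]
  neg <- scores[truths != "non_valid"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

clip_hs <- function(x) pmin(pmax(x, 0), 100)
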