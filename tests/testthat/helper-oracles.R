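# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration for alignments, direct
# closed-form arithmetic for ANOVA decompositions and moments.

# Exhaustive minimum-cost monotone alignment by recursion over all edit
# scripts, with the same tie preference (hit > substitution > deletion >
# insertion) expressed as lexicographic minimization.
brute_align <- function(hyp, ref, lexicon = equiv_lexicon()) {
  rec <- function(i, j) {
    # returns list of c(cost, hit, sub, del, ins) over all completions
    if (i > length(hyp) && j > length(ref)) {
      return(list(c(0, 0, 0, 0, 0)))
    }
    out <- list()
    if (i <= length(hyp) && j <= length(ref)) {
      step <- if (words_match(hyp[i], ref[j], lexicon)) c(0, 1, 0, 0, 0)
              else c(1, 0, 1, 0, 0)
      for (r in rec(i + 1L, j + 1L)) out[[length(out) + 1L]] <- r + step
    }
    if (j <= length(ref)) {
      for (r in rec(i, j + 1L)) out[[length(out) + 1L]] <- r + c(1, 0, 0, 1, 0)
    }
    if (i <= length(hyp)) {
      for (r in rec(i + 1L, j)) out[[length(out) + 1L]] <- r + c(1, 0, 0, 0, 1)
    }
    out
  }
  cands <- do.call(rbind, rec(1L, 1L))
  key <- cands[, 1] * 1e6 - cands[, 2] * 1e4 - cands[, 3] * 1e2 - cands[, 4]
  best <- cands[which.min(key), ]
  list(cost = best[1], hits = best[2], substitutions = best[3],
       deletions = best[4], insertions = best[5])
}

# Closed-form balanced two-way decomposition (equal cell sizes).
balanced_anova_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- unique(as.vector(table(a, b)))
  stopifnot(length(n) == 1L)
  grand <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  ss_a <- n * nlevels(b) * sum((ma - grand)^2)
  ss_b <- n * nlevels(a) * sum((mb - grand)^2)
  inter <- outer(ma - grand, mb - grand, `+`) + grand
  ss_ab <- n * sum((mab - inter)^2)
  ss_tot <- sum((y - grand)^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab,
       ss_error = ss_tot - ss_a - ss_b - ss_ab)
}

# Bias-corrected (type 2) moments computed straight from the formulas.
moment_oracle <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  list(
    skewness = g1 * sqrt(n * (n - 1)) / (n - 2),
    kurtosis = ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  )
}
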