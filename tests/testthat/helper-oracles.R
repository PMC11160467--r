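# Independent oracles used by unit and acceptance tests. Each is a
# deliberately naive implementation, kept separate from the package code
# paths it checks.

# Brute-force k-NN: full sort of each target's distance row, names breaking
# ties, then the mean of the first k training values.
oracle_knn <- function(D, y, targets, k) {
  train <- names(y)
  vapply(targets, function(tg) {
    d <- D[tg, train]
    ord <- order(d, train)
    mean(y[train[ord][seq_len(k)]])
  }, numeric(1))
}

# Loop-based probe filter: for each CpG count species whose BH-adjusted
# median detection p clears the threshold.
oracle_filter <- function(detection, fdr = 0.05, frac = 0.85) {
  p <- detection
  p[is.na(p)] <- 1
  q <- p
  for (i in seq_len(nrow(p))) q[i, ] <- p.adjust(p[i, ], "BH")
  need <- ceiling(frac * nrow(p))
  keep <- character(0)
  for (j in seq_len(ncol(p))) {
    cnt <- 0
    for (i in seq_len(nrow(p))) if (q[i, j] < fdr) cnt <- cnt + 1
    if (cnt >= need) keep <- c(keep, colnames(p)[j])
  }
  keep
}

# Exact two-sided rank-sum p-value by enumeration of all assignments of
# ranks to the first group (untied samples only).
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  all_r <- seq_len(n1 + n2)
  us <- apply(combos, 2, function(idx) sum(all_r[idx]) - n1 * (n1 + 1) / 2)
  if (u_obs > n1 * n2 / 2) p <- 2 * mean(us >= u_obs)
  else if (u_obs < n1 * n2 / 2) p <- 2 * mean(us <= u_obs)
  else p <- 1
  min(p, 1)
}

# Exhaustive truth table for the per-species sex verdict over up to 3
# tissues: significance patterns x sign patterns.
oracle_verdict <- function(pvals, diffs, alpha = 0.01) {
  sig_signs <- c()
  for (i in seq_along(pvals))
    if (pvals[i] <= alpha) sig_signs <- c(sig_signs, sign(diffs[i]))
  if (length(sig_signs) == 0) return(".")
  if (all(sig_signs == 1)) return("+")
  if (all(sig_signs == -1)) return("-")
  "."
}
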