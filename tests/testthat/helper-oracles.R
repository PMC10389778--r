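# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and the wrapped base functions where the package
# wraps one) so each check is a genuine dual route.

# Benjamini-Hochberg by its step-up definition: sort, multiply p_(i) by n/i,
# take cumulative minima from the largest rank, undo the sort.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Step-up rejection set at level alpha, straight from the definition.
bh_reject_bruteforce <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(n) / n * alpha)
  if (length(ks) == 0) return(integer(0))
  sort(o[seq_len(max(ks))])
}

# Upper-tail hypergeometric probability by enumerating every possible draw
# of n from N (set = first K elements of the universe).
hyper_enumerate <- function(k, N, K, n) {
  if (k == 0) return(1)
  if (k > min(K, n)) return(0)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# Welch t statistic, Satterthwaite df and two-sided p, written out in full.
welch_closed_form <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
}

# Small simulated experiment taken through normalization and both
# backgrounds' induction tests; shared by dependence and pipeline tests.
run_small_pipeline <- function(sim, ...) {
  cpm <- normalize_expression(sim$counts, "counts", "cpm")
  list(
    sim = sim,
    cpm = cpm,
    de1 = induction_test(cpm, sim$design, "WT", ...),
    de2 = induction_test(cpm, sim$design, "KO", ...)
  )
}
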