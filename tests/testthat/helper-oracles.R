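# Independent oracles and deterministic generators used across the suite.
# The brute-force scorer mirrors the scoring definition with naive loops
# and its own charge map, sharing no code with the package's vectorized
# implementation.

oracle_charges <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.5, I = 0, K = 1,
  L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0,
  W = 0, Y = 0
)

brute_register_score <- function(qs, qt, off, wd = 1, wa = 0.5) {
  s <- 0
  for (i in seq_along(qs)) {
    j <- off + i
    s <- s - wd * qs[i] * qt[j]
    if (j - 1 >= 1) s <- s - wa * qs[i] * qt[j - 1]
    if (j + 1 <= length(qt)) s <- s - wa * qs[i] * qt[j + 1]
  }
  s
}

brute_pair_score <- function(a, b, wd = 1, wa = 0.5) {
  qa <- unname(oracle_charges[strsplit(a, "")[[1]]])
  qb <- unname(oracle_charges[strsplit(b, "")[[1]]])
  if (length(qa) <= length(qb)) {
    qs <- qa; qt <- qb
  } else {
    qs <- qb; qt <- qa
  }
  best <- -Inf
  for (off in 0:(length(qt) - length(qs)))
    best <- max(best, brute_register_score(qs, qt, off, wd, wa))
  best
}

rand_seq <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Definitional Pearson formula (covariance over product of standard
# deviations) with the t-transform p-value, written independently of
# stats::cor.test.
closed_form_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE))
}

# Deterministic censored two-group survival cohorts; the frozen
# chi-square values in fixtures/logrank_reference.csv were computed from
# these same cohorts with the survival package's score test.
make_surv_cohort <- function(seed) {
  set.seed(seed)
  n_a <- sample(5:25, 1)
  n_b <- sample(5:25, 1)
  time <- round(c(rexp(n_a, 0.10), rexp(n_b, 0.15)), 1)
  event <- stats::rbinom(n_a + n_b, 1, 0.8)
  if (sum(event) == 0) event[1] <- 1
  list(time = time, event = event,
       group = rep(c("a", "b"), c(n_a, n_b)))
}
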