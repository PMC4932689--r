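# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: quantiles by bisection on the CDF, random-effects
# pooling by plain-loop arithmetic.

# Invert the Beta CDF by bracketing/bisection on pbeta, to `tol`.
oracle_beta_quantile <- function(p, a, b, tol = 1e-10) {
  lo <- 0
  hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pbeta(mid, a, b) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# DerSimonian-Laird pooling written as explicit element-wise loops
# (spreadsheet-style), independent of the package's vectorized path.
oracle_dl_pool <- function(rd, v) {
  k <- length(rd)
  w <- numeric(k)
  for (i in seq_len(k)) w[i] <- 1 / v[i]
  sw <- 0
  swr <- 0
  for (i in seq_len(k)) {
    sw <- sw + w[i]
    swr <- swr + w[i] * rd[i]
  }
  rd_fe <- swr / sw
  q <- 0
  sw2 <- 0
  for (i in seq_len(k)) {
    q <- q + w[i] * (rd[i] - rd_fe)^2
    sw2 <- sw2 + w[i]^2
  }
  tau2 <- if (k > 1) max(0, (q - (k - 1)) / (sw - sw2 / sw)) else 0
  sws <- 0
  swsr <- 0
  for (i in seq_len(k)) {
    ws <- 1 / (v[i] + tau2)
    sws <- sws + ws
    swsr <- swsr + ws * rd[i]
  }
  mu <- swsr / sws
  nu <- 1 / sws
  list(mu = mu, nu = nu, tau2 = tau2,
       z = mu / sqrt(nu), p_value = 2 * pnorm(-abs(mu / sqrt(nu))))
}

# Base design of the motivating trial: 80 centers, control-arm mean 0.3,
# treatment probability 0.225.
base_design <- function(n_per_arm, cv = 0.3, k = 80) {
  trial_design(k, 2L * n_per_arm, solve_beta_parameters(0.3, cv), 0.225)
}
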