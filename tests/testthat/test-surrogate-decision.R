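test_that("conjugate Beta updating is exact and additive", {
  expect_equal(beta_posterior(166, 530), c(alpha = 167, beta = 365))
  expect_equal(beta_posterior(5, 933), c(alpha = 6, beta = 929))
  expect_equal(beta_posterior(0, 0), c(alpha = 1, beta = 1))

  set.seed(2)
  for (i in 1:20) {
    n1 <- sample(0:50, 1); y1 <- sample(0:n1, 1)
    n2 <- sample(0:50, 1); y2 <- sample(0:n2, 1)
    step1 <- beta_posterior(y1, n1)
    step2 <- beta_posterior(y2, n2, prior_a = step1["alpha"],
                            prior_b = step1["beta"])
    expect_equal(unname(step2), unname(beta_posterior(y1 + y2, n1 + n2)))
  }
})

test_that("surrogate-link point estimates are simple stratum ratios", {
  link <- macs_link()
  expect_equal(link$n_ptb, 530L)
  expect_equal(link$y_tb, 5L)
  est <- point_estimates(link)
  expect_equal(round(unname(est), 2), c(0.31, 0.99))
  expect_equal(unname(point_estimates(surrogate_link(10, 0, 10, 0))), c(0, 1))
  expect_equal(unname(point_estimates(surrogate_link(10, 10, 10, 10))), c(1, 0))
  expect_error(point_estimates(surrogate_link(0, 0, 10, 1)), "non-empty")
})

test_that("surrogate-link counts load from JSON and CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(n_ptb = 530, y_ptb = 166, n_tb = 933, y_tb = 5),
            path, row.names = FALSE)
  link <- read_surrogate_link(path)
  expect_equal(link$y_ptb, 166L)
  # a uniform prior plus counts keeps all posterior shapes at least 1
  m <- delta_model(link, mu = -0.075, nu = 6.5e-4)
  expect_true(all(c(m$tau_ptb, m$tau_tb) >= 1))
})

test_that("delta draws multiply the surrogate effect by the link contrast", {
  m <- delta_model(macs_link(), mu = -0.075, nu = 6.5e-4)
  d1 <- sample_delta(m, 500, seed = 10)
  d2 <- sample_delta(m, 500, seed = 10)
  expect_identical(d1, d2)

  # a centered surrogate effect yields P(delta < 0) ~ 1/2, because the link
  # contrast is positive with near-certain posterior probability
  m0 <- delta_model(macs_link(), mu = 0, nu = 6.5e-4)
  frac <- mean(sample_delta(m0, 20000, seed = 3) < 0)
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(20000))

  # a sharply negative surrogate effect forces every draw negative
  mneg <- delta_model(macs_link(), mu = -0.075, nu = 1e-12)
  expect_true(all(sample_delta(mneg, 10000, seed = 4) < 0))

  # negating mu mirrors the delta distribution
  mpos <- delta_model(macs_link(), mu = 0.075, nu = 6.5e-4)
  f_neg <- mean(sample_delta(m, 20000, seed = 5) < 0)
  f_pos <- mean(sample_delta(mpos, 20000, seed = 6) < 0)
  expect_lt(abs(f_pos - (1 - f_neg)), 0.02)
})

test_that("a one-to-one surrogate link reduces delta to the surrogate effect", {
  m <- fixed_link_delta_model(1, 0, mu = -0.075, nu = 6.5e-4)
  d <- sample_delta(m, 1000, seed = 12)
  set.seed(12)
  expect_identical(d, rnorm(1000, -0.075, sqrt(6.5e-4)))
})

test_that("decision summaries report strict-negative mass and empirical intervals", {
  s <- decision_summary(c(-1, -1, 1, 1))
  expect_equal(s$prob_delta_negative, 0.5)

  s2 <- decision_summary(c(-3, -2, -1))
  expect_equal(s2$prob_delta_negative, 1)
  expect_true(all(s2$credible_interval < 0))

  set.seed(31)
  x <- rnorm(1e5)
  s3 <- decision_summary(x, interval_mass = 0.95)
  expect_equal(s3$credible_interval, qnorm(c(0.025, 0.975)), tolerance = 0.02)
  expect_equal(s3$credible_interval,
               unname(quantile(x, c(0.025, 0.975))))
})

test_that("P(delta < 0) is monotone in the surrogate effect (paired seeds)", {
  link <- macs_link()
  mus <- seq(0.05, -0.14, length.out = 20)
  fracs <- vapply(mus, function(mu) {
    m <- delta_model(link, mu = mu, nu = 6.5e-4)
    mean(sample_delta(m, 5000, seed = 77) < 0)
  }, 0)
  expect_true(all(diff(fracs) >= 0))
})

test_that("decision-performance summaries aggregate per-trial fractions", {
  d <- base_design(100, k = 10)
  perf <- evaluate_decision_performance(d, macs_link(), n_trials = 1,
                                        n_samples = 500, seed = 2)
  expect_equal(perf$mean_prob_negative, perf$records$prob_delta_negative)
  expect_equal(perf$p5_prob_negative, perf$records$prob_delta_negative)

  # null treatment effect: fractions center on 1/2 across trials
  d0 <- trial_design(20, 800, solve_beta_parameters(0.3, 0.3), 0.3)
  perf0 <- evaluate_decision_performance(d0, macs_link(), n_trials = 300,
                                         n_samples = 1000, seed = 15)
  expect_lt(abs(perf0$mean_prob_negative - 0.5), 0.06)
  expect_true(all(perf0$records$prob_delta_negative >= 0 &
                    perf0$records$prob_delta_negative <= 1))
})
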