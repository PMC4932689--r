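test_that("the analytic variance matches hand-evaluated cases and is monotone", {
  # hand evaluation: 2(0.21 + 0.174375)/1400 + (v_S + v_T)/80
  expect_equal(analytic_variance(0.3, 0.225, 0, 0, 80, 1400),
               2 * (0.21 + 0.174375) / 1400)
  expect_equal(analytic_variance(0.3, 0.225, 0.3, 0, 80, 1400),
               2 * (0.21 + 0.174375) / 1400 + 0.09^2 / 80)

  # strictly decreasing in N; in K only when between-center variance exists
  v1 <- analytic_variance(0.3, 0.225, 0.3, 0.1, 80, 1400)
  expect_lt(analytic_variance(0.3, 0.225, 0.3, 0.1, 80, 2800), v1)
  expect_lt(analytic_variance(0.3, 0.225, 0.3, 0.1, 160, 1400), v1)
  expect_equal(analytic_variance(0.3, 0.225, 0, 0, 80, 1400),
               analytic_variance(0.3, 0.225, 0, 0, 160, 1400))
})

test_that("variance sensitivity reports percent increases over the cv_T = 0 case", {
  tab <- variance_sensitivity(0.3, 0.225, 0.3, 80, 1400,
                              cv_t_values = c(0, 0.1, 0.15))
  expect_equal(tab$pct_increase[1], 0)
  expect_equal(tab$pct_increase,
               100 * (tab$V / tab$V[1] - 1))
  expect_true(all(diff(tab$V) > 0))
})

test_that("the closed-form no-interaction size behaves like the standard formula", {
  n <- closed_form_n_no_interaction(0.3, 0.225, 0.05, 0.8)
  expect_equal(n, 536.34, tolerance = 1e-4)
  # at power 0.5 the z_power term drops
  expect_equal(closed_form_n_no_interaction(0.3, 0.225, 0.05, 0.5),
               qnorm(0.975)^2 * (0.3 * 0.7 + 0.225 * 0.775) / 0.075^2)
  # quadrupling under a halved risk difference at fixed variances
  delta <- 0.075
  var_sum <- 0.3 * 0.7 + 0.225 * 0.775
  expect_equal((qnorm(0.975) + qnorm(0.8))^2 * var_sum / (delta / 2)^2,
               4 * (qnorm(0.975) + qnorm(0.8))^2 * var_sum / delta^2)
  expect_error(closed_form_n_no_interaction(0.3, 0.3), "differ")
})

test_that("power estimates are reproducible with exact Monte-Carlo error", {
  d <- base_design(100, cv = 0, k = 10)
  p1 <- estimate_power(d, n_reps = 50, seed = 6)
  p2 <- estimate_power(d, n_reps = 50, seed = 6)
  expect_identical(p1$power, p2$power)
  expect_equal(p1$mc_se, sqrt(p1$power * (1 - p1$power) / 50))
  pe <- estimate_power(d, n_reps = 1, seed = 9)
  expect_true(pe$power %in% c(0, 1))
})

test_that("power is nondecreasing in the per-arm size up to Monte-Carlo noise", {
  sizes <- c(350, 540, 750)
  pw <- vapply(sizes, function(n) {
    estimate_power(base_design(n, cv = 0), n_reps = 3000, seed = 88)$power
  }, 0)
  expect_true(all(diff(pw) > 0))
  expect_gt(pw[3], 0.85)
  expect_lt(pw[1], 0.7)
})

test_that("the type-I error is controlled in the large-center regime", {
  # null design with 400 patients per center, where the Wald/DL test is
  # asymptotically calibrated
  d <- trial_design(20, 8000, solve_beta_parameters(0.3, 0), 0.3)
  pe <- estimate_power(d, n_reps = 4000, seed = 5)
  expect_lt(abs(pe$power - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("the sample-size search returns grid multiples and is deterministic", {
  sa <- solve_beta_parameters(0.3, 0)
  res <- find_sample_size(10, sa, 0.1, step = 25, n_reps = 200, seed = 17)
  expect_equal(res$n_per_arm %% 25, 0)
  res2 <- find_sample_size(10, sa, 0.1, step = 25, n_reps = 200, seed = 17)
  expect_identical(res$n_per_arm, res2$n_per_arm)
  expect_identical(res$trace, res2$trace)
  expect_true(all(c("n_per_arm", "n_reps", "power", "mc_se", "seed") %in%
                    names(res$trace)))
})

test_that("a trivially attainable power target collapses to the lower bracket", {
  sa <- solve_beta_parameters(0.3, 0)
  # with target far below the attained power at every candidate, the search
  # walks down to the per-arm floor implied by the minimum center size
  res <- find_sample_size(10, sa, 0.225, target_power = 0.01, step = 10,
                          n_reps = 100, seed = 4, min_per_center = 6,
                          n_start = 100)
  expect_equal(res$n_per_arm, 30)
})

test_that("the search errors with a trace when the target is out of reach", {
  sa <- solve_beta_parameters(0.3, 0)
  expect_error(
    find_sample_size(10, sa, 0.29, target_power = 0.99, step = 50,
                     n_reps = 50, seed = 2, n_start = 50, n_max = 200),
    "did not reach")
})
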