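# One replicate of the power engine: simulate a trial under `design` and
# return whether the pooled risk difference is significant at `alpha`.
.replicate_significant <- function(design, alpha) {
  cnt <- .sim_counts(design)
  eff <- .rd_effects(cnt$n_S, cnt$y_S, cnt$n_T, cnt$y_T)
  .dl_pool(eff$rd, eff$var)$p_value < alpha
}

#' Empirical power of a multicenter design
#'
#' Simulates `n_reps` independent trials under `design`, analyzes each with
#' the DerSimonian-Laird random-effects risk-difference model, and returns
#' the fraction of replicates reaching two-sided significance at `alpha`.
#'
#' Replicate `r` reseeds the RNG at `seed + r`, so any single replicate can
#' be reproduced in isolation and reruns with the same seed are
#' bit-identical.
#'
#' @param design A [trial_design()].
#' @param alpha Two-sided significance level.
#' @param n_reps Number of simulated trials.
#' @param seed Integer master seed.
#' @return An object of class `power_estimate`: list with `design`,
#'   `n_reps`, `power`, `mc_se` (binomial Monte-Carlo standard error
#'   `sqrt(power(1-power)/n_reps)`), `alpha`, `seed`.
#' @examples
#' d <- trial_design(20, 400, solve_beta_parameters(0.3, 0.3), 0.225)
#' estimate_power(d, n_reps = 200, seed = 1)
#' @export
estimate_power <- function(design, alpha = 0.05, n_reps = 10000L, seed) {
  stopifnot(inherits(design, "trial_design"), n_reps >= 1,
            is.numeric(seed), length(seed) == 1L)
  n_reps <- as.integer(n_reps)
  sig <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(.fold_seed(seed + r))
    sig[r] <- .replicate_significant(design, alpha)
  }
  pw <- mean(sig)
  out <- list(design = design, n_reps = n_reps, power = pw,
              mc_se = sqrt(pw * (1 - pw) / n_reps),
              alpha = alpha, seed = seed)
  class(out) <- "power_estimate"
  out
}

#' @export
print.power_estimate <- function(x, ...) {
  cat("Empirical power:", format(x$power, digits = 4),
      "(MC se", format(x$mc_se, digits = 3), ")",
      "from", x$n_reps, "replicates at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Closed-form per-arm sample size ignoring between-center variation
#'
#' Standard two-proportion approximation
#' \deqn{n = (z_{1-\alpha/2} + z_{power})^2
#'       \frac{\pi_S(1-\pi_S) + \pi_T(1-\pi_T)}{(\pi_S - \pi_T)^2},}
#' used to initialize the simulation search and as a cross-check of the
#' no-interaction case.
#'
#' @param pi_S,pi_T Control- and treatment-arm event probabilities
#'   (must differ).
#' @param alpha Two-sided type-I error probability.
#' @param power Target power.
#' @return Required per-arm sample size (real, not rounded).
#' @examples
#' closed_form_n_no_interaction(0.3, 0.225)  # ~536.4
#' @export
closed_form_n_no_interaction <- function(pi_S, pi_T, alpha = 0.05,
                                         power = 0.8) {
  stopifnot(pi_S > 0, pi_S < 1, pi_T > 0, pi_T < 1,
            alpha > 0, alpha < 1, power > 0, power < 1)
  if (pi_S == pi_T)
    stop("pi_S and pi_T must differ")
  (qnorm(1 - alpha / 2) + qnorm(power))^2 *
    (pi_S * (1 - pi_S) + pi_T * (1 - pi_T)) / (pi_S - pi_T)^2
}

#' Grid search for the required per-arm sample size
#'
#' Finds the smallest per-arm sample size, on a grid of multiples of
#' `step`, whose empirical power reaches `target_power`. The search starts
#' from the closed-form no-interaction approximation (rounded up to the
#' grid) and walks the grid monotonically: up while power is below target,
#' or down while it stays at or above. The returned size is therefore the
#' first grid point whose estimated power at `n_reps` replicates is at
#' least `target_power`.
#'
#' Candidate `n` uses the seed block `seed + (n/step) * 1e5`, so distinct
#' candidates share no replicate streams and any cell of a sample-size
#' table can be reproduced in isolation.
#'
#' @param k_centers Number of centers.
#' @param standard_arm A [`beta_spec`][solve_beta_parameters] for the
#'   control arm.
#' @param pi_t Treatment-arm event probability.
#' @param alpha Two-sided significance level.
#' @param target_power Required power (default 0.8).
#' @param step Grid step in patients per arm (default 10).
#' @param n_reps Replicates per candidate size.
#' @param seed Integer master seed.
#' @param min_per_center Minimum patients per center.
#' @param treatment_arm_cv Between-center CV of the treatment-arm
#'   probability.
#' @param n_start Optional starting per-arm size; defaults to the
#'   closed-form approximation (required when `pi_t` equals the control
#'   mean, where the closed form is undefined).
#' @param n_max Upper search bound per arm (default `100 * step +
#'   20 * n_start`); exceeding it is a search error.
#' @return An object of class `sample_size_search`: list with `n_per_arm`,
#'   `target_power`, `trace` (data frame: `n_per_arm`, `n_reps`, `power`,
#'   `mc_se`, `seed`), and the search parameters.
#' @export
find_sample_size <- function(k_centers, standard_arm, pi_t, alpha = 0.05,
                             target_power = 0.8, step = 10L,
                             n_reps = 10000L, seed,
                             min_per_center = 6L, treatment_arm_cv = 0,
                             n_start = NULL, n_max = NULL) {
  stopifnot(step >= 1, target_power > 0, target_power < 1)
  step <- as.integer(step)
  # per-arm lower bound implied by the minimum-center-size constraint
  n_floor_raw <- ceiling(k_centers * min_per_center / 2)
  n_floor <- as.integer(ceiling(n_floor_raw / step) * step)
  if (is.null(n_start)) {
    n_start <- closed_form_n_no_interaction(standard_arm$mean, pi_t,
                                            alpha, target_power)
  }
  n_start <- as.integer(max(ceiling(n_start / step) * step, n_floor))
  if (is.null(n_max))
    n_max <- 100L * step + 20L * n_start
  trace <- list()
  eval_power <- function(n_arm) {
    d <- trial_design(k_centers, 2L * n_arm, standard_arm, pi_t,
                      min_per_center = min_per_center,
                      treatment_arm_cv = treatment_arm_cv)
    cand_seed <- seed + (n_arm %/% step) * 1e5
    pe <- estimate_power(d, alpha = alpha, n_reps = n_reps, seed = cand_seed)
    trace[[length(trace) + 1L]] <<- data.frame(
      n_per_arm = n_arm, n_reps = n_reps, power = pe$power,
      mc_se = pe$mc_se, seed = cand_seed)
    pe$power
  }
  n <- n_start
  pw <- eval_power(n)
  if (pw >= target_power) {
    while (n - step >= n_floor) {
      pw_lower <- eval_power(n - step)
      if (pw_lower < target_power) break
      n <- n - step
    }
  } else {
    repeat {
      n <- n + step
      if (n > n_max) {
        tr <- do.call(rbind, trace)
        stop("sample-size search did not reach power ", target_power,
             " by n_max = ", n_max, " per arm; trace:\n",
             paste(utils::capture.output(print(tr)), collapse = "\n"))
      }
      if (eval_power(n) >= target_power) break
    }
  }
  out <- list(n_per_arm = n, target_power = target_power,
              trace = do.call(rbind, trace),
              k_centers = k_centers, standard_arm = standard_arm,
              pi_t = pi_t, alpha = alpha, step = step,
              n_reps = n_reps, seed = seed)
  class(out) <- "sample_size_search"
  out
}

#' @export
print.sample_size_search <- function(x, ...) {
  cat("Required per-arm sample size:", x$n_per_arm,
      "(target power", x$target_power, ",", x$n_reps,
      "replicates per candidate)\n")
  cat("Search trace:\n")
  print(x$trace[order(x$trace$n_per_arm), ], row.names = FALSE)
  invisible(x)
}

#' Closed-form variance of the estimated treatment effect
#'
#' Under equal center sizes `n = N/K`, the variance of the pooled risk
#' difference decomposes into a between-patient and a between-center part:
#' \deqn{V = \frac{2(\sigma_S^2 + \sigma_T^2)}{N} + \frac{v_S + v_T}{K},}
#' where `sigma_i^2 = pi_i (1 - pi_i)` is the between-patient variance and
#' `v_i = (pi_i * CV_i)^2` the between-center variance of arm `i`'s event
#' probability. The between-center term is divided by the number of centers
#' `K`, not the number of patients, which is why more centers (at fixed N)
#' shrink the penalty for treatment-by-center interaction.
#'
#' @param pi_S,pi_T Event probabilities in the standard and treatment arms.
#' @param cv_S,cv_T Between-center CVs of the two arms' probabilities.
#' @param k_centers Number of centers `K`.
#' @param n_total Total sample size `N` (both arms).
#' @return The variance `V` of the estimated treatment effect.
#' @examples
#' analytic_variance(0.3, 0.225, 0, 0, 80, 1400)    # 5.49e-4
#' analytic_variance(0.3, 0.225, 0.3, 0, 80, 1400)  # 6.50e-4
#' @export
analytic_variance <- function(pi_S, pi_T, cv_S = 0, cv_T = 0,
                              k_centers, n_total) {
  stopifnot(pi_S > 0, pi_S < 1, pi_T > 0, pi_T < 1,
            cv_S >= 0, cv_T >= 0, k_centers >= 1, n_total >= 1)
  sigma2_S <- pi_S * (1 - pi_S)
  sigma2_T <- pi_T * (1 - pi_T)
  v_S <- (pi_S * cv_S)^2
  v_T <- (pi_T * cv_T)^2
  2 * (sigma2_S + sigma2_T) / n_total + (v_S + v_T) / k_centers
}

#' Sensitivity of the analytic variance to treatment-arm interaction
#'
#' Evaluates [analytic_variance()] over a grid of treatment-arm CVs and
#' reports each variance together with its percent increase over the
#' `cv_T = 0` case (all other inputs held fixed). Quantifies how robust a
#' design is to the assumption of no between-center variation in the
#' treatment arm.
#'
#' @param pi_S,pi_T,cv_S,k_centers,n_total As in [analytic_variance()].
#' @param cv_t_values Treatment-arm CVs to evaluate.
#' @return Data frame with columns `cv_T`, `V`, `pct_increase`.
#' @examples
#' variance_sensitivity(0.3, 0.225, 0.3, 80, 1400,
#'                      cv_t_values = c(0, 0.1, 0.15))
#' @export
variance_sensitivity <- function(pi_S, pi_T, cv_S, k_centers, n_total,
                                 cv_t_values = c(0, 0.05, 0.1, 0.15, 0.2)) {
  v0 <- analytic_variance(pi_S, pi_T, cv_S, 0, k_centers, n_total)
  v <- vapply(cv_t_values, function(ct)
    analytic_variance(pi_S, pi_T, cv_S, ct, k_centers, n_total), 0)
  data.frame(cv_T = cv_t_values, V = v, pct_increase = 100 * (v / v0 - 1))
}
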