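#' Required sample size over a CV-by-centers grid
#'
#' Runs [find_sample_size()] for every combination of between-center CV and
#' number of centers, reproducing the design table of required per-arm
#' sizes. The first column reports, per CV, the probability that a center's
#' control probability exceeds the treatment probability `pi_t`.
#'
#' Cells whose search fails to converge within `n_max` are returned as `NA`
#' with a warning (the smallest grids at large CVs can require sample sizes
#' far beyond any practical bound).
#'
#' @param cvs Between-center CVs of the control probability.
#' @param ks Numbers of clinical centers.
#' @param mean Mean control-arm event probability.
#' @param pi_t Treatment-arm event probability.
#' @param alpha,target_power,step,n_reps,min_per_center,n_max As in
#'   [find_sample_size()].
#' @param seed Integer master seed; each cell derives its own seed block.
#' @return Data frame with columns `cv`, `tail_prob` (P(center probability
#'   > `pi_t`)), and one column `K<k>` per center count.
#' @export
table1_grid <- function(cvs = c(0, 0.1, 0.2, 0.3, 0.4),
                        ks = c(20, 40, 60, 80, 100),
                        mean = 0.3, pi_t = 0.225, alpha = 0.05,
                        target_power = 0.8, step = 10L, n_reps = 10000L,
                        seed, min_per_center = 6L, n_max = 5000L) {
  out <- data.frame(cv = cvs,
                    tail_prob = vapply(cvs, function(cv)
                      tail_probability(solve_beta_parameters(mean, cv), pi_t),
                      0))
  for (j in seq_along(ks)) {
    col <- integer(length(cvs))
    for (i in seq_along(cvs)) {
      cell_seed <- seed + 1e7 * ((i - 1L) * length(ks) + j)
      col[i] <- tryCatch(
        find_sample_size(ks[j], solve_beta_parameters(mean, cvs[i]), pi_t,
                         alpha = alpha, target_power = target_power,
                         step = step, n_reps = n_reps, seed = cell_seed,
                         min_per_center = min_per_center,
                         n_max = n_max)$n_per_arm,
        error = function(e) {
          warning("cell cv = ", cvs[i], ", K = ", ks[j],
                  " did not converge: ", conditionMessage(e), call. = FALSE)
          NA_integer_
        })
    }
    out[[paste0("K", ks[j])]] <- col
  }
  out
}

#' Decision-rule performance over a CV-by-centers grid
#'
#' Runs [evaluate_decision_performance()] at a fixed per-arm size for every
#' combination of between-center CV and number of centers, reporting per
#' cell the mean and the 5th percentile of the posterior probability that
#' treatment reduces the clinical outcome.
#'
#' @param cvs,ks,mean,pi_t As in [table1_grid()].
#' @param n_per_arm Per-arm sample size held fixed across cells
#'   (default 700).
#' @param link Surrogate-link counts (default [macs_link()]).
#' @param n_trials,n_samples Simulation sizes per cell.
#' @param seed Integer master seed; each cell derives its own seed block.
#' @param min_per_center Minimum patients per center.
#' @return Data frame with columns `cv`, `tail_prob`, and per center count
#'   `K<k>_mean` and `K<k>_p5`.
#' @export
table2_grid <- function(cvs = c(0, 0.1, 0.2, 0.3, 0.4),
                        ks = c(20, 40, 60, 80, 100),
                        mean = 0.3, pi_t = 0.225, n_per_arm = 700L,
                        link = macs_link(), n_trials = 1000L,
                        n_samples = 10000L, seed, min_per_center = 6L) {
  out <- data.frame(cv = cvs,
                    tail_prob = vapply(cvs, function(cv)
                      tail_probability(solve_beta_parameters(mean, cv), pi_t),
                      0))
  for (j in seq_along(ks)) {
    m <- p5 <- numeric(length(cvs))
    for (i in seq_along(cvs)) {
      d <- trial_design(ks[j], 2L * n_per_arm,
                        solve_beta_parameters(mean, cvs[i]), pi_t,
                        min_per_center = min_per_center)
      cell_seed <- seed + 1e7 * ((i - 1L) * length(ks) + j)
      perf <- evaluate_decision_performance(d, link, n_trials = n_trials,
                                            n_samples = n_samples,
                                            seed = cell_seed)
      m[i] <- perf$mean_prob_negative
      p5[i] <- perf$p5_prob_negative
    }
    out[[paste0("K", ks[j], "_mean")]] <- m
    out[[paste0("K", ks[j], "_p5")]] <- p5
  }
  out
}
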