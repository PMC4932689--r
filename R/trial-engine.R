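#' Specify a multicenter two-arm trial design
#'
#' Bundles every parameter needed to simulate one trial: patients are
#' allocated at random to `k_centers` centers (each guaranteed at least
#' `min_per_center` patients), randomized 1:1 within center, and outcomes are
#' Bernoulli with a center-specific control probability drawn from
#' `standard_arm` and a treatment probability `pi_t` that is fixed across
#' centers unless `treatment_arm_cv > 0`.
#'
#' @param k_centers Number of clinical centers (at least 2).
#' @param n_total Total sample size, both arms combined; must be at least
#'   `k_centers * min_per_center`.
#' @param standard_arm A [`beta_spec`][solve_beta_parameters] describing the
#'   between-center distribution of the control-arm event probability.
#' @param pi_t Treatment-arm event probability in (0, 1).
#' @param min_per_center Minimum number of patients per center (default 6).
#' @param treatment_arm_cv Between-center CV of the treatment-arm probability
#'   (default 0, i.e. no between-center variation in the treatment arm).
#' @return An object of class `trial_design`.
#' @examples
#' trial_design(80, 1400, solve_beta_parameters(0.3, 0.3), pi_t = 0.225)
#' @export
trial_design <- function(k_centers, n_total, standard_arm, pi_t,
                         min_per_center = 6L, treatment_arm_cv = 0) {
  stopifnot(is.numeric(k_centers), length(k_centers) == 1L, k_centers >= 2,
            is.numeric(n_total), length(n_total) == 1L,
            inherits(standard_arm, "beta_spec"),
            is.numeric(pi_t), length(pi_t) == 1L, pi_t > 0, pi_t < 1,
            is.numeric(min_per_center), min_per_center >= 2,
            is.numeric(treatment_arm_cv), treatment_arm_cv >= 0)
  k_centers <- as.integer(k_centers)
  n_total <- as.integer(n_total)
  min_per_center <- as.integer(min_per_center)
  if (n_total < k_centers * min_per_center)
    stop("n_total (", n_total, ") must be at least k_centers * min_per_center = ",
         k_centers * min_per_center)
  treatment_arm <- if (treatment_arm_cv > 0)
    solve_beta_parameters(pi_t, treatment_arm_cv) else NULL
  out <- list(k_centers = k_centers, n_total = n_total,
              standard_arm = standard_arm, pi_t = pi_t,
              min_per_center = min_per_center,
              treatment_arm_cv = treatment_arm_cv,
              treatment_arm = treatment_arm)
  class(out) <- "trial_design"
  out
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Multicenter trial design\n")
  cat("  centers:", x$k_centers, "  total n:", x$n_total,
      " (min", x$min_per_center, "per center)\n")
  cat("  control arm: mean", format(x$standard_arm$mean),
      "cv", format(x$standard_arm$cv), "\n")
  cat("  treatment arm: pi_T =", format(x$pi_t),
      if (x$treatment_arm_cv > 0) paste("cv", format(x$treatment_arm_cv))
      else "(fixed across centers)", "\n")
  invisible(x)
}

#' Random allocation of patients to centers
#'
#' Every center receives `min_per_center` patients deterministically; the
#' surplus `n_total - k * min_per_center` is distributed with equal
#' probability among centers (multinomial). This honors the minimum-size
#' constraint without rejection sampling.
#'
#' @param n_total Total number of patients.
#' @param k Number of centers.
#' @param min_per_center Minimum patients per center.
#' @return Integer vector of `k` center sizes, each at least
#'   `min_per_center`, summing to `n_total`.
#' @export
allocate_centers <- function(n_total, k, min_per_center = 6L) {
  stopifnot(n_total >= 1, k >= 1)
  n_total <- as.integer(n_total)
  k <- as.integer(k)
  min_per_center <- as.integer(min_per_center)
  surplus <- n_total - k * min_per_center
  if (surplus < 0)
    stop("infeasible allocation: n_total = ", n_total,
         " < k * min_per_center = ", k * min_per_center)
  if (surplus == 0L)
    return(rep.int(min_per_center, k))
  min_per_center + as.integer(rmultinom(1L, surplus, rep.int(1, k)))
}

#' 1:1 stratified-blocked randomization within a center
#'
#' Splits a center of `center_size` patients half/half between the standard
#' and treatment arms. For odd sizes the extra patient's arm is a fair coin
#' flip, keeping the arms exchangeable.
#'
#' @param center_size Number of patients in the center.
#' @return Named integer vector `c(n_S = , n_T = )` with
#'   `n_S + n_T = center_size` and `|n_S - n_T| <= 1`.
#' @export
randomize_within_center <- function(center_size) {
  stopifnot(length(center_size) == 1L, center_size >= 1)
  center_size <- as.integer(center_size)
  n_s <- center_size %/% 2L
  if (center_size %% 2L == 1L)
    n_s <- n_s + rbinom(1L, 1L, 0.5)
  c(n_S = n_s, n_T = center_size - n_s)
}

# Vectorized arm split for all centers at once.
.split_arms <- function(sizes) {
  n_s <- sizes %/% 2L
  odd <- sizes %% 2L == 1L
  if (any(odd))
    n_s[odd] <- n_s[odd] + rbinom(sum(odd), 1L, 0.5)
  list(n_S = n_s, n_T = sizes - n_s)
}

# Core per-trial draw shared by simulate_trial() and the power loop.
# Returns bare per-center count vectors; no class dispatch for speed.
.sim_counts <- function(design) {
  k <- design$k_centers
  sizes <- allocate_centers(design$n_total, k, design$min_per_center)
  arms <- .split_arms(sizes)
  pi_s <- sample_center_probabilities(design$standard_arm, k)
  y_s <- rbinom(k, arms$n_S, pi_s)
  pi_tc <- if (is.null(design$treatment_arm)) rep.int(design$pi_t, k)
           else rbeta(k, design$treatment_arm$a, design$treatment_arm$b)
  y_t <- rbinom(k, arms$n_T, pi_tc)
  list(n_S = arms$n_S, y_S = y_s, n_T = arms$n_T, y_T = y_t, pi_S = pi_s)
}

#' Simulate one multicenter trial
#'
#' Allocates patients to centers, randomizes 1:1 within center, draws each
#' center's latent control probability from the design's between-center
#' model, and generates Bernoulli (binomial per center) outcome counts.
#'
#' @param design A [trial_design()].
#' @param seed Optional integer seed; if supplied the trial is fully
#'   reproducible, otherwise the current RNG stream is used.
#' @return An object of class `simulated_trial`: a list with `counts` (a
#'   data frame with columns `center`, `n_S`, `y_S`, `n_T`, `y_T`,
#'   `pi_S_latent`), the generating `design`, and `seed`.
#' @examples
#' d <- trial_design(20, 400, solve_beta_parameters(0.3, 0.3), 0.225)
#' tr <- simulate_trial(d, seed = 1)
#' head(tr$counts)
#' @export
simulate_trial <- function(design, seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (!is.null(seed))
    set.seed(.fold_seed(seed))
  cnt <- .sim_counts(design)
  counts <- data.frame(center = seq_len(design$k_centers),
                       n_S = cnt$n_S, y_S = cnt$y_S,
                       n_T = cnt$n_T, y_T = cnt$y_T,
                       pi_S_latent = cnt$pi_S)
  out <- list(counts = counts, design = design,
              seed = if (is.null(seed)) NA_integer_ else seed)
  class(out) <- "simulated_trial"
  out
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat("Simulated multicenter trial:", x$design$k_centers, "centers,",
      x$design$n_total, "patients",
      if (!is.na(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  cat("  pooled control events:", sum(x$counts$y_S), "/", sum(x$counts$n_S),
      "  treatment events:", sum(x$counts$y_T), "/", sum(x$counts$n_T), "\n")
  invisible(x)
}

# Seeds derived by counter offsets can exceed .Machine$integer.max; fold
# them back into the valid range for set.seed().
.fold_seed <- function(seed) {
  as.integer(round(seed) %% 2147483647)
}

#' Write / read per-center trial counts as CSV
#'
#' The CSV carries columns `center`, `n_S`, `y_S`, `n_T`, `y_T`,
#' `pi_S_latent` (the latent column is optional on read) and can be fed back
#' to [analyze_trial()].
#'
#' @param trial A `simulated_trial` (or a data frame with the columns above).
#' @param path File path.
#' @return `read_trial_counts()` returns the counts data frame.
#' @export
write_trial_csv <- function(trial, path) {
  counts <- if (inherits(trial, "simulated_trial")) trial$counts else trial
  stopifnot(all(c("center", "n_S", "y_S", "n_T", "y_T") %in% names(counts)))
  write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_counts <- function(path) {
  counts <- read.csv(path, comment.char = "#")
  need <- c("center", "n_S", "y_S", "n_T", "y_T")
  if (!all(need %in% names(counts)))
    stop("trial CSV must contain columns: ", paste(need, collapse = ", "))
  counts
}
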