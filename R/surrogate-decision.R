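#' Surrogate-link counts
#'
#' A 2x2 table linking surrogate status to the clinical outcome in an
#' external cohort: among `n_ptb` preterm births, `y_ptb` experienced the
#' clinical outcome (perinatal mortality/morbidity); among `n_tb` term
#' births, `y_tb` did.
#'
#' @param n_ptb,y_ptb Preterm births and clinical events among them.
#' @param n_tb,y_tb Term births and clinical events among them.
#' @return An object of class `surrogate_link`.
#' @examples
#' surrogate_link(530, 166, 933, 5)
#' @export
surrogate_link <- function(n_ptb, y_ptb, n_tb, y_tb) {
  stopifnot(n_ptb >= 0, n_tb >= 0,
            y_ptb >= 0, y_ptb <= n_ptb, y_tb >= 0, y_tb <= n_tb)
  out <- list(n_ptb = as.integer(n_ptb), y_ptb = as.integer(y_ptb),
              n_tb = as.integer(n_tb), y_tb = as.integer(y_tb))
  class(out) <- "surrogate_link"
  out
}

#' @export
print.surrogate_link <- function(x, ...) {
  cat("Surrogate-link counts\n")
  cat("  preterm:", x$y_ptb, "events /", x$n_ptb, "\n")
  cat("  term:   ", x$y_tb, "events /", x$n_tb, "\n")
  invisible(x)
}

#' Bundled MACS surrogate-link counts
#'
#' The counts from the MACS cohort of 1463 singleton pregnancies: 530
#' preterm births of which 166 experienced perinatal mortality/morbidity,
#' and 933 term births of which 5 did. Shipped as a plain JSON fixture in
#' `inst/extdata/macs_counts.json`.
#'
#' @return A [surrogate_link()] object.
#' @examples
#' macs_link()
#' @export
macs_link <- function() {
  read_surrogate_link(system.file("extdata", "macs_counts.json",
                                  package = "mctrialsim", mustWork = TRUE))
}

#' Read surrogate-link counts from JSON or CSV
#'
#' Accepts either a JSON object or a one-row CSV with fields
#' `n_ptb`, `y_ptb`, `n_tb`, `y_tb`.
#'
#' @param path File path.
#' @return A [surrogate_link()] object.
#' @export
read_surrogate_link <- function(path) {
  x <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    as.list(read.csv(path)[1L, ])
  } else {
    jsonlite::fromJSON(path)
  }
  surrogate_link(x$n_ptb, x$y_ptb, x$n_tb, x$y_tb)
}

#' Conjugate Beta posterior for a binomial probability
#'
#' With `y` events in `n` trials and a `Beta(prior_a, prior_b)` prior, the
#' posterior is `Beta(prior_a + y, prior_b + n - y)`.
#'
#' @param y,n Event count and number of trials, `0 <= y <= n`.
#' @param prior_a,prior_b Prior shape parameters (default the uniform
#'   `Beta(1, 1)`).
#' @return Named numeric vector `c(alpha = , beta = )`.
#' @examples
#' beta_posterior(166, 530)  # Beta(167, 365)
#' beta_posterior(5, 933)    # Beta(6, 929)
#' @export
beta_posterior <- function(y, n, prior_a = 1, prior_b = 1) {
  stopifnot(y >= 0, y <= n, prior_a > 0, prior_b > 0)
  c(alpha = prior_a + y, beta = prior_b + n - y)
}

#' Point estimates from surrogate-link counts
#'
#' The probability of the clinical outcome given preterm birth,
#' `y_ptb / n_ptb`, and the probability of freedom from the clinical
#' outcome given term birth, `(n_tb - y_tb) / n_tb`.
#'
#' @param link A [surrogate_link()].
#' @return Named numeric vector
#'   `c(p_event_given_preterm = , p_free_given_term = )`.
#' @examples
#' point_estimates(surrogate_link(530, 166, 933, 5))  # 0.31, 0.99
#' @export
point_estimates <- function(link) {
  stopifnot(inherits(link, "surrogate_link"))
  if (link$n_ptb == 0L || link$n_tb == 0L)
    stop("both strata must be non-empty")
  c(p_event_given_preterm = link$y_ptb / link$n_ptb,
    p_free_given_term = (link$n_tb - link$y_tb) / link$n_tb)
}

#' Bayesian model for the clinical-outcome risk difference
#'
#' The between-arm difference in the probability of the clinical outcome
#' decomposes as
#' \deqn{\Delta = (\pi_{ptb|T} - \pi_{ptb|S}) \times
#'       (\tau_{pmm|ptb} - \tau_{pmm|tb}),}
#' the surrogate risk difference times the difference in clinical-outcome
#' probabilities given surrogate status. The surrogate effect carries a
#' Normal(`mu`, `nu`) posterior (typically the pooled risk difference and
#' its variance from [analyze_trial()] under an uninformative normal
#' prior); the two conditional probabilities carry conjugate Beta
#' posteriors built from the surrogate-link counts.
#'
#' @param link A [surrogate_link()].
#' @param mu Posterior mean of the surrogate risk difference
#'   (treatment minus standard).
#' @param nu Posterior variance of the surrogate risk difference; positive.
#' @param prior Length-2 prior shapes for both Beta posteriors (default
#'   `c(1, 1)`, the uniform prior).
#' @return An object of class `delta_model`: list with `tau_ptb` and
#'   `tau_tb` (each `c(alpha, beta)`), `mu`, `nu`.
#' @examples
#' delta_model(macs_link(), mu = -0.075, nu = 6.5e-4)
#' @export
delta_model <- function(link, mu, nu, prior = c(1, 1)) {
  stopifnot(inherits(link, "surrogate_link"),
            is.numeric(mu), length(mu) == 1L,
            is.numeric(nu), length(nu) == 1L, nu > 0,
            length(prior) == 2L, all(prior > 0))
  out <- list(tau_ptb = beta_posterior(link$y_ptb, link$n_ptb,
                                       prior[1], prior[2]),
              tau_tb = beta_posterior(link$y_tb, link$n_tb,
                                      prior[1], prior[2]),
              mu = mu, nu = nu)
  class(out) <- "delta_model"
  out
}

#' Decision model with the conditional-outcome probabilities held fixed
#'
#' Degenerate variant of [delta_model()] in which the clinical-outcome
#' probabilities given surrogate status are known constants instead of Beta
#' posteriors. With `tau_ptb = 1` and `tau_tb = 0` (a one-to-one
#' correspondence between surrogate and clinical outcome) the
#' clinical-outcome risk difference equals the surrogate risk difference
#' exactly, and [sample_delta()] returns the surrogate-effect draws
#' unchanged.
#'
#' @param tau_ptb,tau_tb Fixed clinical-outcome probabilities given preterm
#'   and term birth, each in \[0, 1\].
#' @param mu,nu Surrogate-effect posterior mean and variance.
#' @return A `delta_model` with element `fixed_tau` set.
#' @export
fixed_link_delta_model <- function(tau_ptb, tau_tb, mu, nu) {
  stopifnot(tau_ptb >= 0, tau_ptb <= 1, tau_tb >= 0, tau_tb <= 1,
            is.numeric(mu), length(mu) == 1L, nu > 0)
  out <- list(fixed_tau = c(tau_ptb = tau_ptb, tau_tb = tau_tb),
              mu = mu, nu = nu)
  class(out) <- "delta_model"
  out
}

#' @export
print.delta_model <- function(x, ...) {
  if (!is.null(x$fixed_tau)) {
    cat("Clinical-outcome decision model (fixed link)\n")
    cat("  surrogate effect ~ Normal(", format(x$mu, digits = 4), ", ",
        format(x$nu, digits = 4), ")\n", sep = "")
    cat("  tau_pmm|ptb =", x$fixed_tau[1], " tau_pmm|tb =", x$fixed_tau[2],
        "\n")
    return(invisible(x))
  }
  cat("Clinical-outcome decision model\n")
  cat("  surrogate effect ~ Normal(", format(x$mu, digits = 4), ", ",
      format(x$nu, digits = 4), ")\n", sep = "")
  cat("  tau_pmm|ptb ~ Beta(", x$tau_ptb[1], ", ", x$tau_ptb[2], ")\n",
      sep = "")
  cat("  tau_pmm|tb  ~ Beta(", x$tau_tb[1], ", ", x$tau_tb[2], ")\n",
      sep = "")
  invisible(x)
}

#' Monte-Carlo samples of the clinical-outcome risk difference
#'
#' Each draw multiplies one Normal(`mu`, `nu`) draw of the surrogate risk
#' difference by the difference of one draw from each conditional-outcome
#' Beta posterior. Draws are independent across samples.
#'
#' @param model A [delta_model()].
#' @param n_samples Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_samples` draws of the clinical-outcome risk
#'   difference.
#' @export
sample_delta <- function(model, n_samples, seed = NULL) {
  stopifnot(inherits(model, "delta_model"), n_samples >= 1)
  if (!is.null(seed))
    set.seed(.fold_seed(seed))
  n_samples <- as.integer(n_samples)
  surr <- rnorm(n_samples, model$mu, sqrt(model$nu))
  if (!is.null(model$fixed_tau))
    return(surr * (model$fixed_tau[["tau_ptb"]] - model$fixed_tau[["tau_tb"]]))
  t_ptb <- rbeta(n_samples, model$tau_ptb[1], model$tau_ptb[2])
  t_tb <- rbeta(n_samples, model$tau_tb[1], model$tau_tb[2])
  surr * (t_ptb - t_tb)
}

#' Summarize posterior draws of the clinical-outcome risk difference
#'
#' Reports the strictly-negative fraction (the posterior probability that
#' treatment reduces the clinical outcome) and an equal-tailed empirical
#' credible interval.
#'
#' @param samples Numeric vector of posterior draws.
#' @param interval_mass Credible-interval mass (default 0.95).
#' @return An object of class `decision_result`: list with
#'   `prob_delta_negative`, `credible_interval` (length-2), `interval_mass`,
#'   `n_samples`.
#' @examples
#' decision_summary(rnorm(1e4, -0.02, 0.01))
#' @export
decision_summary <- function(samples, interval_mass = 0.95) {
  stopifnot(is.numeric(samples), length(samples) >= 1,
            interval_mass > 0, interval_mass < 1)
  lo <- (1 - interval_mass) / 2
  ci <- unname(quantile(samples, c(lo, 1 - lo)))
  out <- list(prob_delta_negative = mean(samples < 0),
              credible_interval = ci,
              interval_mass = interval_mass,
              n_samples = length(samples))
  class(out) <- "decision_result"
  out
}

#' @export
print.decision_result <- function(x, ...) {
  cat("Posterior decision summary (", x$n_samples, " draws)\n", sep = "")
  cat("  P(delta < 0) =", format(x$prob_delta_negative, digits = 4), "\n")
  cat("  ", format(100 * x$interval_mass), "% credible interval: [",
      format(x$credible_interval[1], digits = 4), ", ",
      format(x$credible_interval[2], digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Operating characteristics of the surrogate-based decision rule
#'
#' Nested simulation: each of `n_trials` trials is simulated under
#' `design`, analyzed with the random-effects risk-difference model to get
#' the surrogate-effect posterior Normal(`mu`, `nu`), combined with the
#' surrogate-link Beta posteriors into a [delta_model()], and `n_samples`
#' draws of the clinical-outcome risk difference are taken; the negative
#' fraction is recorded per trial. The summary reports the mean and the
#' empirical 5th percentile of those fractions across trials.
#'
#' Trial `r` reseeds the RNG at `seed + r` (simulation, analysis and
#' posterior sampling share that stream), so individual trials are
#' reproducible in isolation.
#'
#' @param design A [trial_design()].
#' @param link A [surrogate_link()].
#' @param n_trials Number of simulated trials.
#' @param n_samples Posterior draws per trial.
#' @param seed Integer master seed.
#' @param prior Prior shapes for the link posteriors.
#' @return An object of class `decision_performance`: list with
#'   `mean_prob_negative`, `p5_prob_negative` (empirical 5th percentile),
#'   `records` (data frame: `trial`, `mu`, `nu`, `tau2`,
#'   `prob_delta_negative`), `n_trials`, `n_samples`, `seed`.
#' @export
evaluate_decision_performance <- function(design, link, n_trials = 1000L,
                                          n_samples = 10000L, seed,
                                          prior = c(1, 1)) {
  stopifnot(inherits(design, "trial_design"), inherits(link, "surrogate_link"),
            n_trials >= 1, n_samples >= 1)
  n_trials <- as.integer(n_trials)
  n_samples <- as.integer(n_samples)
  tau_ptb <- beta_posterior(link$y_ptb, link$n_ptb, prior[1], prior[2])
  tau_tb <- beta_posterior(link$y_tb, link$n_tb, prior[1], prior[2])
  mu <- nu <- tau2 <- frac <- numeric(n_trials)
  for (r in seq_len(n_trials)) {
    set.seed(.fold_seed(seed + r))
    cnt <- .sim_counts(design)
    eff <- .rd_effects(cnt$n_S, cnt$y_S, cnt$n_T, cnt$y_T)
    fit <- .dl_pool(eff$rd, eff$var)
    surr <- rnorm(n_samples, fit$mu, sqrt(fit$nu))
    t1 <- rbeta(n_samples, tau_ptb[1], tau_ptb[2])
    t2 <- rbeta(n_samples, tau_tb[1], tau_tb[2])
    mu[r] <- fit$mu
    nu[r] <- fit$nu
    tau2[r] <- fit$tau2
    frac[r] <- mean(surr * (t1 - t2) < 0)
  }
  out <- list(mean_prob_negative = mean(frac),
              p5_prob_negative = unname(quantile(frac, 0.05)),
              records = data.frame(trial = seq_len(n_trials), mu = mu,
                                   nu = nu, tau2 = tau2,
                                   prob_delta_negative = frac),
              n_trials = n_trials, n_samples = n_samples, seed = seed)
  class(out) <- "decision_performance"
  out
}

#' @export
print.decision_performance <- function(x, ...) {
  cat("Decision-rule operating characteristics (", x$n_trials,
      " trials x ", x$n_samples, " draws)\n", sep = "")
  cat("  mean P(delta < 0):", format(x$mean_prob_negative, digits = 3), "\n")
  cat("  5th percentile:   ", format(x$p5_prob_negative, digits = 3), "\n")
  invisible(x)
}
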