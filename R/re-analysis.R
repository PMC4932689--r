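# Vectorized per-center risk-difference effects. A continuity correction
# (0.5 to each of the four cells, 1 to each arm total) is applied only to
# centers with a zero or full cell, preventing infinite inverse-variance
# weights in centers with as few as 3 patients per arm.
.rd_effects <- function(n_S, y_S, n_T, y_T) {
  if (any(n_S < 1L) || any(n_T < 1L))
    stop("every center must have at least one patient in each arm")
  corrected <- y_S == 0L | y_S == n_S | y_T == 0L | y_T == n_T
  cs <- as.numeric(corrected)
  ys <- y_S + 0.5 * cs
  ns <- n_S + cs
  yt <- y_T + 0.5 * cs
  nt <- n_T + cs
  p_s <- ys / ns
  p_t <- yt / nt
  list(rd = p_t - p_s,
       var = p_t * (1 - p_t) / nt + p_s * (1 - p_s) / ns,
       corrected = corrected)
}

#' Per-center risk difference and its variance
#'
#' Estimates the treatment effect in one center as the risk difference
#' `y_T/n_T - y_S/n_S` (treatment minus standard) with binomial variance
#' `p_T(1-p_T)/n_T + p_S(1-p_S)/n_S`. When any cell of the center's 2x2
#' table is zero or full, 0.5 is added to each cell (1 to each arm total)
#' and both the estimate and its variance are computed on the corrected
#' counts.
#'
#' @param n_S,y_S Standard-arm size and event count.
#' @param n_T,y_T Treatment-arm size and event count.
#' @return An object of class `center_effect`: list with `rd`, `var`,
#'   `corrected`.
#' @examples
#' center_effect(10, 3, 10, 3)   # rd = 0, var = 0.042
#' center_effect(6, 0, 6, 0)     # corrected
#' @export
center_effect <- function(n_S, y_S, n_T, y_T) {
  stopifnot(length(n_S) == 1L, length(n_T) == 1L,
            y_S >= 0, y_S <= n_S, y_T >= 0, y_T <= n_T)
  eff <- .rd_effects(n_S, y_S, n_T, y_T)
  out <- list(rd = eff$rd, var = eff$var, corrected = eff$corrected)
  class(out) <- "center_effect"
  out
}

# DerSimonian-Laird pooling on bare vectors; the hot path of the power
# engine, so no S3 dispatch or data-frame construction here.
.dl_pool <- function(rd, v) {
  k <- length(rd)
  w <- 1 / v
  sw <- sum(w)
  rd_fe <- sum(w * rd) / sw
  q <- sum(w * (rd - rd_fe)^2)
  tau2 <- if (k > 1L) max(0, (q - (k - 1)) / (sw - sum(w^2) / sw)) else 0
  ws <- 1 / (v + tau2)
  sws <- sum(ws)
  mu <- sum(ws * rd) / sws
  nu <- 1 / sws
  z <- mu / sqrt(nu)
  p <- 2 * pnorm(-abs(z))
  list(mu = mu, nu = nu, tau2 = tau2, q = q, z = z, p_value = p, k = k)
}

#' DerSimonian-Laird random-effects pooling of per-center risk differences
#'
#' Method-of-moments random-effects meta-analysis: with per-center effects
#' `rd_i` and variances `v_i`, fixed-effect weights `w_i = 1/v_i` give
#' `Q = sum w_i (rd_i - rd_FE)^2` and the between-center variance estimate
#' `tau^2 = max(0, (Q - (k-1)) / (sum w_i - sum w_i^2 / sum w_i))`. The
#' pooled effect uses weights `w*_i = 1/(v_i + tau^2)`:
#' `mu = sum w*_i rd_i / sum w*_i`, `nu = 1/sum w*_i`, with a two-sided
#' Wald normal test of `mu = 0`.
#'
#' @param effects A list of [center_effect()] objects, or a data frame with
#'   columns `rd` and `var` (one row per center).
#' @param alpha Two-sided significance level (default 0.05).
#' @return An object of class `re_result`: list with `mu`, `nu`, `tau2`,
#'   `q`, `z`, `p_value`, `significant`, `k`, `alpha`.
#' @examples
#' eff <- data.frame(rd = c(-0.2, 0, 0.1), var = c(0.01, 0.02, 0.01))
#' pool_random_effects(eff)
#' @export
pool_random_effects <- function(effects, alpha = 0.05) {
  if (is.data.frame(effects)) {
    rd <- effects$rd
    v <- effects$var
  } else if (is.list(effects) && all(vapply(effects, inherits, TRUE,
                                            "center_effect"))) {
    rd <- vapply(effects, `[[`, 0, "rd")
    v <- vapply(effects, `[[`, 0, "var")
  } else {
    stop("`effects` must be a data frame with columns rd, var or a list of center_effect objects")
  }
  if (length(rd) < 1L)
    stop("need at least one center")
  if (any(v <= 0))
    stop("all center variances must be positive")
  fit <- .dl_pool(rd, v)
  fit$alpha <- alpha
  fit$significant <- fit$p_value < alpha
  class(fit) <- "re_result"
  fit
}

#' Analyze a simulated (or file-loaded) trial
#'
#' Computes per-center risk differences from the trial's 2x2 counts and
#' pools them with [pool_random_effects()].
#'
#' @param trial A `simulated_trial` or a counts data frame (columns `n_S`,
#'   `y_S`, `n_T`, `y_T`), e.g. from [read_trial_counts()].
#' @param alpha Two-sided significance level.
#' @return An `re_result`.
#' @export
analyze_trial <- function(trial, alpha = 0.05) {
  counts <- if (inherits(trial, "simulated_trial")) trial$counts else trial
  eff <- .rd_effects(counts$n_S, counts$y_S, counts$n_T, counts$y_T)
  pool_random_effects(data.frame(rd = eff$rd, var = eff$var), alpha = alpha)
}

#' Two-sided significance flag for a pooled result
#'
#' `TRUE` exactly when the two-sided normal p-value `2(1 - Phi(|z|))` is
#' strictly below `alpha`.
#'
#' @param result An `re_result`.
#' @param alpha Significance level in (0, 1).
#' @return Logical flag.
#' @export
significance_test <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "re_result"), alpha > 0, alpha < 1)
  result$p_value < alpha
}

#' @export
print.re_result <- function(x, ...) {
  cat("Random-effects risk-difference analysis (DerSimonian-Laird)\n")
  cat("  centers:", x$k, "\n")
  cat("  mu =", format(x$mu, digits = 4),
      " nu =", format(x$nu, digits = 4),
      " tau2 =", format(x$tau2, digits = 4), "\n")
  cat("  z =", format(x$z, digits = 4),
      " p =", format(x$p_value, digits = 4),
      if (x$significant) " (significant)" else " (not significant)", "\n")
  invisible(x)
}

#' Serialize a pooled analysis result as a one-row JSON object
#'
#' @param result An `re_result`.
#' @return JSON string with fields `mu`, `nu`, `tau2`, `z`, `p_value`,
#'   `significant`.
#' @export
re_result_to_json <- function(result) {
  stopifnot(inherits(result, "re_result"))
  jsonlite::toJSON(list(mu = result$mu, nu = result$nu, tau2 = result$tau2,
                        z = result$z, p_value = result$p_value,
                        significant = result$significant),
                   auto_unbox = TRUE, digits = NA)
}
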