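#' Moment-matched Beta model for between-center variation
#'
#' Solve for the Beta shape parameters whose mean and coefficient of
#' variation (CV) equal the supplied values. With `m = E(X)`,
#' `c = CV(X)` and `d = m / (1 - m)` (the odds of the mean), the
#' closed-form solution is
#' \deqn{a = \frac{1 - c^2 d}{c^2 (1 + d)}, \qquad
#'       b = \frac{1 - c^2 d}{c^2 d (1 + d)}.}
#' A Beta distribution with these parameters exists only when
#' `cv^2 < (1 - mean) / mean`; larger CVs are incompatible with a
#' probability bounded in (0, 1).
#'
#' `cv = 0` returns a degenerate point-mass spec (all centers share the same
#' probability), flagged by `point_mass = TRUE`; a limiting Beta with
#' infinite `a + b` is deliberately avoided.
#'
#' @param mean Mean event probability across centers, in (0, 1).
#' @param cv Coefficient of variation (sd/mean) of the event probability
#'   across centers; nonnegative.
#' @return An object of class `beta_spec`: a list with elements `mean`, `cv`,
#'   `a`, `b`, `d` and `point_mass`.
#' @examples
#' solve_beta_parameters(0.3, 0.3)  # a = 7.478, b = 17.45
#' solve_beta_parameters(0.3, 0)    # point mass at 0.3
#' @seealso [beta_moments()], [tail_probability()], [beta_quantiles()],
#'   [sample_center_probabilities()]
#' @export
solve_beta_parameters <- function(mean, cv) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(cv), length(cv) == 1L, is.finite(cv))
  if (mean <= 0 || mean >= 1)
    stop("`mean` must lie strictly between 0 and 1, got ", mean)
  if (cv < 0)
    stop("`cv` must be nonnegative, got ", cv)
  d <- mean / (1 - mean)
  if (cv == 0) {
    out <- list(mean = mean, cv = 0, a = NA_real_, b = NA_real_,
                d = d, point_mass = TRUE)
    class(out) <- "beta_spec"
    return(out)
  }
  if (cv^2 >= (1 - mean) / mean)
    stop("infeasible (mean, cv): requires cv^2 < (1 - mean)/mean = ",
         format((1 - mean) / mean), " but cv^2 = ", format(cv^2))
  num <- 1 - cv^2 * d
  a <- num / (cv^2 * (1 + d))
  b <- num / (cv^2 * d * (1 + d))
  out <- list(mean = mean, cv = cv, a = a, b = b, d = d, point_mass = FALSE)
  class(out) <- "beta_spec"
  out
}

#' Build a center-model spec directly from Beta shape parameters
#'
#' The inverse entry point to [solve_beta_parameters()]: given shapes
#' `(a, b)`, derive the implied mean `a/(a+b)` and CV.
#'
#' @param a,b Positive Beta shape parameters.
#' @return A `beta_spec` object.
#' @examples
#' beta_spec_shapes(7.478, 17.45)
#' @export
beta_spec_shapes <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0,
            is.numeric(b), length(b) == 1L, is.finite(b), b > 0)
  m <- a / (a + b)
  v <- a * b / ((a + b)^2 * (a + b + 1))
  out <- list(mean = m, cv = sqrt(v) / m, a = a, b = b,
              d = m / (1 - m), point_mass = FALSE)
  class(out) <- "beta_spec"
  out
}

#' Mean and CV implied by a center-model spec
#'
#' Evaluates `E(X) = a/(a+b)` and
#' `V(X) = ab / ((a+b)^2 (a+b+1))`, returning the mean and the coefficient
#' of variation `sqrt(V)/E`. Round-trips the inputs of
#' [solve_beta_parameters()] to within 1e-10.
#'
#' @param spec A `beta_spec`.
#' @return Named numeric vector `c(mean = , cv = )`.
#' @export
beta_moments <- function(spec) {
  stopifnot(inherits(spec, "beta_spec"))
  if (spec$point_mass)
    return(c(mean = spec$mean, cv = 0))
  a <- spec$a
  b <- spec$b
  m <- a / (a + b)
  v <- a * b / ((a + b)^2 * (a + b + 1))
  c(mean = m, cv = sqrt(v) / m)
}

#' Upper-tail probability of the center model
#'
#' `P(X > threshold)` via the regularized incomplete beta function
#' (`stats::pbeta`). For a point-mass spec the result is 0 or 1 by direct
#' comparison with the mean.
#'
#' @param spec A `beta_spec`.
#' @param threshold Probability threshold in \[0, 1\].
#' @return The probability that a center's event probability exceeds
#'   `threshold`.
#' @examples
#' tail_probability(solve_beta_parameters(0.3, 0.3), 0.225)  # ~0.79
#' @export
tail_probability <- function(spec, threshold) {
  stopifnot(inherits(spec, "beta_spec"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  if (spec$point_mass)
    return(as.numeric(spec$mean > threshold))
  pbeta(threshold, spec$a, spec$b, lower.tail = FALSE)
}

#' Quantiles of the center model
#'
#' Inverse cumulative distribution of the between-center Beta law. For a
#' point-mass spec every quantile equals the mean.
#'
#' @param spec A `beta_spec`.
#' @param probs Probabilities in (0, 1).
#' @return Numeric vector of quantiles, same length as `probs`.
#' @examples
#' beta_quantiles(solve_beta_parameters(0.3, 0.3), c(0.05, 0.95))
#' @export
beta_quantiles <- function(spec, probs) {
  stopifnot(inherits(spec, "beta_spec"), is.numeric(probs),
            all(probs > 0 & probs < 1))
  if (spec$point_mass)
    return(rep.int(spec$mean, length(probs)))
  qbeta(probs, spec$a, spec$b)
}

#' @export
quantile.beta_spec <- function(x, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                               ...) {
  q <- beta_quantiles(x, probs)
  names(q) <- paste0(format(100 * probs, trim = TRUE), "%")
  q
}

#' Draw center-level event probabilities
#'
#' Samples `k` independent center probabilities from the between-center law.
#' A point-mass spec returns `k` copies of the mean (and does not consume
#' random numbers).
#'
#' @param spec A `beta_spec`.
#' @param k Number of centers; positive integer.
#' @return Numeric vector of `k` probabilities.
#' @export
sample_center_probabilities <- function(spec, k) {
  stopifnot(inherits(spec, "beta_spec"),
            is.numeric(k), length(k) == 1L, k >= 1)
  k <- as.integer(k)
  if (spec$point_mass)
    return(rep.int(spec$mean, k))
  rbeta(k, spec$a, spec$b)
}

#' @export
print.beta_spec <- function(x, ...) {
  if (x$point_mass) {
    cat("Between-center model: point mass at", format(x$mean), "(cv = 0)\n")
  } else {
    cat("Between-center Beta model\n")
    cat("  mean =", format(x$mean), "  cv =", format(x$cv), "\n")
    cat("  shapes: a =", format(signif(x$a, 4)),
        " b =", format(signif(x$b, 4)), "\n")
  }
  invisible(x)
}

#' Serialize / deserialize a center-model spec as JSON
#'
#' @param spec A `beta_spec`.
#' @param txt JSON text (or a file path) with fields `mean` and `cv`
#'   (shape fields `a`, `b` are emitted for reference but re-derived on read).
#' @return `beta_spec_to_json()` returns a JSON string; `beta_spec_from_json()`
#'   a `beta_spec`.
#' @export
beta_spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "beta_spec"))
  jsonlite::toJSON(list(mean = spec$mean, cv = spec$cv,
                        a = spec$a, b = spec$b),
                   auto_unbox = TRUE, digits = NA, na = "null")
}

#' @rdname beta_spec_to_json
#' @export
beta_spec_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  solve_beta_parameters(x$mean, x$cv)
}
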