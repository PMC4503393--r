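#' Moment-matched beta distribution on [0, 1]
#'
#' Solves for the beta shape parameters that give exactly the requested mean
#' and standard deviation: with `nu = mean (1 - mean) / sd^2 - 1`,
#' `shape1 = mean * nu` and `shape2 = (1 - mean) * nu`.  A beta on \[0, 1\]
#' can only carry variance up to `mean * (1 - mean)`; an infeasible request
#' is an error that names the bound.  This bound is why the snail life
#' history's process-error grid is capped at CV 0.45: CV 0.5 on a mean
#' survival of 0.8 would need variance 0.16 = 0.8 * 0.2, the bound itself.
#'
#' @param mean Mean, strictly inside (0, 1).
#' @param sd Standard deviation; `sd = 0` denotes a degenerate point mass
#'   and returns `NULL` (no shapes).
#' @return `NULL` if `sd == 0`, else named numeric vector
#'   `c(shape1 = , shape2 = )`.
#' @examples
#' beta_from_moments(0.5, 0.15)  # shape1 = shape2 = 5.0556
#' @export
beta_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("'mean' must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.finite(sd) || sd < 0)
    stop("'sd' must be nonnegative", call. = FALSE)
  if (sd == 0) return(NULL)
  bound <- mean * (1 - mean)
  if (sd^2 >= bound)
    stop(sprintf(paste0(
      "infeasible beta moments: variance %.6g must be smaller than ",
      "mean(1-mean) = %.6g"), sd^2, bound), call. = FALSE)
  nu <- bound / sd^2 - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Moment-matched stretched beta distribution on an arbitrary interval
#'
#' A stretched beta is a standard beta rescaled linearly onto
#' `[lower, upper]`; moment matching is affine-invariant, so the shapes are
#' those of a \[0, 1\] beta with mean `(mean - lower) / (upper - lower)` and
#' sd `sd / (upper - lower)`.  Used for fecundity process error on
#' \[0, 1000\].
#'
#' @inheritParams beta_from_moments
#' @param lower,upper Interval bounds (defaults 0 and 1000).
#' @return `NULL` if `sd == 0`, else a list with `shape1`, `shape2`,
#'   `lower`, `upper`.
#' @export
stretched_beta_from_moments <- function(mean, sd, lower = 0, upper = 1000) {
  if (!is.finite(lower) || !is.finite(upper) || upper <= lower)
    stop("need upper > lower", call. = FALSE)
  if (!is.finite(mean) || mean <= lower || mean >= upper)
    stop("'mean' must lie strictly inside (lower, upper)", call. = FALSE)
  if (sd == 0) return(NULL)
  sh <- beta_from_moments((mean - lower) / (upper - lower),
                          sd / (upper - lower))
  list(shape1 = unname(sh["shape1"]), shape2 = unname(sh["shape2"]),
       lower = lower, upper = upper)
}

# Draw n stochastic vital rates with the given mean and process-error CV on
# [lower, upper].  cv = 0 is a point mass at the mean.  Uses the current RNG
# stream.
rvital <- function(n, mean, cv, lower = 0, upper = 1) {
  if (cv == 0) return(rep.int(mean, n))
  p <- stretched_beta_from_moments(mean, cv * mean, lower, upper)
  lower + (upper - lower) * stats::rbeta(n, p$shape1, p$shape2)
}
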