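#' Overlay normal measurement error on a true trajectory
#'
#' Each age-specific abundance is observed independently as a draw from
#' `Normal(n_true, me_cv * n_true)`, truncated below at zero by clamping
#' negative draws (at study abundance scales the clamp probability is
#' negligible: a draw below zero is a deviation beyond `1 / me_cv` standard
#' deviations).  Observed totals are always the sum of the perturbed age
#' classes; they are never perturbed separately.  `me_cv = 0` returns the
#' true abundances unchanged.
#'
#' @param traj A [simulate_true_series()] trajectory.
#' @param me_cv Measurement-error coefficient of variation (study grid:
#'   0, 0.1, 0.3).
#' @return An `observed_series` object with the same year-by-class layout
#'   as the trajectory.
#' @export
apply_measurement_error <- function(traj, me_cv) {
  stopifnot(inherits(traj, "true_trajectory"))
  if (!is.finite(me_cv) || me_cv < 0)
    stop("'me_cv' must be nonnegative", call. = FALSE)
  N <- traj$abundances
  if (me_cv > 0) {
    obs <- matrix(stats::rnorm(length(N), mean = N, sd = me_cv * N),
                  nrow(N), ncol(N), dimnames = dimnames(N))
    obs[obs < 0] <- 0
  } else {
    obs <- N
  }
  structure(
    list(abundances = obs, totals = rowSums(obs), me_cv = me_cv,
         life_history = traj$life_history, lambda = traj$lambda,
         pe_cv = traj$pe_cv, years = traj$years),
    class = "observed_series"
  )
}

#' Extract the census window used to parameterize estimated models
#'
#' Takes the last `M` years of the 50-year observed census history, i.e.
#' years `50 - M + 1` through 50 inclusive.  Study window lengths are
#' M = 5, 10, 15, 20, 30, 40, 50.
#'
#' @param obs An [apply_measurement_error()] series.
#' @param M Window length in years (2 <= M <= 50).
#' @param history_end Last year of the census history (default 50; the
#'   years beyond it are the projection reference period).
#' @return An `observed_window` object: `abundances` (`M x n_classes`),
#'   `totals`, `me_cv`, and `window = c(start, end)` in trajectory years.
#' @export
extract_window <- function(obs, M, history_end = 50) {
  stopifnot(inherits(obs, "observed_series"))
  M <- as.integer(M)
  if (M < 2L) stop("'M' must be at least 2", call. = FALSE)
  if (M > history_end)
    stop(sprintf("'M' = %d exceeds the %d-year census history", M,
                 history_end), call. = FALSE)
  yrs <- as.character((history_end - M + 1L):history_end)
  structure(
    list(abundances = obs$abundances[yrs, , drop = FALSE],
         totals = obs$totals[yrs], me_cv = obs$me_cv,
         window = c(history_end - M + 1L, history_end),
         life_history = obs$life_history),
    class = "observed_window"
  )
}
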