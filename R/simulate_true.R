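#' Draw one annual projection matrix under process error
#'
#' Each survival rate (including the composite self-loop) is drawn from a
#' moment-matched beta on \[0, 1\] and the shared fecundity from a stretched
#' beta on \[0, 1000\]; every rate has standard deviation `pe_cv` times its
#' mean and all draws are independent (uncorrelated vital rates).  With
#' `pe_cv = 0` the mean matrix is returned exactly.
#'
#' @param spec A [life_history()].
#' @param fecundity Mean fecundity (see [back_calculate_fecundity()]).
#' @param pe_cv Process-error coefficient of variation applied to every
#'   vital rate.
#' @return One Leslie matrix realization.
#' @export
draw_annual_matrix <- function(spec, fecundity, pe_cv) {
  stopifnot(inherits(spec, "life_history"))
  if (pe_cv == 0) return(build_leslie(spec, fecundity))
  s <- vapply(spec$survival, function(m) rvital(1L, m, pe_cv, 0, 1),
              numeric(1))
  f <- rvital(1L, fecundity, pe_cv, 0, 1000)
  build_leslie(spec, f, survival = s)
}

#' Simulate a "true" age-structured population trajectory
#'
#' Projects `n_(t+1) = A_t n_t` for `years` annual steps from an initial
#' population of `n0` individuals at the stable age distribution, drawing a
#' fresh matrix of independent stochastic vital rates each year (one draw
#' per rate per year: survivals by ascending class, then fecundity, each
#' rate's draws taken as a block across years).  The default 60-year run
#' provides a 50-year census history plus a 10-year projection reference
#' period.  Abundances are real-valued: with `n0 = 1e9` demographic
#' stochasticity is negligible and is not modeled.
#'
#' @inheritParams draw_annual_matrix
#' @param lambda Target asymptotic growth rate; the mean fecundity is
#'   back-calculated from it unless `fecundity` is supplied directly.
#' @param fecundity Optional mean fecundity, bypassing the back-calculation
#'   (useful when simulating many replicates at the same `lambda`).
#' @param years Number of annual transitions to simulate (default 60).
#' @param n0 Initial total population size (default 1e9).
#' @return A `true_trajectory` object: list with `abundances`
#'   (`(years + 1) x n_classes` matrix, rows = years `0:years`), `totals`,
#'   and the provenance fields `life_history`, `lambda`, `fecundity`,
#'   `pe_cv`.
#' @export
simulate_true_series <- function(spec, lambda = NULL, pe_cv = 0, years = 60,
                                 n0 = 1e9, fecundity = NULL) {
  stopifnot(inherits(spec, "life_history"), years >= 2)
  if (is.null(fecundity)) {
    if (is.null(lambda)) stop("supply 'lambda' or 'fecundity'", call. = FALSE)
    fecundity <- back_calculate_fecundity(spec, lambda)
  }
  K <- spec$n_classes
  A_mean <- build_leslie(spec, fecundity)
  v <- stable_age_distribution(A_mean)
  N <- matrix(0, years + 1L, K,
              dimnames = list(year = 0:years, class = seq_len(K)))
  N[1L, ] <- n0 * v

  if (pe_cv > 0) {
    surv <- vapply(spec$survival,
                   function(m) rvital(years, m, pe_cv, 0, 1),
                   numeric(years))                 # years x K
    fec <- rvital(years, fecundity, pe_cv, 0, 1000)
  } else {
    surv <- matrix(spec$survival, years, K, byrow = TRUE)
    fec <- rep.int(fecundity, years)
  }

  rep_cl <- spec$reproductive_classes
  for (t in seq_len(years)) {
    n <- N[t, ]
    nn <- numeric(K)
    nn[1L] <- fec[t] * sum(n[rep_cl])
    nn[2:K] <- surv[t, 1:(K - 1L)] * n[1:(K - 1L)]
    nn[K] <- nn[K] + surv[t, K] * n[K]
    N[t + 1L, ] <- nn
  }

  structure(
    list(abundances = N, totals = rowSums(N),
         life_history = spec$name, lambda = lambda,
         fecundity = fecundity, pe_cv = pe_cv, years = years),
    class = "true_trajectory"
  )
}

#' @export
print.true_trajectory <- function(x, ...) {
  cat("True trajectory:", x$life_history,
      sprintf("(lambda = %s, pe_cv = %g)\n",
              if (is.null(x$lambda)) "?" else format(x$lambda), x$pe_cv))
  cat("  years 0..", x$years, ", ", ncol(x$abundances), " age classes\n",
      sep = "")
  cat(sprintf("  total: %.4g at year 0, %.4g at year %d\n",
              x$totals[1L], x$totals[length(x$totals)], x$years))
  invisible(x)
}

# Shared helper: percent decline between two totals.
percent_decline <- function(n_from, n_to) {
  if (any(n_from <= 0)) stop("starting abundance must be positive",
                             call. = FALSE)
  100 * (n_from - n_to) / n_from
}

#' True percent decline over the projection window
#'
#' `100 * (N_from - N_to) / N_from` on trajectory totals; negative values
#' denote population growth.  Defaults to the study's ten-year reference
#' period, years 50 to 60.
#'
#' @param traj A [simulate_true_series()] trajectory.
#' @param from_year,to_year Window endpoints (years since simulation start).
#' @return Signed percent decline (at most 100).
#' @export
true_percent_decline <- function(traj, from_year = 50, to_year = 60) {
  stopifnot(inherits(traj, "true_trajectory"),
            to_year <= traj$years, from_year < to_year)
  n <- traj$totals
  percent_decline(n[[as.character(from_year)]], n[[as.character(to_year)]])
}

#' Realized stochastic growth rate over a window
#'
#' Geometric-mean annual growth over the window:
#' `(N_to / N_from)^(1 / (to_year - from_year))`.  Related to
#' [true_percent_decline()] by `decline = 100 (1 - g^h)`.
#'
#' @inheritParams true_percent_decline
#' @return Positive real growth rate.
#' @export
stochastic_growth_rate <- function(traj, from_year = 50, to_year = 60) {
  stopifnot(inherits(traj, "true_trajectory"),
            to_year <= traj$years, from_year < to_year)
  n <- traj$totals
  a <- n[[as.character(from_year)]]
  b <- n[[as.character(to_year)]]
  if (a <= 0 || b <= 0) stop("totals must be positive over the window",
                             call. = FALSE)
  (b / a)^(1 / (to_year - from_year))
}
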