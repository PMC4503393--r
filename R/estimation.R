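#' Parameterize a scalar (count-based) model from an observed window
#'
#' From an M-year window of observed totals, computes the pool of `M - 1`
#' annual stochastic growth rates `lambda_t = n_(t+1) / n_t`.  Growth rates
#' are never censored or truncated, in contrast to the matrix model's
#' survival estimates.  The projection's initial population size is the
#' final observed total.
#'
#' @param window An [extract_window()] observation window.
#' @return A `scalar_estimate`: list with `lambda_pool` (length `M - 1`)
#'   and `initial_total`.
#' @export
estimate_scalar <- function(window) {
  stopifnot(inherits(window, "observed_window"))
  n <- window$totals
  if (any(n <= 0))
    stop("degenerate census: observed total is zero in some year",
         call. = FALSE)
  M <- length(n)
  structure(
    list(lambda_pool = unname(n[-1L] / n[-M]),
         initial_total = unname(n[M])),
    class = "scalar_estimate"
  )
}

#' Parameterize an age-structured matrix model from an observed window
#'
#' The estimated model has one class fewer than the true life history: its
#' terminal class is a composite pooling the last two observed classes
#' ("9+ years" for the hypothetical life history, "4+ years" for the
#' snail).  From each of the `M - 1` year pairs the window yields
#' cohort-ratio vital-rate estimates:
#' \itemize{
#'   \item per-class survival `s_i = n_(i+1, t+1) / n_(i, t)` for
#'     `i = 1 .. K - 2` (K = true class count);
#'   \item composite survival `n_(K, t+1) / (n_(K-1, t) + n_(K, t))`;
#'   \item shared fecundity `n_(1, t+1)` divided by the observed population
#'     at `t` (see `fecundity_denominator`).
#' }
#' Measurement error can make an observed cohort "grow", producing survival
#' estimates above one; these are biologically impossible and are censored:
#' recorded in `censored_counts` (and kept in `censored_values` for the
#' optional empty-pool fallback in [project_matrix()]) but excluded from the
#' resampling pools.  Estimates with a zero denominator (possible only if
#' clamping produced an exact zero) are likewise excluded and counted.
#' Fecundity estimates are never censored.
#'
#' @param window An [extract_window()] window with the true number of
#'   observed age classes.
#' @param spec The true [life_history()] the census was observed from.
#' @param fecundity_denominator `"total"` (default) divides first-class
#'   recruits by the total observed population, consistent with the
#'   composite class pooling all terminal ages; `"exclude_composite"`
#'   instead sums observed classes `1 .. K - 1` only.
#' @return A `matrix_estimate`: list with `n_est_classes`, `survival_pools`
#'   (list, entries `1 .. n_est - 1` are sub-diagonal transitions, entry
#'   `n_est` is the composite self-loop), `censored_values`,
#'   `censored_counts`, `fecundity_pool`, `initial_vector` (final observed
#'   age abundances aggregated onto the estimated classes).
#' @export
estimate_matrix <- function(window, spec,
                            fecundity_denominator = c("total",
                                                      "exclude_composite")) {
  stopifnot(inherits(window, "observed_window"),
            inherits(spec, "life_history"))
  fecundity_denominator <- match.arg(fecundity_denominator)
  N <- window$abundances
  K <- spec$n_classes
  if (ncol(N) != K)
    stop("window has ", ncol(N), " classes but the life history has ", K,
         call. = FALSE)
  M <- nrow(N)
  Ke <- K - 1L                       # estimated model classes
  from <- N[-M, , drop = FALSE]      # years t
  to <- N[-1L, , drop = FALSE]       # years t + 1

  pools <- vector("list", Ke)
  censored <- vector("list", Ke)
  for (i in seq_len(Ke - 1L)) {      # transitions i -> i + 1, i = 1..K-2
    est <- to[, i + 1L] / from[, i]
    keep <- is.finite(est) & est <= 1
    pools[[i]] <- unname(est[keep])
    censored[[i]] <- unname(est[!keep])
  }
  comp_den <- from[, K - 1L] + from[, K]
  est <- to[, K] / comp_den
  keep <- is.finite(est) & est <= 1
  pools[[Ke]] <- unname(est[keep])
  censored[[Ke]] <- unname(est[!keep])

  den <- if (fecundity_denominator == "total") rowSums(from)
         else rowSums(from[, seq_len(K - 1L), drop = FALSE])
  fec <- to[, 1L] / den
  fec <- unname(fec[is.finite(fec)])

  final <- N[M, ]
  init <- c(final[seq_len(K - 2L)], final[K - 1L] + final[K])

  structure(
    list(n_est_classes = Ke,
         survival_pools = pools,
         censored_values = censored,
         censored_counts = lengths(censored),
         fecundity_pool = fec,
         initial_vector = unname(init),
         n_year_pairs = M - 1L),
    class = "matrix_estimate"
  )
}

#' @export
print.matrix_estimate <- function(x, ...) {
  cat("Matrix PVA estimate:", x$n_est_classes, "classes,",
      x$n_year_pairs, "year pairs\n")
  cat("  retained survival estimates:",
      paste(lengths(x$survival_pools), collapse = ", "), "\n")
  cat("  censored (> 1 or undefined):",
      paste(x$censored_counts, collapse = ", "), "\n")
  cat(sprintf("  fecundity pool: %d values, mean %.4g\n",
              length(x$fecundity_pool), mean(x$fecundity_pool)))
  invisible(x)
}
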