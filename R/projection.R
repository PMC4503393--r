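new_projection_result <- function(declines, model_type, horizon, n_traj,
                                  fallback_classes = integer(0)) {
  structure(
    list(declines = declines,
         median_decline = stats::median(declines),
         model_type = model_type, horizon = horizon, n_traj = n_traj,
         fallback_classes = fallback_classes),
    class = "projection_result"
  )
}

#' Project a scalar PVA model by resampling growth rates
#'
#' Each of `n_traj` trajectories multiplies the initial total by a growth
#' rate drawn uniformly with replacement from the estimated pool, once per
#' year over the horizon; the per-trajectory percent decline is
#' `100 (N_0 - N_h) / N_0`.  Negative declines denote growth: declines are
#' signed and never floored at zero.
#'
#' @param est An [estimate_scalar()] estimate.
#' @param horizon Projection length in years (default 10, the IUCN
#'   criterion A.3 horizon for these short-lived life histories).
#' @param n_traj Number of resampled trajectories (default 1000).
#' @return A `projection_result` with the decline sample and its median.
#' @export
project_scalar <- function(est, horizon = 10, n_traj = 1000) {
  stopifnot(inherits(est, "scalar_estimate"))
  pool <- est$lambda_pool
  if (length(pool) == 0L) stop("empty growth-rate pool", call. = FALSE)
  if (est$initial_total <= 0)
    stop("initial population size must be positive", call. = FALSE)
  growth <- rep.int(1, n_traj)
  for (t in seq_len(horizon)) {
    growth <- growth * pool[sample.int(length(pool), n_traj, replace = TRUE)]
  }
  new_projection_result(100 * (1 - growth), "scalar", horizon, n_traj)
}

#' Project a matrix PVA model by resampling vital-rate pools
#'
#' Every year of every trajectory draws one value per rate pool (each
#' survival transition, the composite self-loop, and the fecundity),
#' independently across rates, years and trajectories, assembles the
#' implied estimated-class Leslie matrix, and advances the age vector.  The
#' initial vector is the final observed census aggregated onto the
#' estimated classes; declines are computed on totals.
#'
#' If censoring removed every estimate for some survival rate, the pool
#' would be empty.  The default fallback (`empty_pool = "cap"`) restores
#' that rate's censored estimates capped at 1.0 and records the affected
#' classes in the result's `fallback_classes`; `empty_pool = "drop"`
#' signals an error of class `pvasim_empty_pool` so a caller can discard
#' the replicate instead.  Either way the event is never silent.
#'
#' @param est An [estimate_matrix()] estimate.
#' @inheritParams project_scalar
#' @param empty_pool `"cap"` (default) or `"drop"`; see Details.
#' @return A `projection_result`.
#' @export
project_matrix <- function(est, horizon = 10, n_traj = 1000,
                           empty_pool = c("cap", "drop")) {
  stopifnot(inherits(est, "matrix_estimate"))
  empty_pool <- match.arg(empty_pool)
  Ke <- est$n_est_classes
  pools <- est$survival_pools
  empty <- which(lengths(pools) == 0L)
  if (length(empty) > 0L) {
    if (empty_pool == "drop")
      stop(structure(
        class = c("pvasim_empty_pool", "error", "condition"),
        list(message = paste("all survival estimates censored for class(es)",
                             paste(empty, collapse = ", ")),
             call = sys.call())))
    for (i in empty) {
      if (length(est$censored_values[[i]]) == 0L)
        stop("no survival estimates at all for class ", i, call. = FALSE)
      pools[[i]] <- pmin(est$censored_values[[i]], 1)
    }
  }
  fec_pool <- est$fecundity_pool
  if (length(fec_pool) == 0L) stop("empty fecundity pool", call. = FALSE)
  init <- est$initial_vector
  if (sum(init) <= 0)
    stop("initial population size must be positive", call. = FALSE)

  state <- matrix(init, Ke, n_traj)            # classes x trajectories
  n0 <- sum(init)
  draw <- function(pool) pool[sample.int(length(pool), n_traj,
                                         replace = TRUE)]
  for (t in seq_len(horizon)) {
    recruits <- draw(fec_pool) * colSums(state)
    surv_to <- matrix(0, Ke, n_traj)
    for (i in seq_len(Ke - 1L)) {
      surv_to[i + 1L, ] <- draw(pools[[i]]) * state[i, ]
    }
    surv_to[Ke, ] <- surv_to[Ke, ] + draw(pools[[Ke]]) * state[Ke, ]
    state <- surv_to
    state[1L, ] <- state[1L, ] + recruits
  }
  new_projection_result(100 * (n0 - colSums(state)) / n0, "matrix",
                        horizon, n_traj, fallback_classes = empty)
}

#' Median percent decline of a projection
#'
#' Sample median of the per-trajectory declines (midpoint of the two
#' central order statistics for an even number of trajectories).  The
#' median is the "best estimate" central tendency recommended for decline
#' estimates under the IUCN Red List guidelines.
#'
#' @param result A [project_scalar()] or [project_matrix()] result.
#' @return Signed percent decline.
#' @export
median_percent_decline <- function(result) {
  stopifnot(inherits(result, "projection_result"))
  stats::median(result$declines)
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("%s-model projection: %d trajectories over %d years\n",
              x$model_type, x$n_traj, x$horizon))
  cat(sprintf("  median decline %.3f%% (IQR %.3f%% to %.3f%%)\n",
              x$median_decline,
              stats::quantile(x$declines, 0.25),
              stats::quantile(x$declines, 0.75)))
  if (length(x$fallback_classes) > 0L)
    cat("  empty-pool fallback applied to class(es):",
        paste(x$fallback_classes, collapse = ", "), "\n")
  invisible(x)
}
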