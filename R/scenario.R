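#' Enumerate the full scenario grid for a life history
#'
#' The study design crosses four growth rates, four process-error CVs (the
#' life history's own grid), three measurement-error CVs and seven window
#' lengths: 4 x 4 x 3 x 7 = 336 scenarios per life history.
#'
#' @param spec A [life_history()].
#' @param lambda,me_cv,M Optional overrides of the default study levels.
#' @param pe_cv Optional override of the life history's process-error grid.
#' @return Data frame with one row per scenario and columns
#'   `life_history`, `lambda`, `pe_cv`, `me_cv`, `M`.
#' @export
scenario_grid <- function(spec, lambda = c(0.9, 0.95, 1.0, 1.025),
                          pe_cv = spec$pe_cv_grid, me_cv = c(0, 0.1, 0.3),
                          M = c(5, 10, 15, 20, 30, 40, 50)) {
  stopifnot(inherits(spec, "life_history"))
  g <- expand.grid(lambda = lambda, pe_cv = pe_cv, me_cv = me_cv, M = M,
                   KEEP.OUT.ATTRS = FALSE)
  cbind(life_history = spec$name, g)
}

#' Run one replicate: simulate, observe, estimate, project, compare
#'
#' One pass through the full pipeline: simulate a 60-year true trajectory,
#' overlay measurement error, and for each requested window length `M`
#' parameterize and project both the scalar and the matrix model, recording
#' the true ten-year percent decline (years 50 to 60), each model's median
#' estimated decline, and the differences `true - estimated` (the study's
#' sign convention: over-estimation of decline appears as a negative
#' difference).
#'
#' All window lengths share the one simulated truth and one observed
#' series, as in the study design where the seven windows are nested
#' subsets of the same 50-year census.
#'
#' @param spec A [life_history()].
#' @param lambda Target true growth rate.
#' @param pe_cv,me_cv Process- and measurement-error CVs.
#' @param M Window length(s) in years; may be a vector.
#' @param n_traj Trajectories per estimated model (default 1000).
#' @param horizon Projection horizon in years (default 10).
#' @param fecundity Optional precomputed mean fecundity.
#' @param fecundity_denominator,empty_pool Passed to [estimate_matrix()]
#'   and [project_matrix()].
#' @return Data frame with one row per `M`: `M`, `true_decline`,
#'   `scalar_median`, `matrix_median`, `scalar_diff`, `matrix_diff`,
#'   `censored`, `censored_frac`, `fallback_n`.
#' @export
run_replicate <- function(spec, lambda, pe_cv, me_cv, M, n_traj = 1000,
                          horizon = 10, fecundity = NULL,
                          fecundity_denominator = "total",
                          empty_pool = "cap") {
  if (is.null(fecundity)) fecundity <- back_calculate_fecundity(spec, lambda)
  traj <- simulate_true_series(spec, lambda = lambda, pe_cv = pe_cv,
                               fecundity = fecundity)
  true_dec <- true_percent_decline(traj)
  obs <- apply_measurement_error(traj, me_cv)

  rows <- lapply(M, function(m) {
    w <- extract_window(obs, m)
    sc <- project_scalar(estimate_scalar(w), horizon, n_traj)
    me <- estimate_matrix(w, spec,
                          fecundity_denominator = fecundity_denominator)
    mx <- project_matrix(me, horizon, n_traj, empty_pool = empty_pool)
    n_est <- me$n_est_classes * me$n_year_pairs
    data.frame(M = m,
               true_decline = true_dec,
               scalar_median = sc$median_decline,
               matrix_median = mx$median_decline,
               scalar_diff = true_dec - sc$median_decline,
               matrix_diff = true_dec - mx$median_decline,
               censored = sum(me$censored_counts),
               censored_frac = sum(me$censored_counts) / n_est,
               fallback_n = length(mx$fallback_classes))
  })
  do.call(rbind, rows)
}

#' Run a scenario: many replicated truth-to-comparison pipelines
#'
#' Replicates [run_replicate()] `n_reps` times.  Each replicate runs on its
#' own RNG substream derived from `seed`, so results are reproducible and
#' the first `k` replicates of a longer run equal a run of `k`.
#'
#' @inheritParams run_replicate
#' @param n_reps Number of true-series replicates (study value: 1000).
#' @param seed Optional integer seed for reproducibility.
#' @param empty_pool `"cap"` or `"drop"`; with `"drop"`, replicates in
#'   which every estimate of some survival rate was censored are discarded
#'   (their rows are omitted and counted in the `dropped` attribute).
#' @return Data frame of per-replicate records (columns of
#'   [run_replicate()] plus `replicate`), with attribute `dropped` giving
#'   the number of discarded replicates.
#' @seealso [summarize_scenario()] for the precision/bias summary.
#' @export
run_scenario <- function(spec, lambda, pe_cv, me_cv,
                         M = c(5, 10, 15, 20, 30, 40, 50),
                         n_reps = 1000, n_traj = 1000, horizon = 10,
                         seed = NULL, fecundity_denominator = "total",
                         empty_pool = "cap") {
  stopifnot(inherits(spec, "life_history"))
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  fecundity <- back_calculate_fecundity(spec, lambda)

  dropped <- 0L
  records <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    rec <- tryCatch(
      run_replicate(spec, lambda, pe_cv, me_cv, M, n_traj, horizon,
                    fecundity = fecundity,
                    fecundity_denominator = fecundity_denominator,
                    empty_pool = empty_pool),
      pvasim_empty_pool = function(e) NULL
    )
    if (is.null(rec)) { dropped <- dropped + 1L; next }
    records[[r]] <- cbind(replicate = r, rec)
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "scenario") <- list(life_history = spec$name, lambda = lambda,
                                pe_cv = pe_cv, me_cv = me_cv,
                                n_reps = n_reps, n_traj = n_traj,
                                horizon = horizon, seed = seed)
  attr(out, "dropped") <- dropped
  out
}

#' Summarize a scenario's precision and bias
#'
#' For each window length and model, summarizes the distribution of
#' per-replicate decline differences (`true - estimated median`): the
#' median difference (bias: differences centered at zero are unbiased),
#' the quartiles, the interquartile-range width, and precision as the
#' inverse of that width (stored as `NA` when the width is zero, as in
#' error-free scenarios, rather than infinity).
#'
#' @param records Per-replicate records from [run_scenario()].
#' @return Data frame with one row per `M` x model: columns `M`, `model`,
#'   `bias`, `q25`, `q75`, `iqr_width`, `precision`, `mean_censored_frac`,
#'   `fallback_total`, `n_reps`.
#' @export
summarize_scenario <- function(records) {
  stopifnot(is.data.frame(records))
  rows <- lapply(split(records, records$M), function(d) {
    one <- function(model, diffs) {
      q <- unname(stats::quantile(diffs, c(0.25, 0.75)))
      w <- q[2L] - q[1L]
      data.frame(M = d$M[1L], model = model,
                 bias = stats::median(diffs), q25 = q[1L], q75 = q[2L],
                 iqr_width = w, precision = if (w > 0) 1 / w else NA_real_,
                 mean_censored_frac = mean(d$censored_frac),
                 fallback_total = sum(d$fallback_n), n_reps = nrow(d))
    }
    rbind(one("scalar", d$scalar_diff), one("matrix", d$matrix_diff))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  sc <- attr(records, "scenario")
  if (!is.null(sc))
    out <- cbind(life_history = sc$life_history, lambda = sc$lambda,
                 pe_cv = sc$pe_cv, me_cv = sc$me_cv, out)
  out
}

#' Run a (sub)grid of scenarios and summarize each
#'
#' Iterates [run_scenario()] over the crossing of the supplied factor
#' levels (defaults: the full study grid for the life history) and binds
#' the [summarize_scenario()] rows.  Scenario seeds are derived from
#' `seed`, so the full table is reproducible.
#'
#' @inheritParams run_scenario
#' @param lambda,pe_cv,me_cv,M Factor levels to cross.
#' @return Data frame with one row per scenario x model.
#' @export
run_grid <- function(spec, lambda = c(0.9, 0.95, 1.0, 1.025),
                     pe_cv = spec$pe_cv_grid, me_cv = c(0, 0.1, 0.3),
                     M = c(5, 10, 15, 20, 30, 40, 50),
                     n_reps = 1000, n_traj = 1000, horizon = 10,
                     seed = NULL, fecundity_denominator = "total",
                     empty_pool = "cap") {
  stopifnot(inherits(spec, "life_history"))
  if (!is.null(seed)) set.seed(seed)
  combos <- expand.grid(lambda = lambda, pe_cv = pe_cv, me_cv = me_cv,
                        KEEP.OUT.ATTRS = FALSE)
  combo_seeds <- sample.int(.Machine$integer.max, nrow(combos))
  out <- lapply(seq_len(nrow(combos)), function(i) {
    rec <- run_scenario(spec, combos$lambda[i], combos$pe_cv[i],
                        combos$me_cv[i], M = M, n_reps = n_reps,
                        n_traj = n_traj, horizon = horizon,
                        seed = combo_seeds[i],
                        fecundity_denominator = fecundity_denominator,
                        empty_pool = empty_pool)
    summarize_scenario(rec)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Percent reduction between two interquartile-range widths
#'
#' `100 * (iqr_from - iqr_to) / iqr_from`: the study's measure of how much
#' precision improves from one scenario to another (e.g. lengthening the
#' census window, or switching life history).
#'
#' @param iqr_from Reference IQR width (must be positive).
#' @param iqr_to Comparison IQR width.
#' @return Signed percent reduction (positive when `iqr_to` is narrower).
#' @export
iqr_reduction <- function(iqr_from, iqr_to) {
  if (any(iqr_from <= 0))
    stop("reference IQR width must be positive", call. = FALSE)
  100 * (iqr_from - iqr_to) / iqr_from
}

#' Look up one scenario's IQR width in a summary table
#'
#' Convenience selector over tables from [summarize_scenario()] or
#' [run_grid()].
#'
#' @param summary Summary data frame.
#' @param model `"scalar"` or `"matrix"`.
#' @param M Window length.
#' @param ... Further `column = value` filters (e.g. `lambda = 1.025`).
#' @return The matching `iqr_width` (scalar).
#' @export
scenario_iqr <- function(summary, model, M, ...) {
  keep <- summary$model == model & summary$M == M
  extra <- list(...)
  for (nm in names(extra)) keep <- keep & summary[[nm]] == extra[[nm]]
  w <- summary$iqr_width[keep]
  if (length(w) != 1L)
    stop("filters matched ", length(w), " rows; expected exactly 1",
         call. = FALSE)
  w
}
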