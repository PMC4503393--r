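#' Validate a run configuration
#'
#' Fills study defaults (growth rates 0.9, 0.95, 1.0, 1.025;
#' measurement-error CVs 0, 0.1, 0.3; window lengths 5, 10, 15, 20, 30,
#' 40, 50; the life history's own process-error grid; 1000 replicates and
#' 1000 trajectories) into a partial configuration and rejects invalid
#' values.  Process-error CVs are checked against the beta-distribution
#' feasibility bound for every mean survival in the life history —
#' `(cv * mu)^2 < mu * (1 - mu)` — which is what caps the snail grid at
#' 0.45.
#'
#' @param raw Named list of overrides.  Recognized keys: `life_history`
#'   (preset name or [life_history()] object), `lambda`, `pe_cv`, `me_cv`,
#'   `M`, `n_reps`, `n_traj`, `horizon`, `seed`,
#'   `fecundity_denominator`, `empty_pool`.
#' @return A validated `pva_config` list, directly splicable into
#'   [run_grid()].
#' @examples
#' validate_config(list(life_history = "hypothetical", lambda = 0.9))
#' @export
validate_config <- function(raw = list()) {
  stopifnot(is.list(raw))
  known <- c("life_history", "lambda", "pe_cv", "me_cv", "M", "n_reps",
             "n_traj", "horizon", "seed", "fecundity_denominator",
             "empty_pool")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  spec <- raw$life_history
  if (is.null(spec)) spec <- "hypothetical"
  if (is.character(spec)) spec <- life_history_preset(spec)
  stopifnot(inherits(spec, "life_history"))

  cfg <- list(
    life_history = spec,
    lambda = raw$lambda %||% c(0.9, 0.95, 1.0, 1.025),
    pe_cv = raw$pe_cv %||% spec$pe_cv_grid,
    me_cv = raw$me_cv %||% c(0, 0.1, 0.3),
    M = raw$M %||% c(5, 10, 15, 20, 30, 40, 50),
    n_reps = raw$n_reps %||% 1000,
    n_traj = raw$n_traj %||% 1000,
    horizon = raw$horizon %||% 10,
    seed = raw$seed,
    fecundity_denominator = raw$fecundity_denominator %||% "total",
    empty_pool = raw$empty_pool %||% "cap"
  )

  if (any(cfg$lambda <= 0)) stop("growth rates must be positive",
                                 call. = FALSE)
  if (any(cfg$me_cv < 0))
    stop("measurement-error CVs must be nonnegative", call. = FALSE)
  if (any(cfg$pe_cv < 0))
    stop("process-error CVs must be nonnegative", call. = FALSE)
  for (cv in cfg$pe_cv[cfg$pe_cv > 0]) {
    for (mu in spec$survival) {
      if ((cv * mu)^2 >= mu * (1 - mu))
        stop(sprintf(paste0(
          "process-error CV %g is infeasible for mean survival %g: ",
          "beta variance bound requires (cv*mu)^2 = %.4g < mu(1-mu) = %.4g"),
          cv, mu, (cv * mu)^2, mu * (1 - mu)), call. = FALSE)
    }
  }
  cfg$M <- as.integer(cfg$M)
  if (any(cfg$M < 2L | cfg$M > 50L))
    stop("window lengths must lie in [2, 50]", call. = FALSE)
  if (cfg$n_reps < 1 || cfg$n_traj < 1 || cfg$horizon < 1)
    stop("'n_reps', 'n_traj' and 'horizon' must be positive", call. = FALSE)
  if (!cfg$fecundity_denominator %in% c("total", "exclude_composite"))
    stop("'fecundity_denominator' must be \"total\" or \"exclude_composite\"",
         call. = FALSE)
  if (!cfg$empty_pool %in% c("cap", "drop"))
    stop("'empty_pool' must be \"cap\" or \"drop\"", call. = FALSE)
  class(cfg) <- "pva_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
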