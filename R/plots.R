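#' Box-plot summary of decline differences
#'
#' Box-and-whisker plots of the per-replicate differences between the true
#' and the median estimated percent decline, with window length on the
#' horizontal axis, faceted by process-error CV (rows) and
#' measurement-error CV (columns), one panel grid per model.  Boxes are
#' centered on the median difference (bias) and span the interquartile
#' range (the inverse of whose width is the study's precision measure).
#'
#' @param records Per-replicate records from [run_scenario()], or several
#'   such tables row-bound (with `pe_cv`/`me_cv` columns added).
#' @param model `"matrix"`, `"scalar"` or `"both"` (facet columns by
#'   model).
#' @return A ggplot object.
#' @export
boxplot_decline_differences <- function(records,
                                        model = c("both", "matrix",
                                                  "scalar")) {
  model <- match.arg(model)
  sc <- attr(records, "scenario")
  if (!is.null(sc) && is.null(records$pe_cv)) {
    records$pe_cv <- sc$pe_cv
    records$me_cv <- sc$me_cv
  }
  long <- rbind(
    data.frame(records[c("M", "pe_cv", "me_cv")], model = "scalar",
               diff = records$scalar_diff),
    data.frame(records[c("M", "pe_cv", "me_cv")], model = "matrix",
               diff = records$matrix_diff)
  )
  if (model != "both") long <- long[long$model == model, ]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$M),
                                          y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = "Census window length M (years)",
                  y = "True - estimated percent decline") +
    ggplot2::theme_bw()
  if (model == "both") {
    p + ggplot2::facet_grid(pe_cv ~ me_cv + model,
                            labeller = ggplot2::label_both)
  } else {
    p + ggplot2::facet_grid(pe_cv ~ me_cv, labeller = ggplot2::label_both)
  }
}
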