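# pvasim

Simulation testing of scalar and matrix population viability projections
under process error, measurement error, and short census time series.

## The problem

Conservation assessments (e.g. IUCN Red List criterion A.3) routinely rest
on a projected percent population decline over ten years, produced by a
population viability analysis (PVA). The analyst must pick a model family —
a *scalar* (count-based) model that resamples whole-population growth
rates, or a *matrix* (demographic) model built from age-specific survivals
and fecundities — and must fit it to a census that is short, noisy, and
shaped by year-to-year environmental variability. `pvasim` implements a
controlled factorial experiment that quantifies how model structure,
process error, measurement error, and census length jointly determine the
precision and bias of projected declines, for two short-lived life
histories: a ten-class hypothetical organism (all survivals 0.5) and the
threatened Tasmanian snail *Tasmaphena lamproides* (five classes,
survivals 0.4/0.5/0.8/0.75, composite self-loop 0.7).

## The method in brief

1. **Truth.** A 60-year age-structured census is simulated as
   `n[t+1] = A[t] n[t]` from 10⁹ individuals at the stable age
   distribution. Each year's Leslie matrix draws every vital rate
   independently: survivals from moment-matched beta distributions on
   [0, 1], the shared fecundity from a stretched beta on [0, 1000], each
   with standard deviation CV<sub>pe</sub> × mean. The shared fecundity is
   back-calculated so the mean matrix's dominant eigenvalue equals a target
   λ ∈ {0.9, 0.95, 1.0, 1.025}.
2. **Observation.** Every age-specific abundance is observed with
   Normal(n, CV<sub>me</sub>·n) noise (clamped at zero,
   CV<sub>me</sub> ∈ {0, 0.1, 0.3}); the last M ∈ {5, …, 50} census years
   form the fitting window.
3. **Models.** From the same window, the scalar model pools the M−1
   observed total-growth ratios; the matrix model pools cohort-ratio
   survivals and fecundities for an estimated model with a terminal
   composite class. Survival estimates above 1 (observed cohorts that
   "grew") are censored — excluded and counted — which is the mechanism
   that biases matrix projections toward over-estimated declines.
4. **Comparison.** Each model projects 10 years by resampling its pools;
   the per-replicate difference *true − median estimated decline* is
   summarized per scenario as bias (median difference) and precision
   (inverse IQR width).

## Worked example

```r
library(pvasim)
hyp <- life_history_preset("hypothetical")
back_calculate_fecundity(hyp, 1.025)
#> [1] 0.525

rec <- run_scenario(hyp, lambda = 1.025, pe_cv = 0.3, me_cv = 0.3,
                    M = c(5, 10, 15), n_reps = 200, n_traj = 200, seed = 40)
s <- summarize_scenario(rec)
s[, c("M", "model", "bias", "iqr_width", "precision", "mean_censored_frac")]
#>    M  model   bias iqr_width precision mean_censored_frac
#> 1  5 scalar  -8.81       171   0.00583             0.0856
#> 2  5 matrix -24.58       156   0.00639             0.0856
#> 3 10 scalar  -2.78       130   0.00769             0.0847
#> 4 10 matrix -23.37       112   0.00895             0.0847
#> 5 15 scalar   1.26       124   0.00806             0.0872
#> 6 15 matrix -22.94       103   0.00968             0.0872

iqr_reduction(scenario_iqr(s, "matrix", 5), scenario_iqr(s, "matrix", 10))
#> [1] 28.58153
```

Reading the output: at a growing truth (λ = 1.025) with strong process and
measurement error, the matrix model over-estimates decline by ~23–25
percentage points at every window length (negative bias = over-estimation;
the censored-survival mechanism, ~8.5% of estimates censored here), while
the scalar model is near-unbiased by M = 10. Lengthening the census from 5
to 10 years narrows the matrix model's IQR by ~29%; gains from 10 to 15
years are much smaller.

## The analysis workflow

Numbered drivers under `analysis/` run the experiment and write tables to
`results/`:

| script | what it does |
|---|---|
| `01_life_histories.R` | back-calculated fecundities, generation times |
| `02_true_series_properties.R` | realized stochastic growth rates, variance drag, census floors |
| `03_zero_error_collapse.R` | exact recovery of the truth when pe = me = 0 |
| `04_precision_window_length.R` | IQR reductions as the census lengthens (200×200) |
| `05_life_history_comparison.R` | snail vs hypothetical precision and bias |
| `06_grid_and_figures.R` | reduced-replication grid sweep + box-plot panels |

Each is a thin narrative wrapper over the package functions
(`simulate_true_series()`, `apply_measurement_error()`,
`extract_window()`, `estimate_scalar()`, `estimate_matrix()`,
`project_scalar()`, `project_matrix()`, `run_scenario()`, `run_grid()`),
so every computation is unit-tested in `tests/testthat/`. The methods
vignette (`vignettes/pva-simulation-experiment.Rmd`) documents the model,
its assumptions, and the design choices.

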