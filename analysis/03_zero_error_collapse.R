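#!/usr/bin/env Rscript

# Step 3: identifiability check - with no process and no measurement error
# both estimated models recover the truth exactly.
#
# Every scenario with pe_cv = me_cv = 0 must give decline differences of
# zero for both the scalar and the matrix model, at every growth rate,
# window length and life history: the cohort-ratio estimators read the true
# vital rates straight off the deterministic census, and resampling a
# degenerate pool reproduces the deterministic projection.

library(pvasim)

dir.create("results", showWarnings = FALSE)

rows <- list()
for (nm in c("hypothetical", "t_lamproides")) {
  spec <- life_history_preset(nm)
  for (l in c(0.9, 0.95, 1.0, 1.025)) {
    rec <- run_scenario(spec, l, pe_cv = 0, me_cv = 0,
                        M = c(5, 10, 15, 20, 30, 40, 50),
                        n_reps = 10, n_traj = 50, seed = 30)
    rows[[length(rows) + 1L]] <- data.frame(
      life_history = nm, lambda = l,
      max_abs_scalar_diff = max(abs(rec$scalar_diff)),
      max_abs_matrix_diff = max(abs(rec$matrix_diff)))
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/zero_error_collapse.csv", row.names = FALSE)

print(tab, row.names = FALSE)
cat(sprintf(paste0(
  "\nLargest absolute difference across all error-free scenarios: %.2e\n",
  "percentage points - pure floating-point round-off; the estimators are\n",
  "exact on error-free censuses.\n"),
  max(tab$max_abs_scalar_diff, tab$max_abs_matrix_diff)))
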