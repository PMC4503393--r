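#!/usr/bin/env Rscript

# Step 2: behavior of the "true" stochastic simulations.
#
# For each life history, growth rate and process-error CV, simulates
# replicate 60-year trajectories and summarizes the realized stochastic
# growth rate over the ten-year reference period (years 50-60): its mean
# drops below the deterministic lambda (variance drag) and its spread
# grows with process error.  Also tracks the minimum population total over
# the census years as a check that demographic stochasticity is safely
# ignorable at these abundances.

library(pvasim)

dir.create("results", showWarnings = FALSE)
set.seed(20)
n_reps <- 200  # desk-scale replication; the patterns are stable by here

specs <- list(hypothetical = life_history_preset("hypothetical"),
              t_lamproides = life_history_preset("t_lamproides"))
rows <- list()
for (nm in names(specs)) {
  spec <- specs[[nm]]
  for (l in c(0.9, 0.95, 1.0, 1.025)) {
    f <- back_calculate_fecundity(spec, l)
    for (pe in spec$pe_cv_grid) {
      g <- numeric(n_reps)
      min_total <- Inf
      for (i in seq_len(n_reps)) {
        traj <- simulate_true_series(spec, lambda = l, pe_cv = pe,
                                     fecundity = f)
        g[i] <- stochastic_growth_rate(traj)
        min_total <- min(min_total, traj$totals[1:51])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        life_history = nm, lambda = l, pe_cv = pe,
        mean_growth = mean(g), sd_growth = sd(g),
        min_census_total = min_total)
    }
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/stochastic_growth_rates.csv", row.names = FALSE)

cat("Realized ten-year stochastic growth rates (", n_reps, "replicates):\n")
print(tab, row.names = FALSE, digits = 4)
cat("\nMean growth tends to fall below lambda (variance drag) and its SD",
    "\nrises as process error increases; the smallest census total seen was",
    format(min(tab$min_census_total), big.mark = ","), "individuals.\n")
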