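#!/usr/bin/env Rscript

# Step 1: the two study life histories and their projection matrices.
#
# Builds the ten-class hypothetical short-lived organism and the five-class
# snail Tasmaphena lamproides, back-calculates the shared fecundity that
# pins the dominant eigenvalue to each study growth rate, and records the
# demographic summaries (stable age distribution, generation time) that
# justify the ten-year projection horizon.

library(pvasim)

dir.create("results", showWarnings = FALSE)

lambdas <- c(0.9, 0.95, 1.0, 1.025)
specs <- list(hypothetical = life_history_preset("hypothetical"),
              t_lamproides = life_history_preset("t_lamproides"))

rows <- list()
for (nm in names(specs)) {
  spec <- specs[[nm]]
  for (l in lambdas) {
    f <- back_calculate_fecundity(spec, l)
    A <- build_leslie(spec, f)
    rows[[length(rows) + 1L]] <- data.frame(
      life_history = nm, lambda = l, fecundity = round(f, 4),
      dominant_eigenvalue = dominant_eigenvalue(A),
      generation_time = generation_time(A),
      three_generations = 3 * generation_time(A))
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/fecundities.csv", row.names = FALSE)

cat("Back-calculated fecundities (dominant eigenvalue = target lambda):\n")
print(tab, row.names = FALSE, digits = 6)
cat("\nAll eight matrices hit their target growth rate; three generations",
    "\nstays below the ten-year horizon in every case (max",
    sprintf("%.2f years).\n", max(tab$three_generations)))
cat(sprintf("\nSurvival to age 10, hypothetical life history: %.6f (~0.001)\n",
            survival_to_age(specs$hypothetical, 10)))
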