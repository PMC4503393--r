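test_that("the scenario grid has exactly 336 combinations per life history", {
  g_hyp <- scenario_grid(hyp_spec)
  g_snail <- scenario_grid(snail_spec)
  expect_equal(nrow(g_hyp), 336)
  expect_equal(nrow(g_snail), 336)
  expect_equal(max(g_hyp$pe_cv), 0.5)
  expect_equal(max(g_snail$pe_cv), 0.45)
  expect_equal(nrow(scenario_grid(hyp_spec, lambda = 1.0)), 84)
  expect_equal(nrow(unique(g_hyp)), 336)
})

test_that("zero-error scenarios collapse to zero difference and zero IQR", {
  rec <- run_scenario(hyp_spec, 0.95, pe_cv = 0, me_cv = 0,
                      M = c(5, 50), n_reps = 3, n_traj = 40, seed = 801)
  expect_true(all(abs(rec$scalar_diff) < 1e-9))
  expect_true(all(abs(rec$matrix_diff) < 1e-9))
  s <- summarize_scenario(rec)
  expect_true(all(s$iqr_width < 1e-9))
  expect_true(all(is.na(s$precision) | s$precision > 0))
  expect_true(all(abs(s$bias) < 1e-9))
})

test_that("scenario runs are reproducible and extendable under a fixed seed", {
  a <- run_scenario(hyp_spec, 0.9, 0.3, 0.1, M = 10, n_reps = 6,
                    n_traj = 50, seed = 802)
  b <- run_scenario(hyp_spec, 0.9, 0.3, 0.1, M = 10, n_reps = 6,
                    n_traj = 50, seed = 802)
  expect_identical(a$matrix_diff, b$matrix_diff)
  expect_identical(summarize_scenario(a), summarize_scenario(b))
  # first replicates of a longer run coincide with a shorter run
  c4 <- run_scenario(hyp_spec, 0.9, 0.3, 0.1, M = 10, n_reps = 4,
                     n_traj = 50, seed = 802)
  expect_identical(a$matrix_diff[1:4], c4$matrix_diff)
})

test_that("replicate records have the documented shape and finite fields", {
  rec <- run_replicate(hyp_spec, 0.9, 0.3, 0.1, M = c(5, 10), n_traj = 50)
  expect_equal(rec$M, c(5, 10))
  expect_true(all(vapply(rec, function(x) all(is.finite(x)), logical(1))))
  expect_true(all(rec$true_decline <= 100))
  expect_equal(rec$scalar_diff, rec$true_decline - rec$scalar_median)
  expect_equal(rec$matrix_diff, rec$true_decline - rec$matrix_median)
})

test_that("IQR width grows with process error and shrinks with window length", {
  widths <- vapply(c(0.1, 0.3, 0.5), function(pe) {
    s <- summarize_scenario(
      run_scenario(hyp_spec, 0.9, pe, me_cv = 0, M = 20, n_reps = 40,
                   n_traj = 60, seed = 803))
    scenario_iqr(s, "matrix", 20)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))

  # precision gains concentrate below M ~ 15 and flatten after, so the
  # strict ordering is asserted against M = 5 only
  s <- summarize_scenario(
    run_scenario(hyp_spec, 1.0, 0.3, 0.3, M = c(5, 15, 50), n_reps = 150,
                 n_traj = 100, seed = 804))
  for (model in c("scalar", "matrix")) {
    w <- vapply(c(5, 15, 50), function(m) scenario_iqr(s, model, m),
                numeric(1))
    expect_gt(w[1], w[2])
    expect_gt(w[1], w[3])
  }
})

test_that("iqr_reduction and scenario_iqr compute the documented quantities", {
  expect_equal(iqr_reduction(10, 5), 50)
  expect_equal(iqr_reduction(10, 10), 0)
  expect_equal(iqr_reduction(10, 12), -20)
  expect_error(iqr_reduction(0, 5), "positive")

  s <- data.frame(model = c("scalar", "matrix"), M = c(5, 5),
                  iqr_width = c(2, 3))
  expect_equal(scenario_iqr(s, "matrix", 5), 3)
  expect_error(scenario_iqr(s, "matrix", 10), "matched 0")
})

test_that("run_grid binds one summary row per scenario and model", {
  s <- run_grid(hyp_spec, lambda = c(0.9, 1.025), pe_cv = 0.1,
                me_cv = c(0, 0.1), M = c(5, 10), n_reps = 4, n_traj = 30,
                seed = 805)
  expect_equal(nrow(s), 2 * 1 * 2 * 2 * 2)  # lambdas x pe x me x M x models
  expect_setequal(unique(s$model), c("scalar", "matrix"))
  expect_true(all(s$iqr_width >= 0))
})

test_that("configuration validation fills study defaults and rejects bad input", {
  cfg <- validate_config(list(life_history = "hypothetical"))
  expect_equal(cfg$lambda, c(0.9, 0.95, 1.0, 1.025))
  expect_equal(cfg$pe_cv, c(0, 0.1, 0.3, 0.5))
  expect_equal(cfg$me_cv, c(0, 0.1, 0.3))
  expect_equal(cfg$M, as.integer(c(5, 10, 15, 20, 30, 40, 50)))
  expect_equal(cfg$n_reps, 1000)
  expect_equal(cfg$n_traj, 1000)

  # beta feasibility: cv 0.5 on mean survival 0.8 breaches the bound
  expect_error(validate_config(list(life_history = "t_lamproides",
                                    pe_cv = 0.5)), "infeasible")
  # the snail's own capped grid is accepted
  expect_silent(validate_config(list(life_history = "t_lamproides")))
  expect_error(validate_config(list(me_cv = -0.1)), "nonnegative")
  expect_error(validate_config(list(bogus_key = 1)), "unknown")
})

test_that("box-plot summaries build from replicate records", {
  rec <- run_scenario(hyp_spec, 0.9, 0.3, 0.1, M = c(5, 10), n_reps = 5,
                      n_traj = 30, seed = 806)
  p <- boxplot_decline_differences(rec)
  expect_s3_class(p, "ggplot")
  pm <- boxplot_decline_differences(rec, model = "matrix")
  expect_s3_class(pm, "ggplot")
})
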