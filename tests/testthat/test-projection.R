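make_scalar_estimate <- function(pool, initial = 1000) {
  structure(list(lambda_pool = pool, initial_total = initial),
            class = "scalar_estimate")
}

make_matrix_estimate <- function(pools, fec, init,
                                 censored = rep(list(numeric(0)),
                                                length(pools))) {
  structure(
    list(n_est_classes = length(pools), survival_pools = pools,
         censored_values = censored, censored_counts = lengths(censored),
         fecundity_pool = fec, initial_vector = init,
         n_year_pairs = length(fec) + length(censored[[1]])),
    class = "matrix_estimate"
  )
}

test_that("degenerate pools give the deterministic closed-form decline", {
  r <- project_scalar(make_scalar_estimate(rep(0.9, 4)), n_traj = 100)
  expect_equal(unique(r$declines), 100 * (1 - 0.9^10), tolerance = 1e-12)
  expect_equal(round(median_percent_decline(r), 3), 65.132)

  r1 <- project_scalar(make_scalar_estimate(1.0), n_traj = 50)
  expect_equal(unique(r1$declines), 0)
})

test_that("scalar resampling converges to the exhaustive enumeration", {
  pool <- c(0.8, 1.2)
  exact <- enumerate_scalar_declines(pool, horizon = 2)
  # sequences (0.8,0.8), (0.8,1.2), (1.2,0.8), (1.2,1.2), equally likely
  expect_setequal(round(sort(unique(exact)), 10), c(-44, 4, 36))
  expect_equal(mean(abs(exact - 4) < 1e-9), 0.5)

  set.seed(701)
  mc <- project_scalar(make_scalar_estimate(pool), horizon = 2,
                       n_traj = 1e5)
  for (v in unique(exact)) {
    expect_equal(mean(abs(mc$declines - v) < 1e-9), mean(exact == v),
                 tolerance = 0.01)
  }

  # 3-value pool, horizon 3: compare full distributions by mean/median
  pool3 <- c(0.7, 1.0, 1.1)
  exact3 <- enumerate_scalar_declines(pool3, horizon = 3)
  set.seed(702)
  mc3 <- project_scalar(make_scalar_estimate(pool3), horizon = 3,
                        n_traj = 1e5)
  expect_equal(mean(mc3$declines), mean(exact3), tolerance = 0.01)
  expect_equal(stats::median(mc3$declines), stats::median(exact3),
               tolerance = 2)
})

test_that("matrix resampling matches brute-force enumeration on a 2-class model", {
  pools <- list(c(0.4, 0.6), c(0.5, 0.7))
  fec <- c(0.8, 1.1)
  init <- c(60, 40)
  # one projection year: enumerate all 2^3 rate combinations
  combos <- expand.grid(s1 = pools[[1]], comp = pools[[2]], f = fec)
  exact <- with(combos,
                100 * (100 - (f * 100 + s1 * 60 + comp * 40)) / 100)
  set.seed(703)
  mc <- project_matrix(make_matrix_estimate(pools, fec, init),
                       horizon = 1, n_traj = 1e5)
  expect_equal(mean(mc$declines), mean(exact), tolerance = 0.01)
  for (v in unique(exact)) {
    expect_equal(mean(abs(mc$declines - v) < 1e-9), 1 / 8,
                 tolerance = 0.01)
  }
})

test_that("single-class matrix projection reduces to scalar behavior", {
  # one composite class, fecundity zero: growth = composite survival draw
  est <- make_matrix_estimate(list(c(0.9, 0.9)), fec = c(0, 0), init = 100)
  r <- project_matrix(est, horizon = 10, n_traj = 50)
  expect_equal(unique(r$declines), 100 * (1 - 0.9^10), tolerance = 1e-9)
})

test_that("zero-error pools reproduce the deterministic truth end to end", {
  traj <- simulate_true_series(hyp_spec, lambda = 0.9, pe_cv = 0)
  w <- extract_window(apply_measurement_error(traj, 0), 10)
  true_dec <- true_percent_decline(traj)
  mx <- project_matrix(estimate_matrix(w, hyp_spec), n_traj = 64)
  sc <- project_scalar(estimate_scalar(w), n_traj = 64)
  expect_equal(unique(round(mx$declines, 9)), round(true_dec, 9))
  expect_equal(mx$median_decline, true_dec, tolerance = 1e-9)
  expect_equal(sc$median_decline, true_dec, tolerance = 1e-9)
})

test_that("projections are seed-reproducible and never negative", {
  est <- make_matrix_estimate(list(c(0.4, 0.9), c(0.3, 1.0)),
                              fec = c(0.2, 1.5), init = c(10, 5))
  set.seed(704)
  a <- project_matrix(est, n_traj = 200)
  set.seed(704)
  b <- project_matrix(est, n_traj = 200)
  expect_identical(a$declines, b$declines)
  expect_true(all(a$declines <= 100))
})

test_that("empty survival pools trigger the documented fallback or drop", {
  est <- make_matrix_estimate(list(numeric(0), c(0.5, 0.6)),
                              fec = c(0.4, 0.5), init = c(10, 5),
                              censored = list(c(1.4, 1.2), numeric(0)))
  set.seed(705)
  r <- project_matrix(est, n_traj = 100, empty_pool = "cap")
  expect_equal(r$fallback_classes, 1L)
  # capped pool values are all 1.0, so class-1 survival never exceeds one
  expect_true(all(is.finite(r$declines)))
  expect_error(project_matrix(est, n_traj = 10, empty_pool = "drop"),
               class = "pvasim_empty_pool")
})

test_that("median convention is the midpoint of central order statistics", {
  res <- structure(list(declines = c(10, 20, 30), model_type = "scalar"),
                   class = "projection_result")
  expect_equal(median_percent_decline(res), 20)
  res$declines <- c(10, 20, 30, 40)
  expect_equal(median_percent_decline(res), 25)
})
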