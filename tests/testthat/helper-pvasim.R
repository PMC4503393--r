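# Shared fixtures and independent oracles for the test suite.

hyp_spec <- life_history_preset("hypothetical")
snail_spec <- life_history_preset("t_lamproides")
study_lambdas <- c(0.9, 0.95, 1.0, 1.025)
study_M <- c(5, 10, 15, 20, 30, 40, 50)

# Independent power-iteration oracle for the dominant eigenpair.
power_iterate <- function(A, iters = 10000) {
  v <- rep(1, nrow(A))
  for (i in seq_len(iters)) {
    w <- A %*% v
    v <- as.numeric(w / sum(w))
  }
  list(lambda = sum(A %*% v) / sum(v), vector = v / sum(v))
}

# Euler-Lotka moment oracle for cohort generation time: truncated direct
# summation with the composite class extended age by age.
gen_time_oracle <- function(survival, fecundity, nmax = 5000) {
  K <- length(survival)
  l <- numeric(nmax)
  l[1] <- 1
  for (x in 2:nmax) l[x] <- l[x - 1] * survival[min(x - 1, K)]
  w <- l * fecundity
  sum(seq_len(nmax) * w) / sum(w)
}

# Exhaustive enumeration of scalar-projection declines: all pool^horizon
# sequences, equally likely.
enumerate_scalar_declines <- function(pool, horizon) {
  seqs <- expand.grid(rep(list(pool), horizon))
  growth <- apply(seqs, 1, prod)
  100 * (1 - growth)
}

# Hand-built 3-class observation window (no randomness) for estimator
# arithmetic: years 1..3, classes 1..3 (class 3 composite).
toy_window <- function(counts = rbind(c(100, 50, 40),
                                      c(60, 40, 45),
                                      c(90, 30, 50))) {
  rownames(counts) <- 1:3
  as_observed_window(counts, me_cv = 0)
}

# Tiny 3-class life history matching toy_window's shape.
toy_spec <- life_history("toy", survival = c(0.5, 0.6, 0.7))
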