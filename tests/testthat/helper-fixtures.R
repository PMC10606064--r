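# Shared fixtures and independent oracles used across test files.

# Reference titration concentrations (M): ligand-free point plus a 2-100 uM
# ramp, the working range of a tyrosine-quench titration.
titration_concs <- function() c(0, 2, 5, 10, 20, 50, 100) * 1e-6

qct_truth <- function(noise_cv = 0, seed = 1, ...) {
  quench_truth(f_a = 0.12, K = 1 / 2.4e-6, noise_cv = noise_cv, seed = seed,
               ...)
}

# Brute-force Otsu oracle: scan every distinct intensity as the class
# boundary and minimise the weighted within-class variance directly.
otsu_brute_force <- function(x) {
  x <- as.numeric(x)
  cand <- sort(unique(x))
  cand <- cand[-length(cand)]          # boundary below the max keeps 2 classes
  n <- length(x)
  wcv <- vapply(cand, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    v0 <- if (length(lo) > 1) stats::var(lo) * (length(lo) - 1) / length(lo) else 0
    v1 <- if (length(hi) > 1) stats::var(hi) * (length(hi) - 1) / length(hi) else 0
    (length(lo) * v0 + length(hi) * v1) / n
  }, numeric(1))
  cand[which.min(wcv)]
}

# Grid-search oracle for the two-population quench model: minimise the
# residual sum of squares of F([Q]) over an (f_a, K) grid.
quench_grid_oracle <- function(conc, f, F0, f_a_grid, K_grid) {
  best <- c(f_a = NA_real_, K = NA_real_, sse = Inf)
  for (fa in f_a_grid) {
    for (K in K_grid) {
      pred <- fa * F0 / (1 + K * conc) + (1 - fa) * F0
      sse <- sum((pred - f)^2)
      if (sse < best["sse"]) best <- c(f_a = fa, K = K, sse = sse)
    }
  }
  best
}

# Grid-search oracle for the median-effect model: minimise squared error in
# viability space over an (m, Dm) grid.
median_effect_grid_oracle <- function(doses, viability, m_grid, Dm_grid) {
  best <- c(m = NA_real_, Dm = NA_real_, sse = Inf)
  for (m in m_grid) {
    for (Dm in Dm_grid) {
      pred <- 1 - 1 / (1 + (Dm / doses)^m)
      sse <- sum((pred - viability)^2)
      if (sse < best["sse"]) best <- c(m = m, Dm = Dm, sse = sse)
    }
  }
  best
}
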