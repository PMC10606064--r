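test_that("inner-filter correction has the closed form and inverts the generator", {
  expect_equal(inner_filter_correct(100, 0, 0), 100)
  expect_equal(inner_filter_correct(100, 0.1, 0.1), 100 * exp(0.1))
  expect_error(inner_filter_correct(100, -0.1, 0), "non-negative")
  expect_error(inner_filter_correct(-5, 0, 0), "positive")

  # correcting the generator's attenuated signal returns the true intensity
  tr <- quench_truth(f_a = 0.4, K = 2e5, eps_ex_compound = 8000,
                     eps_em_compound = 2000, noise_cv = 0, seed = 2)
  ti <- simulate_titration(tr, titration_concs())
  expect_equal(inner_filter_correct(ti$F_obs, ti$A_ex, ti$A_em), ti$F_true,
               tolerance = 1e-12)
})

test_that("modified Stern-Volmer transform produces the analytic points", {
  # hand evaluation: f_a = 0.5, K = 1e6, [Q] = 1e-6 -> F0/dF = (1+K Q)/(f_a K Q)
  tr <- quench_truth(f_a = 0.5, K = 1e6, eps_ex_protein = 0, noise_cv = 0,
                     seed = 1)
  ti <- simulate_titration(tr, c(0, 1e-6, 2e-6, 4e-6, 8e-6))
  pts <- stern_volmer_points(ti)
  expect_equal(pts$F0_over_dF[pts$conc_M == 1e-6], 4.0, tolerance = 1e-12)
  # abscissae are exactly the reciprocals of the positive concentrations
  expect_equal(pts$inv_conc, 1 / c(1e-6, 2e-6, 4e-6, 8e-6))

  # constant intensity: no quench anywhere
  flat <- tibble::tibble(conc_M = c(0, 1e-6, 2e-6, 4e-6), F_obs = rep(100, 4))
  expect_error(stern_volmer_points(flat), "no quench")
})

test_that("noiseless round trip recovers f_a and K_D with and without inner filter", {
  cases <- list(
    list(f_a = 0.12, K_D = 2.4e-6),   # embedded binder
    list(f_a = 0.39, K_D = 7.0e-6),   # exposed binder
    list(f_a = 0.38, K_D = 6.4e-6),
    list(f_a = 1.00, K_D = 1.0e-5)    # fully accessible edge case
  )
  for (cs in cases) {
    for (eps in c(0, 6000)) {
      tr <- quench_truth(f_a = cs$f_a, K = 1 / cs$K_D,
                         eps_ex_compound = eps, noise_cv = 0, seed = 1)
      ti <- simulate_titration(tr, titration_concs())
      fit <- suppressWarnings(fit_modified_stern_volmer(ti))
      expect_equal(fit$f_a, cs$f_a, tolerance = 1e-3)
      expect_equal(fit$K_D, cs$K_D, tolerance = 1e-3)
    }
  }
})

test_that("K_D * K = 1 identity and intensity-scale invariance hold on every fit", {
  for (s in 1:5) {
    fa <- runif(1, 0.1, 1); KD <- 10^runif(1, -6.5, -5)
    tr <- quench_truth(f_a = fa, K = 1 / KD, noise_cv = 0.02, seed = s)
    ti <- simulate_titration(tr, titration_concs())
    fit <- suppressWarnings(fit_modified_stern_volmer(ti))
    expect_equal(fit$K_D * fit$K, 1, tolerance = 1e-12)

    ti_scaled <- dplyr::mutate(ti, F_obs = F_obs * 37.5)
    fit2 <- suppressWarnings(fit_modified_stern_volmer(ti_scaled))
    expect_equal(fit2$K_D, fit$K_D, tolerance = 1e-9)
    expect_equal(fit2$f_a, fit$f_a, tolerance = 1e-9)
  }
})

test_that("linear-transform estimate agrees with a grid-search oracle", {
  tr <- quench_truth(f_a = 0.3, K = 5e5, eps_ex_protein = 0, noise_cv = 0,
                     seed = 4)
  ti <- simulate_titration(tr, c(0, 1, 2, 5, 10, 20) * 1e-6)
  fit <- fit_modified_stern_volmer(ti)
  best <- quench_grid_oracle(
    ti$conc_M, ti$F_obs, F0 = ti$F_obs[ti$conc_M == 0],
    f_a_grid = seq(0.05, 1, length.out = 200),
    K_grid = 10^seq(4.5, 6.5, length.out = 200)
  )
  expect_equal(fit$f_a, unname(best["f_a"]), tolerance = 0.02)
  expect_equal(fit$K, unname(best["K"]), tolerance = 0.03)
})

test_that("regular Stern-Volmer is the linearity diagnostic", {
  # fully accessible fluorophore: regular and modified K agree
  tr1 <- quench_truth(f_a = 1, K = 2e5, noise_cv = 0, seed = 1)
  ti1 <- simulate_titration(tr1, titration_concs())
  reg <- fit_regular_stern_volmer(ti1)
  mod <- suppressWarnings(fit_modified_stern_volmer(ti1))
  expect_equal(reg$K_free, mod$K, tolerance = 1e-6)
  expect_equal(reg$intercept_free, 1, tolerance = 1e-6)

  # partially accessible fluorophore curves the regular plot
  tr2 <- quench_truth(f_a = 0.12, K = 1 / 2.4e-6, noise_cv = 0, seed = 1)
  ti2 <- simulate_titration(tr2, titration_concs())
  reg2 <- fit_regular_stern_volmer(ti2)
  mod2 <- fit_modified_stern_volmer(ti2)
  expect_lt(reg2$r_squared, mod2$r_squared)

  # no quench at all
  flat <- tibble::tibble(conc_M = c(0, 1e-6, 2e-6, 4e-6), F_obs = rep(10, 4))
  expect_error(fit_regular_stern_volmer(flat), "no quench")
})

test_that("fit errors and flags are informative", {
  # fluorescence increasing with ligand: wrong sign of quench
  up <- tibble::tibble(conc_M = c(0, 1e-6, 2e-6, 4e-6, 8e-6),
                       F_obs = c(100, 110, 120, 130, 140))
  expect_error(fit_modified_stern_volmer(up), "no quench|non-physical")

  # absorbance columns absent: result flagged uncorrected, not an error
  tr <- quench_truth(f_a = 0.5, K = 1e5, noise_cv = 0, seed = 1)
  ti <- dplyr::select(simulate_titration(tr, titration_concs()),
                      "conc_M", "F_obs")
  fit <- fit_modified_stern_volmer(ti)
  expect_true("uncorrected" %in% fit$flags)
})

test_that("nonlinear cross-check fit agrees with the linear transform", {
  tr <- quench_truth(f_a = 0.25, K = 4e5, noise_cv = 0, seed = 9)
  ti <- simulate_titration(tr, titration_concs())
  lin <- fit_modified_stern_volmer(ti)
  nls_fit <- fit_quench_nls(ti)
  expect_true(nls_fit$converged)
  expect_equal(nls_fit$f_a, lin$f_a, tolerance = 1e-4)
  expect_equal(nls_fit$K_D, lin$K_D, tolerance = 1e-4)
})

test_that("K_D estimator is approximately unbiased at 2 % noise", {
  # 1000 seeded replicates at the embedded-binder truth
  errs <- vapply(1:1000, function(s) {
    ti <- simulate_titration(qct_truth(noise_cv = 0.02, seed = s),
                             titration_concs())
    fit <- try(suppressWarnings(fit_modified_stern_volmer(ti)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    fit$K_D / 2.4e-6 - 1
  }, numeric(1))
  expect_lt(abs(median(errs, na.rm = TRUE)), 0.10)
})
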