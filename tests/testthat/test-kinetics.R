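test_that("exponential-plateau fit recovers noiseless parameters", {
  times <- ths_time_grid()
  y <- 100 + (-80) * exp(times / (-120))
  fit <- fit_exp_plateau(tibble::tibble(time_min = times, intensity = y))
  expect_true(fit$converged)
  expect_equal(fit$Y0, 100, tolerance = 1e-4)
  expect_equal(fit$A, -80, tolerance = 1e-4)
  expect_equal(fit$t_const, -120, tolerance = 1e-4)
  # the model's long-time prediction is the plateau Y0
  aug <- augment(fit)
  expect_equal(fit$Y0 + fit$A * exp(1e6 / fit$t_const), fit$Y0)

  # constant signal: degenerate flag, no nonlinear fit attempted
  flat <- fit_exp_plateau(tibble::tibble(time_min = times,
                                         intensity = rep(50, 36)))
  expect_true(flat$degenerate)
  expect_equal(flat$Y0, 50)
  expect_equal(flat$A, 0)
  expect_equal(plateau_value(flat), 50)
})

test_that("plateau estimates stay within the noise level for noisy wells", {
  truth <- aggregation_truth(half_inhibition_conc = 20, plateau_control = 1000,
                             baseline = 50, noise_cv = 0.02, seed = 1)
  hits <- vapply(1:500, function(s) {
    tr <- aggregation_truth(half_inhibition_conc = 20, plateau_control = 1000,
                            baseline = 50, noise_cv = 0.02, seed = s)
    tc <- simulate_ths_timecourse(tr, 0)
    fit <- fit_exp_plateau(tc)
    fit$converged && abs(fit$Y0 - 1000) <= 0.02 * 1000
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("inhibition percent has the plateau-referenced form", {
  expect_equal(inhibition_percent(100, 100, 20), 0)
  expect_equal(inhibition_percent(20, 100, 20), 100)
  expect_equal(inhibition_percent(60, 100, 20), 50)
  # cap at 100: a treated plateau below baseline cannot exceed full inhibition
  expect_equal(inhibition_percent(10, 100, 20), 100)
  expect_error(inhibition_percent(50, 20, 20), "exceed")

  # affine invariance: shifting all three inputs leaves the percent unchanged
  for (shift in c(-15, 0, 33, 1000)) {
    expect_equal(inhibition_percent(60 + shift, 100 + shift, 20 + shift), 50)
  }
})

test_that("IC50 from collinear log-dose points matches the closed form", {
  # slope 60 %/decade through (1, 20) and (10, 80): 50 % crossing at 10^0.5
  d <- tibble::tibble(conc_uM = c(1, 10^0.5, 10),
                      inhibition_pct = c(20, 50, 80))
  fit <- estimate_ic50(d)
  expect_equal(fit$slope, 60, tolerance = 1e-9)
  expect_equal(fit$intercept, 20, tolerance = 1e-9)
  expect_equal(fit$ic50, 10^0.5, tolerance = 1e-9)

  # flat response carries no dose information
  flat <- tibble::tibble(conc_uM = c(1, 3, 10), inhibition_pct = rep(40, 3))
  expect_error(estimate_ic50(flat), "no dose response")

  # fully saturated panel is rejected
  sat <- tibble::tibble(conc_uM = c(10, 30, 100), inhibition_pct = rep(100, 3))
  expect_error(estimate_ic50(sat), "saturated")

  # no observed point straddling 50 %: flagged extrapolated
  lo <- tibble::tibble(conc_uM = c(1, 2, 4), inhibition_pct = c(10, 20, 30))
  expect_true("extrapolated" %in% estimate_ic50(lo)$flags)
})

test_that("full panel chain recovers the generator half-inhibition concentration", {
  for (half in c(17.3, 9.7)) {
    truth <- aggregation_truth(half_inhibition_conc = half, noise_cv = 0,
                               seed = 2)
    panel <- simulate_ths_panel(truth, ths_panel_concentrations(half))
    res <- ths_inhibition_analysis(panel)
    expect_equal(res$ic50_fit$ic50, half, tolerance = 0.02)
  }
})

test_that("IC50 is equivariant under concentration unit rescaling", {
  truth <- aggregation_truth(half_inhibition_conc = 17.3, noise_cv = 0,
                             seed = 2)
  panel <- simulate_ths_panel(truth, ths_panel_concentrations(17.3))
  res_uM <- ths_inhibition_analysis(panel)
  panel_nM <- dplyr::mutate(panel, conc_uM = conc_uM * 1000)
  res_nM <- ths_inhibition_analysis(panel_nM)
  expect_equal(res_nM$ic50_fit$ic50, 1000 * res_uM$ic50_fit$ic50,
               tolerance = 1e-9)
})

test_that("saturated wells are excluded from the log-linear fit", {
  truth <- aggregation_truth(half_inhibition_conc = 10, noise_cv = 0, seed = 2)
  # three wells beyond twice the half-inhibition point saturate at 100 %
  panel <- simulate_ths_panel(truth, c(7, 9, 11, 13, 25, 40, 80))
  res <- ths_inhibition_analysis(panel)
  expect_equal(res$ic50_fit$n_saturated, 3)
  expect_equal(res$ic50_fit$n_points, 4)
  # the surviving 7-13 uM points span ~0.27 decades, so the log-axis
  # curvature bias is a few percent; the estimate must still centre on 10
  expect_equal(res$ic50_fit$ic50, 10, tolerance = 0.04)
})

test_that("dissolution trend separates dissolving from stable filaments", {
  times <- seq(0, 600, by = 60)
  falling <- tibble::tibble(time_min = times,
                            intensity = seq(100, 60, length.out = 11))
  tr <- dissolution_trend(falling)
  expect_equal(tr$classification, "dissolving")
  expect_equal(tr$relative_drop_pct, 40, tolerance = 1e-9)
  expect_lt(tr$slope, 0)

  flat <- tibble::tibble(time_min = times, intensity = rep(80, 11))
  expect_equal(dissolution_trend(flat)$classification, "stable")
  expect_equal(dissolution_trend(flat)$relative_drop_pct, 0)

  # an untreated assembly control rises to plateau: not dissolving
  ctrl <- simulate_ths_timecourse(
    aggregation_truth(half_inhibition_conc = 20, noise_cv = 0, seed = 1), 0)
  expect_equal(dissolution_trend(ctrl)$classification, "stable")
})
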