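test_that("noiseless titration follows the two-population quench model pointwise", {
  concs <- titration_concs()

  # no quencher, no inner filter: the observed signal is the full intensity
  tr0 <- quench_truth(f_a = 0.3, K = 1e5, F0_total = 1234,
                      eps_ex_protein = 0, noise_cv = 0, seed = 1)
  ti0 <- simulate_titration(tr0, concs)
  expect_equal(ti0$F_obs[ti0$conc_M == 0], 1234)

  # strong-binding limit: only the buried fraction remains at [Q] > 0
  tr_inf <- quench_truth(f_a = 0.25, K = 1e12, F0_total = 1000,
                         eps_ex_protein = 0, noise_cv = 0, seed = 1)
  ti_inf <- simulate_titration(tr_inf, concs)
  expect_equal(ti_inf$F_obs[ti_inf$conc_M > 0],
               rep(0.75 * 1000, sum(concs > 0)), tolerance = 1e-4)

  # hand evaluation at [Q] = K_D: accessible term is halved
  tr <- quench_truth(f_a = 0.12, K = 1 / 2.4e-6, F0_total = 1,
                     eps_ex_protein = 0, noise_cv = 0, seed = 1)
  ti <- simulate_titration(tr, c(0, 2.4e-6))
  expect_equal(ti$F_obs[2], 0.12 / 2 + 0.88, tolerance = 1e-12)

  # model identity on random truths
  for (s in 1:5) {
    fa <- runif(1, 0.05, 1); K <- 10^runif(1, 4, 7)
    trr <- quench_truth(f_a = fa, K = K, eps_ex_protein = 0, noise_cv = 0,
                        seed = s)
    tir <- simulate_titration(trr, concs)
    expect_equal(tir$F_obs,
                 fa * 1e6 / (1 + K * concs) + (1 - fa) * 1e6,
                 tolerance = 1e-12)
  }
})

test_that("titration rejects duplicate concentrations and attenuates by total absorbance", {
  tr <- quench_truth(f_a = 0.5, K = 1e5, eps_ex_compound = 5000,
                     eps_em_compound = 1000, noise_cv = 0, seed = 1)
  expect_error(simulate_titration(tr, c(0, 1e-6, 1e-6)), "duplicate")

  ti <- simulate_titration(tr, c(0, 1e-5, 1e-4))
  expect_equal(ti$A_ex, 7700 * 5e-6 + 5000 * c(0, 1e-5, 1e-4))
  expect_equal(ti$F_obs, ti$F_true * exp(-(ti$A_ex + ti$A_em) / 2))
})

test_that("seed changes noise only, never the noiseless expectation", {
  concs <- titration_concs()
  t1 <- simulate_titration(qct_truth(noise_cv = 0.02, seed = 1), concs)
  t2 <- simulate_titration(qct_truth(noise_cv = 0.02, seed = 2), concs)
  t1b <- simulate_titration(qct_truth(noise_cv = 0.02, seed = 1), concs)
  expect_identical(t1$F_obs, t1b$F_obs)
  expect_false(identical(t1$F_obs, t2$F_obs))
  expect_identical(t1$F_true, t2$F_true)
})

test_that("ThS time course plateaus follow the linear-then-saturating dose law", {
  tr <- aggregation_truth(half_inhibition_conc = 20, plateau_control = 1000,
                          baseline = 50, tau_rise = 120, noise_cv = 0,
                          seed = 3)
  t_long <- c(0, 500, 5000, 50000)

  ctrl <- simulate_ths_timecourse(tr, 0, times = t_long)
  expect_equal(ctrl$intensity[4], 1000, tolerance = 1e-6)
  expect_equal(ctrl$intensity[1], 50)

  half <- simulate_ths_timecourse(tr, 20, times = t_long)
  expect_equal(half$intensity[4], (1000 + 50) / 2, tolerance = 1e-6)

  # at twice the half-inhibition concentration the clip gives full
  # suppression: flat baseline at all times
  full <- simulate_ths_timecourse(tr, 40, times = ths_time_grid())
  expect_equal(full$intensity, rep(50, 36))

  expect_error(simulate_ths_timecourse(tr, -1), "compound_conc")

  # plateau monotone non-increasing in concentration
  plateaus <- vapply(c(0, 5, 10, 20, 30, 40, 80), function(cc) {
    max(simulate_ths_timecourse(tr, cc, times = t_long)$intensity)
  }, numeric(1))
  expect_true(all(diff(plateaus) <= 1e-9))
})

test_that("viability generator matches the median-effect closed form", {
  # D = Dm gives viability one half by definition
  expect_equal(simulate_viability(m = 2, Dm = 5, doses = 5, seed = 1)$viability,
               0.5)
  # compound-9-grade curve: m = 1, Dm = 1.6, D = 0.4 -> 1 - 1/(1+4)
  expect_equal(
    simulate_viability(m = 1, Dm = 1.6, doses = 0.4, seed = 1)$viability,
    0.8)
  # steep-slope limit approaches a step at Dm
  v <- simulate_viability(m = 200, Dm = 1, doses = c(0.9, 1.1), seed = 1)
  expect_gt(v$viability[1], 0.999)
  expect_lt(v$viability[2], 0.001)
})

test_that("persistent-random-walk tracks honour their limits", {
  # infinite persistence, noiseless steps: a straight line
  tr <- motility_truth(mean_speed = 1, persistence_time = Inf,
                       step_shape = Inf, n_frames = 61, total_time = 600,
                       seed = 5)
  tk <- simulate_tracks(tr, 1)
  m <- track_metrics(tk)
  expect_equal(m$persistence, 1, tolerance = 1e-12)
  expect_equal(m$total_distance, 600)

  # step-length sum equals mean_speed * total_time in noiseless mode
  tr2 <- motility_truth(mean_speed = 0.7, persistence_time = 10,
                        step_shape = Inf, seed = 6)
  m2 <- track_metrics(simulate_tracks(tr2, 3))
  expect_equal(m2$total_distance, rep(0.7 * 600, 3), tolerance = 1e-9)

  # zero speed: all points identical
  tr3 <- motility_truth(mean_speed = 0, persistence_time = 10, seed = 7)
  tk3 <- simulate_tracks(tr3, 1)
  expect_equal(diff(range(tk3$x_um)), 0)
  expect_equal(diff(range(tk3$y_um)), 0)

  # two populations at speed ratio 0.68: mean velocity ratio ~ 0.68
  fast <- track_metrics(simulate_tracks(
    motility_truth(mean_speed = 0.5, persistence_time = 30, seed = 8), 80))
  slow <- track_metrics(simulate_tracks(
    motility_truth(mean_speed = 0.34, persistence_time = 30, seed = 9), 80))
  expect_equal(mean(slow$velocity) / mean(fast$velocity), 0.68,
               tolerance = 0.05)
})

test_that("synthetic cell image has exact ground-truth coverage", {
  truth <- image_truth(width = 128, height = 128, cell_mask_fraction = 0.3,
                       mt_coverage_of_cell = 0.39, noise_sd = 0, seed = 11)
  img <- simulate_cell_image(truth)
  n_cell <- sum(img$cell_mask)
  # exact to pixel rounding: the foreground count is round(0.39 * n_cell)
  expect_lte(abs(sum(img$mt_mask) / n_cell - 0.39), 0.5 / n_cell + 1e-12)
  expect_true(all(img$mt_mask[img$mt_mask] & img$cell_mask[img$mt_mask]))
  # noiseless channels are two-valued
  expect_setequal(unique(as.numeric(img$tubulin)), c(50, 200))

  # full coverage: tubulin foreground equals the cell mask
  img1 <- simulate_cell_image(
    image_truth(width = 64, height = 64, mt_coverage_of_cell = 1, seed = 12))
  expect_identical(img1$mt_mask, img1$cell_mask)

  # infeasible requests are rejected with a message
  expect_error(
    simulate_cell_image(image_truth(width = 64, height = 64,
                                    cell_mask_fraction = 0.9,
                                    mt_coverage_of_cell = 0.4, seed = 1)),
    "does not fit")
  expect_error(
    simulate_cell_image(image_truth(width = 64, height = 64,
                                    cell_mask_fraction = 0.05,
                                    mt_coverage_of_cell = 1e-5, seed = 1)),
    "not achievable")
})
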