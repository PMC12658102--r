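test_that("c(s) round trip recovers a single species", {
  expt <- cell_experiment(times_s = seq(900, 9000, by = 450), rpm = 50000)
  sp <- hydro_species(1.5, n = 1,
                      M = mass_from_s(1.5, 1.4, 0.73, temperature_C = 25),
                      signal_coef = 0.01)
  # noise-free: integrated sw equals the true s to 1%
  clean <- gen_auc_scans(expt, sp, loading = 30, noise_sd = 0, seed = 1,
                         ncells = 250)
  cs <- fit_cs(clean, s_grid = seq(0.5, 8, length.out = 60), ncells = 200)
  expect_equal(integrate_cs(cs)$sw_S, 1.5, tolerance = 0.01)
  # noisy: still within 2% (seeded)
  noisy <- gen_auc_scans(expt, sp, loading = 30, noise_sd = 0.005, seed = 9,
                         ncells = 250)
  csn <- fit_cs(noisy, s_grid = seq(0.5, 8, length.out = 60), ncells = 200)
  expect_equal(integrate_cs(csn)$sw_S, 1.5, tolerance = 0.02)
  expect_lt(csn$rmsd, 0.0075)
})

test_that("a 1.5 + 4.0 S mixture resolves into two equal peaks", {
  expt <- cell_experiment(times_s = seq(900, 9000, by = 450), rpm = 50000)
  sp <- list(
    hydro_species(1.5, n = 1, M = mass_from_s(1.5, 1.4, 0.73, temperature_C = 25),
                  signal_coef = 0.01),
    hydro_species(4.0, n = 1, M = mass_from_s(4.0, 1.4, 0.73, temperature_C = 25),
                  signal_coef = 0.01))
  mix <- gen_auc_scans(expt, sp, loading = c(25, 25), noise_sd = 0.005,
                       seed = 5, ncells = 250)
  cs <- fit_cs(mix, s_grid = seq(0.5, 8, length.out = 60), ncells = 200)
  pk <- cs_peak_ranges(cs)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$s_peak, c(1.5, 4.0), tolerance = 0.05)
  loads <- vapply(seq_len(nrow(pk)), function(i)
    integrate_cs(cs, c(pk$s_lo[i], pk$s_hi[i]))$loading_AU, 0)
  expect_equal(loads[1] / loads[2], 1.0, tolerance = 0.1)
  # full-range sw: hand integration of the known equal mixture
  expect_equal(integrate_cs(cs)$sw_S, 2.75, tolerance = 0.03)
  # signal-to-concentration conversion recovers the loading
  expect_equal(integrate_cs(cs, signal_coef = 0.01,
                            pathlength_mm = 12)$loading_uM,
               50, tolerance = 0.05)
})

test_that("zero input flags a degenerate distribution; amplitudes stay nonnegative", {
  expt <- cell_experiment(times_s = seq(900, 5400, by = 900), rpm = 50000)
  zero <- scan_set(expt$times_s, small_radii(0.01),
                   matrix(0, length(expt$times_s), length(small_radii(0.01))),
                   rpm = 50000)
  cs <- fit_cs(zero, s_grid = seq(1, 5, length.out = 20))
  expect_true(cs$degenerate)
  expect_true(all(cs$c == 0))
  expect_error(fit_cs(zero, s_grid = c(1, 1, 2)), "increasing")
})

test_that("integrate_cs handles analytic distributions", {
  d <- structure(list(s = seq(1, 3, length.out = 41),
                      c = rep(1, 41), f_f0 = 1.4, lambda = 0, rmsd = 0,
                      degenerate = FALSE), class = "cs_distribution")
  out <- integrate_cs(d)
  expect_equal(out$sw_S, 2.0)                 # uniform on [1,3]
  expect_equal(out$loading_AU, 2.0)
  # delta-like peak at s0
  cc <- rep(0, 41); cc[21] <- 5
  d2 <- structure(list(s = d$s, c = cc, f_f0 = 1.4, lambda = 0, rmsd = 0,
                       degenerate = FALSE), class = "cs_distribution")
  expect_equal(integrate_cs(d2)$sw_S, d$s[21])
  expect_error(integrate_cs(d, s_range = c(10, 11)), "range")
})

test_that("regularization never lowers the misfit and keeps amplitudes nonnegative", {
  expt <- cell_experiment(times_s = seq(900, 7200, by = 900), rpm = 50000)
  sp <- hydro_species(2.5, n = 1,
                      M = mass_from_s(2.5, 1.4, 0.73, temperature_C = 25),
                      signal_coef = 0.01)
  noisy <- gen_auc_scans(expt, sp, loading = 30, noise_sd = 0.005, seed = 3,
                         ncells = 200, radii_cm = small_radii(0.01))
  grid <- seq(1, 5, length.out = 30)
  strong <- fit_cs(noisy, s_grid = grid, level = 0.95, ncells = 150)
  weak <- fit_cs(noisy, s_grid = grid, level = 0.683, ncells = 150)
  expect_gte(strong$rmsd, weak$rmsd - 1e-12)
  expect_true(all(strong$c >= 0) && all(weak$c >= 0))
})
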