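test_that("no rotor field leaves a uniform profile unchanged", {
  expt <- cell_experiment(times_s = c(600, 3600), rpm = 0)
  sp <- hydro_species(2.0, n = 1, signal_coef = 1)
  ss <- simulate_boundaries(expt, sp, loading = 10, ncells = 200)
  plateau <- 10 * 1.2
  expect_true(all(abs(ss$signal - plateau) < 1e-9 * plateau))
})

test_that("D = 0 boundary follows the analytic radial-dilution law", {
  expt <- cell_experiment(times_s = 3600, rpm = 50000, temperature_C = 20,
                          pathlength_mm = 10)
  sp <- hydro_species(2.0, n = 1, D_cm2s = 0, signal_coef = 1)
  ss <- simulate_boundaries(expt, sp, loading = 1, ncells = 2000, cfl = 0.5,
                            radii_cm = seq(6.0, 7.2, by = 0.003))
  sw2t <- 2e-13 * expt$omega2 * 3600
  r_true <- 6.0 * exp(sw2t)          # 6.12 cm
  plat_true <- exp(-2 * sw2t)        # 0.961
  y <- ss$signal[1, ]
  r <- ss$radii_cm
  plat <- mean(y[r > 6.5 & r < 7.0])
  expect_equal(plat, plat_true, tolerance = 1e-6)
  j <- which(y >= plat / 2)[1]
  mid <- r[j - 1] + (plat / 2 - y[j - 1]) / (y[j] - y[j - 1]) * (r[j] - r[j - 1])
  expect_equal(mid, r_true, tolerance = 0.005)
})

test_that("sector mass is conserved and the grid is converged", {
  expt <- cell_experiment(times_s = seq(600, 30000, by = 3000), rpm = 50000)
  sp <- hydro_species(1.54, n = 1, signal_coef = 0.01)
  radii <- seq(6.02, 7.14, by = 0.005)
  a <- simulate_boundaries(expt, sp, loading = 107, ncells = 400, cfl = 0.5,
                           radii_cm = radii)
  mt <- attr(a, "mass_trace")
  expect_lt(max(abs(mt - mt[1])) / mt[1], 1e-3)
  b <- simulate_boundaries(expt, sp, loading = 107, ncells = 800, cfl = 0.5,
                           radii_cm = radii)
  expect_lt(sqrt(mean((a$signal - b$signal)^2)) / max(b$signal), 2e-3)
  # reacting run conserves total monomer equivalents too
  hi <- simulate_boundaries(expt, mdt_species(), scheme = mdt_scheme(),
                            loading = 107, ncells = 300)
  mt2 <- attr(hi, "mass_trace")
  expect_lt(max(abs(mt2 - mt2[1])) / mt2[1], 1e-3)
})

test_that("the reacting solver reduces to independent species as Kds diverge", {
  expt <- cell_experiment(times_s = seq(1800, 14400, by = 3600), rpm = 50000)
  weak <- association_scheme(c(1, 2, 4), stepwise_kd = c(1e14, 1e14))
  radii <- small_radii(0.01)
  # same species list in both runs so the transport stepping is identical;
  # the independent run simply loads zero dimer and tetramer
  coupled <- simulate_boundaries(expt, mdt_species(), scheme = weak,
                                 loading = 50, ncells = 200,
                                 radii_cm = radii,
                                 return_concentrations = TRUE)
  solo <- simulate_boundaries(expt, mdt_species(), loading = c(50, 0, 0),
                              ncells = 200, radii_cm = radii,
                              return_concentrations = TRUE)
  expect_equal(attr(coupled, "conc")[, , 1], attr(solo, "conc")[, , 1],
               tolerance = 1e-9)
})

test_that("association raises the apparent boundary speed with loading", {
  expt <- small_expt()
  radii <- small_radii(0.01)
  hi <- simulate_boundaries(expt, mdt_species(), scheme = mdt_scheme(),
                            loading = 107, ncells = 200, radii_cm = radii)
  lo <- simulate_boundaries(expt, mdt_species(), scheme = mdt_scheme(),
                            loading = 17, ncells = 200, radii_cm = radii)
  # normalized remaining signal near the meniscus at the last scan:
  # the faster-sedimenting high-loading sample is more depleted
  near <- radii < 6.3
  last <- length(expt$times_s)
  f_hi <- mean(hi$signal[last, near]) / mean(hi$signal[1, near])
  f_lo <- mean(lo$signal[last, near]) / mean(lo$signal[1, near])
  expect_lt(f_hi, f_lo)
})

test_that("pathlength scales the signal linearly", {
  e3 <- cell_experiment(times_s = 3600, pathlength_mm = 3)
  e12 <- cell_experiment(times_s = 3600, pathlength_mm = 12)
  sp <- hydro_species(2.0, n = 1, signal_coef = 0.01)
  radii <- small_radii(0.01)
  s3 <- simulate_boundaries(e3, sp, loading = 10, ncells = 150, radii_cm = radii)
  s12 <- simulate_boundaries(e12, sp, loading = 10, ncells = 150, radii_cm = radii)
  expect_equal(4 * s3$signal, s12$signal, tolerance = 1e-12)
})
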