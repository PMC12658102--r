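test_that("noise-free single-species data self-fit to machine precision", {
  expt <- cell_experiment(times_s = seq(1800, 21600, length.out = 10),
                          rpm = 50000)
  sp <- hydro_species(2.0, n = 1, signal_coef = 0.01)
  d <- gen_auc_scans(expt, sp, loading = 30, noise_sd = 0, seed = 1,
                     ncells = 150, radii_cm = small_radii(0.01))
  f <- fit_association_model(d, association_scheme(1), expt, n_starts = 1,
                             ncells = 150)
  expect_lt(f$rmsd, 1e-6)
  expect_equal(unname(f$s_S), 2.0, tolerance = 1e-4)   # 4 significant figures
  # self-consistency: re-simulating at the fitted parameters reproduces rmsd
  r <- f$.resid_fun(f$par)
  expect_equal(sqrt(sum(r^2) / length(r)), f$rmsd, tolerance = 1e-6)
})

test_that("two-concentration recovery lands near the generating constants", {
  expt <- small_expt()
  radii <- small_radii()
  d58 <- gen_auc_scans(expt, mdt_species(), scheme = mdt_scheme(),
                       loading = 58, noise_sd = 0.005, seed = 21,
                       ncells = 150, radii_cm = radii)
  d107 <- gen_auc_scans(expt, mdt_species(), scheme = mdt_scheme(),
                        loading = 107, noise_sd = 0.005, seed = 22,
                        ncells = 150, radii_cm = radii)
  fit <- fit_association_model(list(d58, d107), mdt_scheme(), expt,
                               n_starts = 2, seed = 1, ncells = 150)
  expect_equal(fit$rmsd, 0.005, tolerance = 0.05)
  expect_equal(unname(fit$s_S[["monomer"]]), 1.54, tolerance = 0.03)
  expect_equal(unname(fit$s_S[["tetramer"]]), 3.94, tolerance = 0.08)
  expect_equal(unname(fit$loadings_uM), c(58, 107), tolerance = 0.03)
  # reduced-size fits determine Kd,dim-tet within a factor ~2
  expect_gt(fit$stepwise_kd_uM[2], 2.7 / 2.5)
  expect_lt(fit$stepwise_kd_uM[2], 2.7 * 2.5)
  # interval from the error-surface projection brackets the truth
  ci <- profile_interval(fit, "log10_kd2", max_steps = 12)
  expect_lt(ci[["lower"]], 2.7)
  expect_gt(ci[["upper"]], 2.7)
})

test_that("profile scan matches the analytic crossing on a quadratic surface", {
  # 1-parameter quadratic ssr(theta) = a + b (theta - t0)^2, no nuisance
  a <- 2.0; b <- 3.5; t0 <- 1.2
  refit <- function(theta, warm) list(ssr = a + b * (theta - t0)^2,
                                      warm = warm)
  target <- a * 1.05
  half <- sqrt((target - a) / b)
  out <- helimer:::.profile_scan(refit, setNames(t0, "x"), 1, a, target,
                                 step = half / 6, lo_bound = -10,
                                 hi_bound = 10, max_steps = 50)
  expect_equal(out$lower, t0 - half, tolerance = 0.02)
  expect_equal(out$upper, t0 + half, tolerance = 0.02)
  expect_false(any(out$open))
  # coverage over noisy quadratic surfaces: crossing recovered each time
  set.seed(4)
  cover <- vapply(1:20, function(i) {
    tt <- runif(1, -1, 1); bb <- runif(1, 0.5, 5)
    rf <- function(theta, warm) list(ssr = 1 + bb * (theta - tt)^2,
                                     warm = warm)
    o <- helimer:::.profile_scan(rf, setNames(tt, "x"), 1, 1, 1.1,
                                 step = 0.05, lo_bound = -10, hi_bound = 10,
                                 max_steps = 60)
    h <- sqrt(0.1 / bb)
    abs(o$lower - (tt - h)) < 0.05 && abs(o$upper - (tt + h)) < 0.05
  }, TRUE)
  expect_gte(mean(cover), 0.9)
  # insensitive parameter: flat surface -> open interval flagged
  flat <- function(theta, warm) list(ssr = 1, warm = warm)
  o <- helimer:::.profile_scan(flat, setNames(0, "x"), 1, 1, 1.1, 0.5,
                               -10, 10, 10)
  expect_true(all(o$open))
  expect_identical(unname(c(o$lower, o$upper)), c(-Inf, Inf))
})

test_that("scheme comparison ranks the generating model first and flags misfits", {
  expt <- small_expt(10)
  radii <- small_radii(0.01)
  d107 <- gen_auc_scans(expt, mdt_species(), scheme = mdt_scheme(),
                        loading = 107, noise_sd = 0.005, seed = 31,
                        ncells = 150, radii_cm = radii)
  md <- association_scheme(c(1, 2), stepwise_kd = 100)
  mt <- association_scheme(c(1, 4), overall_kd = 1e5)
  cmp <- suppressWarnings(
    compare_schemes(d107, list(md, mdt_scheme(), mt), expt, n_starts = 2,
                    seed = 1, ncells = 150))
  expect_equal(cmp$scheme[1], "monomer-dimer-tetramer")
  # the two-state monomer-dimer model misfits by well over 2x the noise SD
  i_md <- which(cmp$scheme == "monomer-dimer")
  expect_gt(cmp$rmsd[i_md], 2 * 0.005)
  expect_false(cmp$plausible[i_md])
  # monomer-tetramer reaches similar fit quality (rmsd ratio within 10%)
  i_mt <- which(cmp$scheme == "monomer-tetramer")
  expect_lt(cmp$rmsd[i_mt] / cmp$rmsd[1], 1.1)
})

test_that("single-species data rank the single-species scheme first", {
  expt <- small_expt(8)
  radii <- small_radii(0.012)
  sp <- hydro_species(2.0, n = 1, signal_coef = 0.01)
  d <- gen_auc_scans(expt, sp, loading = 30, noise_sd = 0.003, seed = 2,
                     ncells = 120, radii_cm = radii)
  cmp <- suppressWarnings(
    compare_schemes(d, list(association_scheme(1),
                            association_scheme(c(1, 2), stepwise_kd = 10)),
                    expt, n_starts = 1, seed = 1, ncells = 120))
  # equal fit quality is a tie; the monomer-only model must not lose
  expect_lte(cmp$rmsd[cmp$scheme == "monomer"],
             cmp$rmsd[cmp$scheme == "monomer-dimer"] * 1.02)
})
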