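#' Describe a sedimentation-velocity cell and run
#'
#' @param times_s scan times in seconds, strictly increasing.
#' @param meniscus_cm,bottom_cm radial positions of the meniscus and cell
#'   bottom, cm (0 < meniscus < bottom).
#' @param rpm rotor speed, revolutions per minute.
#' @param temperature_C run temperature.
#' @param density,viscosity solvent density (g/mL) and viscosity (poise);
#'   default water at the run temperature.
#' @param pathlength_mm optical pathlength of the centerpiece, mm.
#' @return an object of class `cell_experiment`.
#' @examples
#' cell_experiment(times_s = seq(600, 30000, by = 600))
#' @export
cell_experiment <- function(times_s, meniscus_cm = 6.0, bottom_cm = 7.2,
                            rpm = 50000, temperature_C = 25, density = NULL,
                            viscosity = NULL, pathlength_mm = 12) {
  stopifnot(is.numeric(times_s), length(times_s) >= 1, all(is.finite(times_s)),
            all(times_s > 0))
  if (is.unsorted(times_s, strictly = TRUE)) stop("scan times must be strictly increasing")
  if (!(meniscus_cm > 0 && bottom_cm > meniscus_cm))
    stop("need 0 < meniscus < bottom")
  if (!(rpm >= 0)) stop("rpm must be >= 0")
  if (is.null(density)) density <- water_density(temperature_C)
  if (is.null(viscosity)) viscosity <- water_viscosity(temperature_C)
  omega <- rpm * 2 * pi / 60
  structure(list(times_s = times_s, meniscus_cm = meniscus_cm,
                 bottom_cm = bottom_cm, rpm = rpm, omega = omega,
                 omega2 = omega^2, temperature_C = temperature_C,
                 density = density, viscosity = viscosity,
                 pathlength_mm = pathlength_mm),
            class = "cell_experiment")
}

#' Hydrodynamic description of a sedimenting species
#'
#' @param s_S sedimentation coefficient at experimental conditions, Svedberg.
#' @param n monomer units in the species (used for reacting systems and for
#'   the per-species molar mass default `n * monomer_mass`).
#' @param M molar mass in Da; default `n * monomer_mass`.
#' @param monomer_mass monomer molar mass, Da.
#' @param vbar partial specific volume, mL/g.
#' @param D_cm2s diffusion coefficient; if `NULL` it is derived from the
#'   Svedberg relation `D = s R T / (M (1 - vbar rho))` at simulation time.
#' @param signal_coef per-monomer signal coefficient, AU/(µM cm).  Species
#'   signal is `signal_coef * n * molar concentration * pathlength`.
#' @param label species label.
#' @return an object of class `hydro_species`.
#' @export
hydro_species <- function(s_S, n = 1, M = NULL, monomer_mass = 16000,
                          vbar = 0.73, D_cm2s = NULL, signal_coef = 0.01,
                          label = NULL) {
  stopifnot(is.finite(s_S), s_S > 0, n >= 1, n == round(n))
  if (is.null(M)) M <- n * monomer_mass
  stopifnot(M > 0, signal_coef >= 0)
  if (vbar <= 0.5 || vbar >= 1.0)
    warning("partial specific volume outside the usual protein range (0.5, 1.0)")
  if (!is.null(D_cm2s) && D_cm2s < 0) stop("D must be >= 0")
  if (is.null(label)) label <- .nmer_label(n)
  structure(list(label = label, s_S = s_S, n = as.integer(n), M = M,
                 vbar = vbar, D_cm2s = D_cm2s, signal_coef = signal_coef),
            class = "hydro_species")
}

#' Construct a scan set
#'
#' Container for one sedimentation-velocity experiment: timed radial signal
#' profiles plus run metadata.
#'
#' @param times_s scan times, s.
#' @param radii_cm radii common to all scans, strictly increasing.
#' @param signal matrix of signal (AU), scans in rows.
#' @param rpm,temperature_C,pathlength_mm run metadata.
#' @param label set label (e.g. loading concentration).
#' @param truth optional list recording the generating ground truth.
#' @return object of class `scan_set`.
#' @export
scan_set <- function(times_s, radii_cm, signal, rpm, temperature_C = 25,
                     pathlength_mm = 12, label = "", truth = NULL) {
  signal <- as.matrix(signal)
  stopifnot(length(times_s) == nrow(signal), length(radii_cm) == ncol(signal))
  if (is.unsorted(radii_cm, strictly = TRUE)) stop("radii must be strictly increasing")
  if (any(!is.finite(signal))) stop("signal must be finite")
  structure(list(times_s = times_s, radii_cm = radii_cm, signal = signal,
                 rpm = rpm, temperature_C = temperature_C,
                 pathlength_mm = pathlength_mm, label = label, truth = truth),
            class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat("scan set", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      ":", nrow(x$signal), "scans,", length(x$radii_cm), "radii,",
      x$rpm, "rpm\n")
  invisible(x)
}

#' Forward-simulate sedimentation-velocity boundaries
#'
#' Solves the Lamm equation for each species on a conservative
#' finite-volume radial grid with no-flux walls.  For a reacting scheme the
#' species are transported independently within each time step and then
#' re-equilibrated cell-by-cell onto the mass-action manifold, conserving
#' local monomer equivalents (the rapid-equilibrium limit appropriate for
#' fast-exchange self-association).  Exponential flux fitting keeps the
#' scheme stable and mass-conservative from the diffusion-dominated to the
#' D = 0 limit.
#'
#' @param experiment a [cell_experiment].
#' @param species list of [hydro_species], ordered to match `scheme` when
#'   one is given.
#' @param scheme optional [association_scheme] linking the species.
#' @param loading with a scheme: total loading in µM monomer equivalents
#'   (scalar); without: per-species molar concentrations in µM.
#' @param radii_cm radii at which scans are reported; default every
#'   0.003 cm across the solution column.
#' @param ncells number of radial cells (default 500).
#' @param cfl advective Courant number controlling the time step.
#' @param theta time-weighting (0.5 = Crank-Nicolson, 1 = implicit Euler).
#' @param return_concentrations keep per-species concentration profiles as
#'   attribute `"conc"`.
#' @return a [scan_set] of noise-free signal profiles; attribute
#'   `"mass_trace"` holds the total monomer-equivalent sector mass at t = 0
#'   and at each scan (conserved to well under 0.1%).
#' @export
simulate_boundaries <- function(experiment, species, scheme = NULL, loading,
                                radii_cm = NULL, ncells = 500, cfl = 1.0,
                                theta = 0.5, return_concentrations = FALSE) {
  stopifnot(inherits(experiment, "cell_experiment"))
  if (inherits(species, "hydro_species")) species <- list(species)
  stopifnot(all(vapply(species, inherits, TRUE, "hydro_species")))
  nspec <- length(species)
  n_units <- vapply(species, function(x) as.numeric(x$n), 0)

  react <- !is.null(scheme)
  if (react) {
    stopifnot(inherits(scheme, "association_scheme"))
    if (length(scheme$n) != nspec || any(scheme$n != n_units))
      stop("species must map one-to-one onto scheme species (same n, same order)")
    if (length(loading) != 1 || loading <= 0)
      stop("with a scheme, loading is a positive total in µM monomer equivalents")
    c0 <- unname(solve_speciation(loading, scheme)$molar_uM)
    K <- scheme$K_uM
  } else {
    if (length(loading) != nspec) stop("need one molar loading per species")
    if (any(loading < 0)) stop("loadings must be >= 0")
    c0 <- loading
    K <- rep(1, nspec)
  }

  s_sec <- vapply(species, function(x) x$s_S * 1e-13, 0)
  D <- vapply(species, function(x) {
    if (!is.null(x$D_cm2s)) x$D_cm2s
    else .d_from_svedberg(x$s_S, x$M, x$vbar, experiment$density,
                          experiment$temperature_C)
  }, 0)

  sol <- .lamm_solve_cpp(experiment$meniscus_cm, experiment$bottom_cm,
                         as.integer(ncells), experiment$omega2, s_sec, D, c0,
                         experiment$times_s, n_units, K, react, cfl, theta)
  conc <- array(sol$conc, dim = c(ncells, length(experiment$times_s), nspec))

  # default reporting range leaves out the optical artifacts at the
  # meniscus and the back-diffusion pile-up at the bottom, as a fit
  # range on real data would
  if (is.null(radii_cm))
    radii_cm <- seq(experiment$meniscus_cm + 0.01,
                    experiment$bottom_cm - 0.05, by = 0.003)
  nt <- length(experiment$times_s)
  sig <- matrix(0, nt, length(radii_cm))
  pl_cm <- experiment$pathlength_mm / 10
  for (k in seq_len(nspec)) {
    coef <- species[[k]]$signal_coef * n_units[k] * pl_cm
    if (coef == 0) next
    for (it in seq_len(nt))
      sig[it, ] <- sig[it, ] + coef *
        approx(sol$r, conc[, it, k], xout = radii_cm, rule = 2)$y
  }
  ss <- scan_set(experiment$times_s, radii_cm, sig, experiment$rpm,
                 experiment$temperature_C, experiment$pathlength_mm)
  attr(ss, "mass_trace") <- sol$mass_trace
  if (return_concentrations) {
    attr(ss, "conc") <- conc
    attr(ss, "r_centers") <- sol$r
  }
  ss
}
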