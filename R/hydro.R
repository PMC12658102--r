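#' Hydrodynamics of an equivalent sphere
#'
#' The standard Svedberg / Stokes-Einstein / sphere-volume triplet: from a
#' molar mass, partial specific volume and frictional ratio, compute the
#' anhydrous sphere radius `R0 = (3 M vbar / 4 pi N_A)^(1/3)`, the friction
#' coefficient `f = 6 pi eta (f/f0) R0`, the diffusion coefficient
#' `D = k_B T / f` and the sedimentation coefficient
#' `s = M (1 - vbar rho) / (N_A f)`.
#'
#' @param M molar mass, Da.
#' @param vbar partial specific volume, mL/g.  Values outside (0.5, 1.0)
#'   trigger a warning (unusual for proteins).
#' @param f_f0 frictional ratio, >= 1.
#' @param rho,eta solvent density (g/mL) and viscosity (poise); default
#'   water at `temperature_C`.
#' @param temperature_C temperature, degrees Celsius.
#' @return list with `R0_nm`, `f`, `D_cm2s`, `s_S`.
#' @examples
#' sphere_hydrodynamics(14000, vbar = 0.73, f_f0 = 1.0)$s_S  # about 2.1 S
#' @export
sphere_hydrodynamics <- function(M, vbar = 0.73, f_f0 = 1.0, rho = NULL,
                                 eta = NULL, temperature_C = 20) {
  stopifnot(is.finite(M), M > 0, is.finite(f_f0), f_f0 >= 1)
  if (vbar <= 0.5 || vbar >= 1.0)
    warning("partial specific volume outside the usual protein range (0.5, 1.0)")
  if (is.null(rho)) rho <- water_density(temperature_C)
  if (is.null(eta)) eta <- water_viscosity(temperature_C)
  buoy <- 1 - vbar * rho
  if (buoy <= 0) stop("non-physical buoyancy: 1 - vbar*rho <= 0")
  TK <- temperature_C + 273.15
  R0 <- (3 * M * vbar / (4 * pi * .const$N_A))^(1 / 3) # cm
  f <- 6 * pi * eta * f_f0 * R0
  D <- .const$k_B * TK / f
  s <- M * buoy / (.const$N_A * f)
  list(R0_nm = R0 * 1e7, f = f, D_cm2s = D, s_S = s / 1e-13)
}

#' Molar mass from a sedimentation coefficient and frictional ratio
#'
#' Inverse of [sphere_hydrodynamics]: since `s` scales as `M^(2/3)` at
#' fixed `vbar` and `f/f0`, the mass follows in closed form.
#'
#' @inheritParams sphere_hydrodynamics
#' @param s_S sedimentation coefficient, Svedberg.
#' @return molar mass in Da.
#' @export
mass_from_s <- function(s_S, f_f0 = 1.0, vbar = 0.73, rho = NULL, eta = NULL,
                        temperature_C = 20) {
  stopifnot(is.finite(s_S), s_S > 0, f_f0 >= 1)
  if (is.null(rho)) rho <- water_density(temperature_C)
  if (is.null(eta)) eta <- water_viscosity(temperature_C)
  buoy <- 1 - vbar * rho
  if (buoy <= 0) stop("non-physical buoyancy: 1 - vbar*rho <= 0")
  s <- s_S * 1e-13
  a <- (3 * vbar / (4 * pi * .const$N_A))^(1 / 3)
  (s * .const$N_A * 6 * pi * eta * f_f0 * a / buoy)^(3 / 2)
}

#' Diffusion coefficient implied by s and a frictional ratio
#'
#' Used to build c(s) Lamm-solution libraries: the mass follows from
#' [mass_from_s], then `D = k_B T / f`.
#'
#' @inheritParams mass_from_s
#' @return diffusion coefficient, cm^2/s.
#' @export
d_from_s <- function(s_S, f_f0 = 1.4, vbar = 0.73, rho = NULL, eta = NULL,
                     temperature_C = 20) {
  if (is.null(rho)) rho <- water_density(temperature_C)
  if (is.null(eta)) eta <- water_viscosity(temperature_C)
  M <- mass_from_s(s_S, f_f0, vbar, rho, eta, temperature_C)
  sphere_hydrodynamics(M, vbar, f_f0, rho, eta, temperature_C)$D_cm2s
}

# Svedberg relation: D = s R T / (M (1 - vbar rho)), s in Svedberg
.d_from_svedberg <- function(s_S, M, vbar, rho, temperature_C) {
  buoy <- 1 - vbar * rho
  if (buoy <= 0) stop("non-physical buoyancy: 1 - vbar*rho <= 0")
  s_S * 1e-13 * .const$R * (temperature_C + 273.15) / (M * buoy)
}

#' Correct a sedimentation coefficient to standard conditions
#'
#' `s20,w = s_exp * (eta_exp / eta_20w) * (1 - vbar rho_20w) / (1 - vbar rho_exp)`,
#' with water-at-20-C constants bundled (rho 0.99821 g/mL, eta 1.0020 cP).
#'
#' @param s_S experimental sedimentation coefficient, Svedberg.
#' @param rho_exp,eta_exp experimental solvent density (g/mL) and viscosity
#'   (poise).
#' @param vbar partial specific volume, mL/g.
#' @return s20,w in Svedberg.
#' @examples
#' standardize_s(1.40, water_density(25), water_viscosity(25), vbar = 0.73)
#' @export
standardize_s <- function(s_S, rho_exp, eta_exp, vbar) {
  stopifnot(is.finite(s_S), is.finite(rho_exp), rho_exp > 0,
            is.finite(eta_exp), eta_exp > 0, is.finite(vbar), vbar > 0)
  b_exp <- 1 - vbar * rho_exp
  b_20w <- 1 - vbar * .water20$rho
  if (b_exp <= 0 || b_20w <= 0) stop("non-physical buoyancy: 1 - vbar*rho <= 0")
  s_S * (eta_exp / .water20$eta) * b_20w / b_exp
}
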