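#' Density of pure water
#'
#' Kell's polynomial for the density of air-free water at atmospheric
#' pressure, valid 0-100 degrees C.
#'
#' @param temperature_C temperature in degrees Celsius.
#' @return density in g/mL.
#' @examples
#' water_density(20)  # 0.9982
#' @export
water_density <- function(temperature_C) {
  t <- temperature_C
  stopifnot(is.numeric(t), all(is.finite(t)), all(t >= 0), all(t <= 100))
  num <- 999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 -
    46.170461e-6 * t^3 + 105.56302e-9 * t^4 - 280.54253e-12 * t^5
  num / (1 + 16.879850e-3 * t) / 1000
}

#' Viscosity of pure water
#'
#' Standard correlations (Hardy & Cottington below 20 C, Korson et al.
#' above) anchored at 1.0020 cP at 20 C.
#'
#' @param temperature_C temperature in degrees Celsius.
#' @return dynamic viscosity in poise.
#' @examples
#' water_viscosity(20)  # 0.010020
#' @export
water_viscosity <- function(temperature_C) {
  t <- temperature_C
  stopifnot(is.numeric(t), all(is.finite(t)), all(t >= 0), all(t <= 100))
  eta20 <- 1.0020 # cP
  cp <- ifelse(
    t >= 20,
    eta20 * 10^((1.3272 * (20 - t) - 0.001053 * (20 - t)^2) / (t + 105)),
    10^(1301 / (998.333 + 8.1855 * (t - 20) + 0.00585 * (t - 20)^2) - 3.30233)
  )
  cp / 100
}

# water at 20 C, the s20,w reference state
.water20 <- list(rho = 0.9982071, eta = 0.010020)
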