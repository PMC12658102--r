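#' Fit a continuous c(s) distribution
#'
#' Builds a library of noise-free single-species Lamm solutions on a grid of
#' sedimentation coefficients (diffusion tied to s through a common
#' frictional ratio), then solves the non-negative least-squares problem
#' with a second-derivative Tikhonov penalty.  The penalty strength is
#' scaled so that the penalized chi-square exceeds the unpenalized minimum
#' by the one-standard-deviation F-ratio (confidence level `level`),
#' mirroring standard maximum-entropy/Tikhonov practice in sedimentation
#' analysis.
#'
#' @param scans a [scan_set].
#' @param s_grid grid of sedimentation coefficients, Svedberg, strictly
#'   increasing (default 100 points on 0.5-10 S).
#' @param f_f0 common frictional ratio, or `"fit"` to scan `f_f0_grid` and
#'   return the best.
#' @param vbar partial specific volume, mL/g.
#' @param level confidence level of the regularization F-ratio.
#' @param skip_scans drop this many early scans before fitting (large
#'   aggregates clear the cell early; dropping early scans removes their
#'   contribution).
#' @param ncells radial cells used for the library solutions.
#' @param f_f0_grid frictional-ratio grid used when `f_f0 = "fit"`.
#' @return object of class `cs_distribution`: `s`, `c` (signal per S),
#'   `f_f0`, `lambda`, `rmsd`, `degenerate`.
#' @export
fit_cs <- function(scans, s_grid = seq(0.5, 10, length.out = 100),
                   f_f0 = 1.4, vbar = 0.73, level = 0.683, skip_scans = 0,
                   ncells = 250, f_f0_grid = seq(1.1, 2.0, by = 0.1)) {
  stopifnot(inherits(scans, "scan_set"))
  if (is.unsorted(s_grid, strictly = TRUE))
    stop("s grid must be strictly increasing (no duplicate s)")
  if (skip_scans > 0) {
    keep <- setdiff(seq_along(scans$times_s), seq_len(skip_scans))
    scans <- scan_set(scans$times_s[keep], scans$radii_cm,
                      scans$signal[keep, , drop = FALSE], scans$rpm,
                      scans$temperature_C, scans$pathlength_mm, scans$label)
  }
  if (length(scans$times_s) < 5) stop("need at least 5 scans")
  b <- as.vector(t(scans$signal))
  if (all(b == 0)) {
    return(structure(list(s = s_grid, c = rep(0, length(s_grid)),
                          f_f0 = if (identical(f_f0, "fit")) NA_real_ else f_f0,
                          lambda = 0, rmsd = 0, degenerate = TRUE),
                     class = "cs_distribution"))
  }
  if (identical(f_f0, "fit")) {
    fits <- lapply(f_f0_grid, function(ff)
      .fit_cs_one(scans, s_grid, ff, vbar, level, ncells, b))
    best <- which.min(vapply(fits, function(f) f$rmsd, 0))
    return(fits[[best]])
  }
  .fit_cs_one(scans, s_grid, f_f0, vbar, level, ncells, b)
}

.fit_cs_one <- function(scans, s_grid, f_f0, vbar, level, ncells, b) {
  ns <- length(s_grid)
  expt <- cell_experiment(times_s = scans$times_s, rpm = scans$rpm,
                          temperature_C = scans$temperature_C,
                          pathlength_mm = scans$pathlength_mm)
  # library: unit-loading single-species solutions, signal_coef 1, ds column scale
  ds <- diff(s_grid)
  w <- c(ds[1] / 2, (ds[-1] + ds[-length(ds)]) / 2, ds[length(ds)] / 2) # trapezoid weights
  A <- matrix(0, length(b), ns)
  for (j in seq_len(ns)) {
    sp <- hydro_species(s_grid[j], n = 1, M = 1, vbar = vbar,
                        D_cm2s = d_from_s(s_grid[j], f_f0, vbar,
                                          expt$density, expt$viscosity,
                                          expt$temperature_C),
                        signal_coef = 1 / (expt$pathlength_mm / 10))
    sim <- simulate_boundaries(expt, list(sp), loading = 1,
                               radii_cm = scans$radii_cm, ncells = ncells)
    A[, j] <- as.vector(t(sim$signal)) * w[j]
  }
  # second-difference penalty operator
  L <- matrix(0, ns - 2, ns)
  for (i in seq_len(ns - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)

  solve_pen <- function(lam) {
    Aa <- rbind(A, sqrt(lam) * L)
    ba <- c(b, rep(0, nrow(L)))
    fit <- pracma::lsqnonneg(Aa, ba)
    x <- fit$x
    list(x = x, chisq = sum((A %*% x - b)^2))
  }
  f0 <- solve_pen(0)
  ndf <- length(b) - ns
  target <- f0$chisq * (1 + qf(level, 1, ndf) / ndf)
  # bisection on log10(lambda); chi-square is nondecreasing in lambda
  lo <- -8; hi <- 6
  fhi <- solve_pen(10^hi)
  if (fhi$chisq <= target) {
    best <- fhi; lam <- 10^hi
  } else {
    best <- f0; lam <- 0
    for (i in 1:24) {
      mid <- (lo + hi) / 2
      fm <- solve_pen(10^mid)
      if (fm$chisq <= target) { lo <- mid; best <- fm; lam <- 10^mid }
      else hi <- mid
    }
  }
  # columns carry the quadrature weights, so the amplitudes are already
  # the distribution density (signal per S)
  structure(list(s = s_grid, c = best$x, f_f0 = f_f0, lambda = lam,
                 rmsd = sqrt(best$chisq / length(b)), degenerate = FALSE),
            class = "cs_distribution")
}

#' @export
print.cs_distribution <- function(x, ...) {
  cat("c(s) distribution:", length(x$s), "points on",
      paste(range(x$s), collapse = "-"), "S, f/f0 =", x$f_f0,
      ", rmsd =", signif(x$rmsd, 3), "AU\n")
  invisible(x)
}

#' Integrate a c(s) distribution
#'
#' Loading signal `integral of c(s) ds` and weighted-average sedimentation
#' coefficient `sw = integral of s c(s) ds / integral of c(s) ds` over an
#' s-range (trapezoidal rule on the stored grid).  When a signal
#' coefficient and pathlength are supplied, the loading is also converted
#' to µM.
#'
#' @param dist a `cs_distribution`.
#' @param s_range range of s to integrate, Svedberg (default full grid).
#' @param signal_coef optional per-monomer signal coefficient, AU/(µM cm).
#' @param pathlength_mm optical pathlength, mm.
#' @return list with `loading_AU`, `sw_S`, and `loading_uM` when
#'   convertible.
#' @export
integrate_cs <- function(dist, s_range = range(dist$s), signal_coef = NULL,
                         pathlength_mm = NULL) {
  stopifnot(inherits(dist, "cs_distribution"))
  idx <- which(dist$s >= s_range[1] & dist$s <= s_range[2])
  if (length(idx) < 2) stop("empty or degenerate integration range")
  s <- dist$s[idx]; cc <- dist$c[idx]
  tr <- function(y) sum(diff(s) * (y[-1] + y[-length(y)]) / 2)
  load <- tr(cc)
  if (load <= 0) stop("no signal in the requested s-range")
  sw <- tr(s * cc) / load
  out <- list(loading_AU = load, sw_S = sw)
  if (!is.null(signal_coef) && !is.null(pathlength_mm))
    out$loading_uM <- load / (signal_coef * pathlength_mm / 10)
  out
}

#' Peak ranges of a c(s) distribution
#'
#' Splits the s-grid at local minima of c(s); ties are broken toward lower
#' s.  Used to define integration boundaries for individual peaks.
#'
#' @param dist a `cs_distribution`.
#' @param min_signal peaks whose maximum amplitude is below this fraction
#'   of the global maximum are dropped.
#' @return data.frame with columns `s_lo`, `s_hi`, `s_peak`.
#' @export
cs_peak_ranges <- function(dist, min_signal = 0.02) {
  stopifnot(inherits(dist, "cs_distribution"))
  cc <- dist$c; s <- dist$s; n <- length(cc)
  if (all(cc == 0)) return(data.frame(s_lo = numeric(), s_hi = numeric(),
                                      s_peak = numeric()))
  is_min <- which(vapply(2:(n - 1), function(i)
    cc[i] <= cc[i - 1] && cc[i] < cc[i + 1], TRUE)) + 1
  bounds <- c(1, is_min, n)
  out <- do.call(rbind, lapply(seq_len(length(bounds) - 1), function(j) {
    lo <- bounds[j]; hi <- bounds[j + 1]
    pk <- lo - 1 + which.max(cc[lo:hi])
    data.frame(s_lo = s[lo], s_hi = s[hi], s_peak = s[pk],
               height = cc[pk])
  }))
  out <- out[out$height >= min_signal * max(cc), c("s_lo", "s_hi", "s_peak")]
  rownames(out) <- NULL
  out
}
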