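#' Global direct boundary fitting of self-association models
#'
#' Fits a mass-action association model directly to one or more
#' sedimentation-velocity scan sets by minimizing the summed squared
#' residuals of the reacting Lamm-equation forward model over all scans and
#' sets jointly (Levenberg-Marquardt, multistart).  Dissociation constants
#' are fitted in log space; per-set loading concentrations are free
#' nuisance parameters.  An optional non-participating "aggregate" species
#' (own s-value and per-set amplitude) absorbs trace amounts of large
#' material.
#'
#' @param scan_sets a [scan_set] or list of them (global fit).
#' @param scheme an [association_scheme] template; its constants seed the
#'   parameterization when no heuristic start is requested.
#' @param experiment a [cell_experiment] describing the geometry/solvent;
#'   scan times are taken from each scan set.
#' @param monomer_mass monomer molar mass, Da (masses fixed at
#'   `n * monomer_mass`; D follows from s via the Svedberg relation).
#' @param vbar partial specific volume, mL/g.
#' @param signal_coef per-monomer signal coefficient, AU/(µM cm), known and
#'   fixed (loadings absorb scale).
#' @param n_starts number of seeded multistarts (first start is the
#'   heuristic; later starts draw log-uniform dissociation constants).
#' @param seed integer seed making the multistart reproducible.
#' @param include_aggregate add a trace non-participating aggregate species.
#' @param ncells,cfl,theta forward-solver controls (see
#'   [simulate_boundaries]).
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return object of class `fit_result` with fitted `s_S`, `stepwise_kd_uM`
#'   (or `overall_kd`), `loadings_uM`, optional aggregate parameters,
#'   `rmsd`, per-set residual matrices, convergence metadata, and the data
#'   and settings needed to re-simulate.
#' @export
fit_association_model <- function(scan_sets, scheme, experiment,
                                  monomer_mass = 16000, vbar = 0.73,
                                  signal_coef = 0.01, n_starts = 5, seed = 1,
                                  include_aggregate = FALSE, ncells = 300,
                                  cfl = 1.0, theta = 0.5, maxiter = 60) {
  if (inherits(scan_sets, "scan_set")) scan_sets <- list(scan_sets)
  stopifnot(length(scan_sets) >= 1,
            all(vapply(scan_sets, inherits, TRUE, "scan_set")),
            inherits(scheme, "association_scheme"),
            inherits(experiment, "cell_experiment"))
  J <- length(scheme$n)
  nset <- length(scan_sets)
  stepwise <- !is.null(scheme$stepwise_kd_uM) || J == 1
  nkd <- J - 1
  pl_cm <- vapply(scan_sets, function(x) x$pathlength_mm / 10, 0)

  ## ---- packing -------------------------------------------------------
  pnames <- c(paste0("s_", scheme$labels),
              if (nkd > 0) paste0("log10_kd", seq_len(nkd)),
              paste0("loading_", seq_len(nset)),
              if (include_aggregate) c("s_agg", paste0("agg_uM_", seq_len(nset))))
  kd_pow <- if (stepwise) rep(1, nkd) else pmax(scheme$n[-1] - 1, 1)
  lower <- c(rep(0.05, J), rep(-4, nkd), rep(1e-3, nset),
             if (include_aggregate) c(0.1, rep(0, nset)))
  upper <- c(rep(30, J), 7 * kd_pow, rep(1e5, nset),
             if (include_aggregate) c(60, rep(100, nset)))

  unpack <- function(p) {
    s <- p[seq_len(J)]
    kd <- if (nkd > 0) 10^p[J + seq_len(nkd)] else numeric()
    load <- p[J + nkd + seq_len(nset)]
    agg <- if (include_aggregate) {
      i0 <- J + nkd + nset
      list(s = p[i0 + 1], conc = p[i0 + 1 + seq_len(nset)])
    } else NULL
    list(s = s, kd = kd, load = load, agg = agg)
  }

  sim_set <- function(q, i) {
    ss <- scan_sets[[i]]
    expt <- cell_experiment(times_s = ss$times_s,
                            meniscus_cm = experiment$meniscus_cm,
                            bottom_cm = experiment$bottom_cm,
                            rpm = ss$rpm, temperature_C = ss$temperature_C,
                            density = experiment$density,
                            viscosity = experiment$viscosity,
                            pathlength_mm = ss$pathlength_mm)
    sch <- if (J > 1) {
      if (stepwise) association_scheme(scheme$n, stepwise_kd = q$kd,
                                       labels = scheme$labels)
      else association_scheme(scheme$n, overall_kd = q$kd,
                              labels = scheme$labels)
    } else NULL
    sp <- lapply(seq_len(J), function(j)
      hydro_species(q$s[j], n = scheme$n[j], monomer_mass = monomer_mass,
                    vbar = vbar, signal_coef = signal_coef,
                    label = scheme$labels[j]))
    sig <- simulate_boundaries(expt, sp, scheme = sch,
                               loading = if (J > 1) q$load[i] else q$load[i],
                               radii_cm = ss$radii_cm, ncells = ncells,
                               cfl = cfl, theta = theta)$signal
    if (!is.null(q$agg) && q$agg$conc[i] > 0) {
      spa <- hydro_species(q$agg$s, n = 1, M = 20 * monomer_mass,
                           vbar = vbar, signal_coef = signal_coef,
                           label = "aggregate")
      sig <- sig + simulate_boundaries(expt, list(spa),
                                       loading = q$agg$conc[i],
                                       radii_cm = ss$radii_cm,
                                       ncells = ncells, cfl = cfl,
                                       theta = theta)$signal
    }
    sig
  }

  resid_fun <- function(p) {
    q <- unpack(p)
    unlist(lapply(seq_len(nset), function(i)
      as.vector(sim_set(q, i) - scan_sets[[i]]$signal)), use.names = FALSE)
  }

  ## ---- heuristic starts ---------------------------------------------
  sw0 <- .sw_heuristic(scan_sets[[which.max(vapply(scan_sets, function(x)
    max(x$signal), 0))]], experiment)
  load0 <- vapply(seq_len(nset), function(i) {
    max(mean(scan_sets[[i]]$signal[1, ]), 1e-3) / (signal_coef * pl_cm[i])
  }, 0)
  set.seed(seed)
  starts <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    s0 <- pmax(0.8 * sw0, 0.2) * scheme$n^(2 / 3)
    kd0 <- if (nkd == 0) numeric()
    else if (k == 1) kd_pow * log10(max(load0))
    else kd_pow * runif(nkd, 0, 4.5)
    p0 <- c(s0 * runif(J, 0.9, 1.1), kd0, load0,
            if (include_aggregate) c(max(s0) * 3, rep(0.05, nset)))
    starts[[k]] <- pmin(pmax(p0, lower), upper)
  }

  best <- NULL; meta <- list()
  for (k in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[k]], fn = resid_fun, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) { meta[[k]] <- list(ok = FALSE); next }
    ssr <- fit$deviance
    meta[[k]] <- list(ok = TRUE, ssr = ssr, info = fit$info, niter = fit$niter)
    if (is.null(best) || ssr < best$deviance) { best <- fit; best_start <- k }
  }
  if (is.null(best)) stop("no optimizer start converged")

  p <- setNames(best$par, pnames)
  at_bound <- which(p <= lower + 1e-12 | p >= upper - 1e-12)
  if (length(at_bound))
    warning("parameters at bounds: ", paste(pnames[at_bound], collapse = ", "))
  q <- unpack(p)
  nres <- sum(vapply(scan_sets, function(x) length(x$signal), 0L))
  rmsd <- sqrt(best$deviance / nres)
  residuals <- lapply(seq_len(nset), function(i)
    sim_set(q, i) - scan_sets[[i]]$signal)

  structure(list(
    par = p, s_S = setNames(q$s, scheme$labels),
    stepwise_kd_uM = if (stepwise && nkd > 0) q$kd else NULL,
    overall_kd = if (!stepwise && nkd > 0) q$kd else NULL,
    loadings_uM = q$load, aggregate = q$agg,
    rmsd = rmsd, ssr = best$deviance, n_residuals = nres,
    residuals = residuals, starts = meta, best_start = best_start,
    seed = seed, scheme = scheme, experiment = experiment,
    settings = list(monomer_mass = monomer_mass, vbar = vbar,
                    signal_coef = signal_coef, ncells = ncells, cfl = cfl,
                    theta = theta, include_aggregate = include_aggregate,
                    maxiter = maxiter),
    data = scan_sets,
    .resid_fun = resid_fun, .lower = lower, .upper = upper,
    .pnames = pnames), class = "fit_result")
}

# crude signal-weighted s from boundary midpoint motion; truth-agnostic
.sw_heuristic <- function(ss, experiment) {
  om2 <- (ss$rpm * 2 * pi / 60)^2
  nr <- length(ss$radii_cm)
  plat <- apply(ss$signal[, max(1, nr - round(nr / 10)):nr, drop = FALSE], 1, mean)
  mid <- vapply(seq_len(nrow(ss$signal)), function(i) {
    y <- ss$signal[i, ]
    j <- which(y >= plat[i] / 2)[1]
    if (is.na(j)) NA_real_ else ss$radii_cm[j]
  }, 0)
  ok <- is.finite(mid) & mid > experiment$meniscus_cm
  if (sum(ok) < 3) return(2.0)
  sl <- stats::coef(stats::lm(log(mid[ok]) ~ ss$times_s[ok]))[2] / om2
  if (!is.finite(sl) || sl <= 0) return(2.0)
  sl / 1e-13
}

#' @export
print.fit_result <- function(x, ...) {
  cat("global Lamm-equation fit:",
      paste(x$scheme$labels, collapse = "-"), "model\n")
  cat("  s (S):", paste(signif(x$s_S, 4), collapse = ", "), "\n")
  if (!is.null(x$stepwise_kd_uM))
    cat("  stepwise Kd (uM):",
        paste(signif(x$stepwise_kd_uM, 4), collapse = ", "), "\n")
  if (!is.null(x$overall_kd))
    cat("  overall Kd (uM^(n-1)):",
        paste(signif(x$overall_kd, 4), collapse = ", "), "\n")
  cat("  loadings (uM):", paste(signif(x$loadings_uM, 4), collapse = ", "), "\n")
  cat("  rmsd:", signif(x$rmsd, 4), "AU over", x$n_residuals, "points\n")
  invisible(x)
}

#' Error-surface-projection confidence interval
#'
#' Scans one parameter away from its best-fit value, re-optimizing all
#' other parameters at each step, and reports the interval within which
#' `chisq <= chisq_min * (1 + p/(N-p) * F(p, N-p, level))` (projection of
#' the joint confidence region).  Bounds that never cross the target within
#' the scan range are reported as open (`-Inf`/`Inf`) and flagged.
#'
#' @param fit a `fit_result`.
#' @param parameter name of the packed parameter, e.g. `"log10_kd2"`,
#'   `"s_monomer"`, `"loading_1"` (see `fit$.pnames`); dissociation
#'   constants are profiled on the log10 scale and the interval is
#'   returned in µM.
#' @param level confidence level (default one standard deviation, 0.683).
#' @param max_steps,rel_step scan length and relative step size.
#' @return named vector `c(lower, upper)` on the natural scale, with
#'   attributes `open` (logical pair) and `target_ssr`.
#' @export
profile_interval <- function(fit, parameter, level = 0.683, max_steps = 20,
                             rel_step = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  idx <- match(parameter, fit$.pnames)
  if (is.na(idx)) stop("unknown parameter: ", parameter,
                       " (see fit$.pnames)")
  p_hat <- fit$par
  N <- fit$n_residuals; np <- length(p_hat)
  target <- fit$ssr * (1 + np / (N - np) * qf(level, np, N - np))
  is_log <- grepl("^log10_kd", parameter)
  step <- if (!is.null(rel_step)) rel_step
  else if (is_log) 0.15 else 0.02 * max(abs(p_hat[idx]), 0.1)

  refit <- function(theta, warm) {
    if (np == 1) {
      r <- fit$.resid_fun(theta)
      return(list(ssr = sum(r^2), warm = warm))
    }
    fn <- function(q) {
      full <- warm; full[idx] <- theta; full[-idx] <- q
      fit$.resid_fun(full)
    }
    f <- minpack.lm::nls.lm(par = warm[-idx], fn = fn,
                            lower = fit$.lower[-idx],
                            upper = fit$.upper[-idx],
                            control = minpack.lm::nls.lm.control(
                              maxiter = fit$settings$maxiter))
    w <- warm; w[idx] <- theta; w[-idx] <- f$par
    list(ssr = f$deviance, warm = w)
  }

  out <- .profile_scan(refit, p_hat, idx, fit$ssr, target, step,
                       fit$.lower[idx], fit$.upper[idx], max_steps)
  lw <- out$lower; up <- out$upper
  if (is_log) {
    lw <- if (is.finite(lw)) 10^lw else 0
    up <- if (is.finite(up)) 10^up else Inf
  }
  structure(setNames(c(lw, up), c("lower", "upper")),
            open = out$open, target_ssr = target)
}

# generic one-parameter scan used by profile_interval; `refit` maps
# (theta, warm start) -> list(ssr, warm)
.profile_scan <- function(refit, p_hat, idx, ssr_min, target, step,
                          lo_bound, hi_bound, max_steps) {
  scan_dir <- function(dir) {
    warm <- p_hat
    th_prev <- p_hat[idx]; ssr_prev <- ssr_min
    for (k in seq_len(max_steps)) {
      th <- p_hat[idx] + dir * k * step
      if (th < lo_bound || th > hi_bound) return(list(val = dir * Inf, open = TRUE))
      r <- refit(th, warm)
      warm <- r$warm
      if (r$ssr >= target) {
        # linear interpolation of the crossing
        fr <- (target - ssr_prev) / (r$ssr - ssr_prev)
        return(list(val = unname(th_prev + fr * (th - th_prev)),
                    open = FALSE))
      }
      th_prev <- th; ssr_prev <- r$ssr
    }
    list(val = dir * Inf, open = TRUE)
  }
  dn <- scan_dir(-1); up <- scan_dir(+1)
  list(lower = if (dn$open) -Inf else dn$val,
       upper = if (up$open) Inf else up$val,
       open = c(lower = dn$open, upper = up$open))
}

#' Rank association schemes by fit quality
#'
#' Fits each candidate scheme to the same scan sets and ranks them by rms
#' deviation, flagging physically unreasonable results: fitted s-ratios
#' deviating from the smooth-sphere expectation `n^(2/3)` by more than
#' `s_ratio_factor`, or s-values that do not increase with stoichiometry.
#'
#' @param scan_sets data as in [fit_association_model].
#' @param schemes list of [association_scheme] candidates.
#' @param experiment a [cell_experiment].
#' @param s_ratio_factor plausibility factor for s-ratio deviations.
#' @param ... passed to [fit_association_model].
#' @return data.frame ranking (label, rmsd, plausible, reason), with the
#'   fits in attribute `"fits"`; schemes whose fit errored keep an NA row.
#' @export
compare_schemes <- function(scan_sets, schemes, experiment,
                            s_ratio_factor = 1.5, ...) {
  stopifnot(length(schemes) >= 2)
  fits <- lapply(schemes, function(sch)
    tryCatch(fit_association_model(scan_sets, sch, experiment, ...),
             error = function(e) e))
  rows <- lapply(seq_along(schemes), function(i) {
    sch <- schemes[[i]]; f <- fits[[i]]
    lab <- paste(sch$labels, collapse = "-")
    if (inherits(f, "error"))
      return(data.frame(scheme = lab, rmsd = NA_real_, plausible = NA,
                        reason = conditionMessage(f)))
    reason <- ""
    plausible <- TRUE
    if (length(f$s_S) > 1) {
      if (any(diff(f$s_S) <= 0)) {
        plausible <- FALSE; reason <- "s does not increase with n"
      } else {
        ratio <- (f$s_S / f$s_S[1]) / sch$n^(2 / 3)
        if (any(pmax(ratio, 1 / ratio) > s_ratio_factor)) {
          plausible <- FALSE
          reason <- sprintf("s-ratio off n^(2/3) by > %.2gx", s_ratio_factor)
        }
      }
    }
    data.frame(scheme = lab, rmsd = f$rmsd, plausible = plausible,
               reason = reason)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rmsd), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
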