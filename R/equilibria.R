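#' Define a mass-action self-association scheme
#'
#' A scheme is a set of species with stoichiometries `n` (monomer units per
#' species) and the equilibrium constants connecting them.  Stepwise
#' dissociation constants follow the species-molar convention
#' `Kd = [reactant]^2 / [product]` for a reactant that dimerizes into the
#' next species (monomer -> dimer: `Kd1 = [M]^2/[D]`; dimer -> tetramer:
#' `Kd2 = [D]^2/[T]`).  This is the only convention under which a
#' monomer-dimer-tetramer model with Kd 2.4 mM / 2.7 µM reproduces the
#' speciation it is quoted with, and it is used throughout the package.
#' Schemes whose stoichiometries do not double at each step (for example
#' monomer-trimer) are specified through overall dissociation constants
#' `K_j` such that `[species j] = [M]^{n_j} / K_j` (units µM^(n_j - 1)).
#'
#' @param n integer vector of monomer units per species; must start at 1
#'   and be strictly increasing.
#' @param stepwise_kd dissociation constants for consecutive dimerization
#'   steps (length `length(n) - 1`); requires `n[j+1] == 2 n[j]`.
#' @param overall_kd alternative to `stepwise_kd`: overall dissociation
#'   constants for species 2..J, units µM^(n_j - 1).
#' @param labels optional species labels; sensible defaults are derived
#'   from `n` ("monomer", "dimer", ...).
#' @param kd_unit unit of the supplied constants, `"uM"` (default) or
#'   `"mM"`; `"mM"` inputs are converted as `uM = mM * 1000` for stepwise
#'   constants (overall constants must be given in µM powers).
#' @return an object of class `association_scheme` with elements `n`,
#'   `labels`, `K_uM` (overall constants, monomer = 1) and, when supplied,
#'   `stepwise_kd_uM`.
#' @examples
#' association_scheme(c(1, 2, 4), stepwise_kd = c(2.4, 2.7e-3), kd_unit = "mM")
#' @export
association_scheme <- function(n, stepwise_kd = NULL, overall_kd = NULL,
                               labels = NULL, kd_unit = c("uM", "mM")) {
  kd_unit <- match.arg(kd_unit)
  if (length(n) < 1 || any(n != round(n)) || any(n < 1))
    stop("species stoichiometries must be integers >= 1")
  n <- as.integer(n)
  if (n[1] != 1) stop("the monomer (n = 1) must be the first species")
  if (length(n) > 1 && any(diff(n) <= 0))
    stop("stoichiometries must be strictly increasing")
  if (is.null(labels)) labels <- .nmer_label(n)
  J <- length(n)
  if (!is.null(stepwise_kd) && !is.null(overall_kd))
    stop("supply stepwise_kd or overall_kd, not both")
  K <- rep(1, J)
  sk <- NULL
  if (J > 1) {
    if (!is.null(stepwise_kd)) {
      if (length(stepwise_kd) != J - 1)
        stop("need one stepwise Kd per association step")
      if (any(!is.finite(stepwise_kd)) || any(stepwise_kd <= 0))
        stop("all Kds must be finite and > 0")
      if (any(n[-1] != 2 * n[-J]))
        stop("stepwise Kds require doubling stoichiometries; use overall_kd")
      sk <- if (kd_unit == "mM") stepwise_kd * 1000 else stepwise_kd
      for (j in 2:J) K[j] <- K[j - 1]^2 * sk[j - 1]
    } else if (!is.null(overall_kd)) {
      if (length(overall_kd) != J - 1)
        stop("need one overall Kd per non-monomer species")
      if (any(!is.finite(overall_kd)) || any(overall_kd <= 0))
        stop("all Kds must be finite and > 0")
      if (kd_unit == "mM")
        stop("overall constants must be supplied in µM powers")
      K[-1] <- overall_kd
    } else stop("a multi-species scheme needs dissociation constants")
  }
  structure(list(labels = labels, n = n, K_uM = K, stepwise_kd_uM = sk),
            class = "association_scheme")
}

.nmer_label <- function(n) {
  nm <- c("monomer", "dimer", "trimer", "tetramer", "pentamer", "hexamer",
          "heptamer", "octamer")
  ifelse(n <= length(nm), nm[pmin(n, length(nm))], paste0(n, "-mer"))
}

#' @export
print.association_scheme <- function(x, ...) {
  cat("association scheme:", paste(x$labels, collapse = " / "), "\n")
  if (!is.null(x$stepwise_kd_uM))
    cat("stepwise Kd (uM):", paste(signif(x$stepwise_kd_uM, 4), collapse = ", "), "\n")
  cat("overall K (uM^(n-1)):", paste(signif(x$K_uM, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Solve mass-action speciation
#'
#' Finds the unique non-negative free-monomer concentration satisfying the
#' mass balance `total = sum_j n_j [M]^{n_j} / K_j` by bracketed bisection
#' (via [stats::uniroot]) followed by Newton polishing, then reports all
#' species concentrations.
#'
#' @param total_uM total concentration in µM monomer equivalents.
#' @param scheme an [association_scheme].
#' @return an object of class `speciation`: `free_monomer_uM`, per-species
#'   `molar_uM`, per-species `monomer_equiv_uM` (`n * molar`), `total_uM`.
#' @examples
#' sch <- association_scheme(c(1, 2, 4), stepwise_kd = c(2400, 2.7))
#' sp <- solve_speciation(107, sch)
#' sp$monomer_equiv_uM
#' @export
solve_speciation <- function(total_uM, scheme) {
  stopifnot(inherits(scheme, "association_scheme"))
  if (!is.numeric(total_uM) || length(total_uM) != 1 || !is.finite(total_uM))
    stop("total must be a finite number")
  if (total_uM < 0) stop("total concentration must be >= 0")
  n <- as.numeric(scheme$n); K <- scheme$K_uM
  if (total_uM == 0) {
    molar <- setNames(rep(0, length(n)), scheme$labels)
    return(structure(list(free_monomer_uM = 0, molar_uM = molar,
                          monomer_equiv_uM = molar, total_uM = 0,
                          scheme = scheme), class = "speciation"))
  }
  f <- function(m) sum(n * m^n / K) - total_uM
  m <- uniroot(f, c(0, total_uM), tol = 1e-12 * max(total_uM, 1))$root
  for (i in 1:3) { # Newton polish
    fp <- sum(n^2 * m^(n - 1) / K)
    m <- m - f(m) / fp
  }
  molar <- setNames(m^n / K, scheme$labels)
  me <- n * molar
  if (abs(sum(me) - total_uM) > 1e-9 * total_uM)
    stop("speciation failed to satisfy mass balance")
  structure(list(free_monomer_uM = m, molar_uM = molar,
                 monomer_equiv_uM = setNames(me, scheme$labels),
                 total_uM = total_uM, scheme = scheme),
            class = "speciation")
}

#' @export
print.speciation <- function(x, ...) {
  cat("speciation at", x$total_uM, "uM monomer equivalents\n")
  print(data.frame(species = names(x$molar_uM),
                   molar_uM = signif(unname(x$molar_uM), 4),
                   monomer_equiv_uM = signif(unname(x$monomer_equiv_uM), 4)),
        row.names = FALSE)
  invisible(x)
}

#' Smooth-sphere s-ratio expected for an n-mer
#'
#' At equal partial specific volume and frictional ratio, the sedimentation
#' coefficient of an n-mer relative to the monomer scales as `n^(2/3)`
#' (mass grows as n, the frictional radius as n^(1/3)).  A dimer is thus
#' expected at about 1.59x the monomer s-value.
#'
#' @param n stoichiometry (integer >= 1, vectorized).
#' @return dimensionless s-ratio `n^(2/3)`.
#' @examples
#' expected_s_nmer(2)
#' @export
expected_s_nmer <- function(n) {
  if (any(!is.finite(n)) || any(n < 1) || any(n != round(n)))
    stop("n must be an integer >= 1")
  n^(2 / 3)
}

#' Signal-weighted average sedimentation coefficient
#'
#' Weighted average `sw = sum(s_j n_j c_j) / sum(n_j c_j)` over the species
#' of a speciation, assuming an equal per-monomer signal coefficient for
#' every species (same chromophore count per monomer unit).
#'
#' @param speciation a [solve_speciation] result.
#' @param s_values per-species sedimentation coefficients, Svedberg.
#' @return weighted-average s in Svedberg.
#' @export
signal_weighted_s <- function(speciation, s_values) {
  stopifnot(inherits(speciation, "speciation"))
  if (length(s_values) != length(speciation$molar_uM))
    stop("need one s-value per species")
  w <- speciation$monomer_equiv_uM
  if (sum(w) <= 0) stop("total signal is zero; sw undefined")
  sum(s_values * w) / sum(w)
}
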