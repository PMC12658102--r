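# Synthetic-data generators.  Every generator is deterministic given its
# seed and records the generating ground truth on the returned object, so
# round-trip tests can compare against it.

#' Generate noisy sedimentation-velocity scan sets
#'
#' Forward-simulates boundaries with [simulate_boundaries] and adds i.i.d.
#' Gaussian signal noise (default 0.005 AU, typical absorbance-optics
#' noise), plus an optional time-invariant baseline.  The generating
#' parameters are recorded in the `truth` field.
#'
#' @inheritParams simulate_boundaries
#' @param noise_sd Gaussian signal noise SD, AU (>= 0).
#' @param baseline optional time-invariant baseline added to every scan
#'   (scalar or one value per radius).
#' @param seed integer seed.
#' @param ... further arguments to [simulate_boundaries] (`ncells`, ...).
#' @return a [scan_set] with noise; `truth` records scheme, species,
#'   loading, noise and seed.
#' @export
gen_auc_scans <- function(experiment, species, scheme = NULL, loading,
                          noise_sd = 0.005, baseline = 0, seed = 1,
                          radii_cm = NULL, ...) {
  if (noise_sd < 0) stop("noise SD must be >= 0")
  ss <- simulate_boundaries(experiment, species, scheme = scheme,
                            loading = loading, radii_cm = radii_cm, ...)
  set.seed(seed)
  noise <- matrix(rnorm(length(ss$signal), 0, noise_sd), nrow(ss$signal))
  ss$signal <- ss$signal + noise + rep(baseline, length.out = ncol(ss$signal))[col(ss$signal)]
  ss$truth <- list(scheme = scheme, species = species, loading = loading,
                   noise_sd = noise_sd, baseline = baseline, seed = seed)
  ss
}

# --- ideal helix construction (NeRF internal-coordinate chain builder) ---

# place D given A-B-C, bond |CD|, angle B-C-D (deg), torsion A-B-C-D (deg)
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m2 + d2[3] * n
}

#' Build an ideal polypeptide backbone
#'
#' Constructs N, CA, C, O (and CB for non-glycine) coordinates from
#' standard backbone internal coordinates and the supplied phi/psi angles
#' (defaults: ideal alpha-helix, phi = -57, psi = -47, which yields the
#' textbook 1.5 A rise and 100 degree twist per residue).  Coordinates in
#' nm, principal axis aligned to z and centered at the origin.
#'
#' @param n_res number of residues.
#' @param phi,psi backbone dihedrals, degrees.
#' @param resno_start first residue number.
#' @param resname residue name used for all residues (default "ALA").
#' @param chain chain id.
#' @return a single-frame [traj_ensemble].
#' @export
build_ideal_helix <- function(n_res, phi = -57, psi = -47,
                              resno_start = 310, resname = "ALA",
                              chain = "A") {
  stopifnot(n_res >= 2)
  # lengths in Angstrom here; converted to nm at the end
  bN_CA <- 1.458; bCA_C <- 1.525; bC_N <- 1.329; bC_O <- 1.231; bCA_CB <- 1.53
  aN_CA_C <- 111.2; aCA_C_N <- 116.2; aC_N_CA <- 121.7
  aCA_C_O <- 120.8; aN_CA_CB <- 110.5
  N <- matrix(0, n_res, 3); CA <- N; C <- N; O <- N; CB <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bN_CA, 0, 0)
  a0 <- aN_CA_C * pi / 180
  C[1, ] <- CA[1, ] + bCA_C * c(-cos(a0), sin(a0), 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], bC_N,
                            aCA_C_N, psi)
      CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], bN_CA,
                             aC_N_CA, 180)           # omega trans
      C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ], bCA_C,
                            aN_CA_C, phi)
    }
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], bC_O, aCA_C_O, psi - 180)
    CB[i, ] <- .place_atom(C[i, ], N[i, ], CA[i, ], bCA_CB, aN_CA_CB, 122.6)
  }
  has_cb <- resname != "GLY"
  per_res <- if (has_cb) c("N", "CA", "C", "O", "CB") else c("N", "CA", "C", "O")
  coords <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    m <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (has_cb) m <- rbind(m, CB[i, ])
    m
  }))
  atoms <- data.frame(
    chain = chain,
    resno = rep(resno_start + seq_len(n_res) - 1, each = length(per_res)),
    resname = resname,
    name = rep(per_res, n_res),
    element = rep(substr(per_res, 1, 1), n_res),
    stringsAsFactors = FALSE)
  # align principal axis of the CA trace to z, center at origin
  coords <- sweep(coords, 2, colMeans(coords))
  ca <- coords[atoms$name == "CA", ]
  ax <- svd(sweep(ca, 2, colMeans(ca)))$v[, 1]
  if (ax[3] < 0) ax <- -ax
  rot <- .rotation_onto(ax, c(0, 0, 1))
  coords <- coords %*% t(rot)
  traj_ensemble(atoms, array(coords, c(1, nrow(coords), 3)),
                unit = "angstrom")
}

# rotation matrix taking unit vector a onto unit vector b
.rotation_onto <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (abs(cth + 1) < 1e-12) return(diag(c(1, -1, -1))) # antiparallel
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

#' Generate a synthetic helical-bundle trajectory
#'
#' Builds ideal alpha-helices, arranges the chains on a regular polygon
#' with a stated axis spacing (antiparallel arrangements alternate chain
#' direction around the polygon, emulating a four-fold bundle where
#' adjacent helices run antiparallel), and emits frames with Gaussian
#' coordinate jitter and an optional scripted dissociation of one chain.
#' The dissociation script is recorded as ground truth.
#'
#' @param n_chains number of chains (>= 1).
#' @param arrangement `"antiparallel"` (alternating) or `"parallel"`.
#' @param inter_axis_nm spacing between adjacent helix axes, nm.
#' @param n_res residues per chain.
#' @param resno_start first residue number (default 310).
#' @param n_frames frames to emit.
#' @param jitter_sd_nm Gaussian coordinate jitter SD, nm.
#' @param dissociation optional list `(chain, start, end, distance_nm)`:
#'   during frames `start..end` that chain is displaced radially outward by
#'   `distance_nm`.
#' @param seed integer seed.
#' @param resname residue name (default "ALA").
#' @return a [traj_ensemble]; attribute `"truth"` records the script.
#' @export
gen_helical_bundle <- function(n_chains = 4,
                               arrangement = c("antiparallel", "parallel"),
                               inter_axis_nm = 1.0, n_res = 41,
                               resno_start = 310, n_frames = 10,
                               jitter_sd_nm = 0.02, dissociation = NULL,
                               seed = 1, resname = "ALA") {
  arrangement <- match.arg(arrangement)
  stopifnot(n_chains >= 1, inter_axis_nm > 0, n_frames >= 1,
            jitter_sd_nm >= 0)
  base <- build_ideal_helix(n_res, resno_start = resno_start,
                            resname = resname, chain = "A")
  chains <- LETTERS[seq_len(n_chains)]
  atoms_list <- list(); coords_list <- list()
  R <- if (n_chains > 1) inter_axis_nm / (2 * sin(pi / n_chains)) else 0
  for (k in seq_len(n_chains)) {
    th <- 2 * pi * (k - 1) / n_chains
    xyz <- base$xyz[1, , ]
    if (arrangement == "antiparallel" && k %% 2 == 0)
      xyz <- xyz %*% diag(c(1, -1, -1))   # flip about x: reverses helix axis
    xyz <- xyz + matrix(c(R * cos(th), R * sin(th), 0), nrow(xyz), 3,
                        byrow = TRUE)
    a <- base$atoms; a$chain <- chains[k]
    atoms_list[[k]] <- a
    coords_list[[k]] <- xyz
  }
  atoms <- do.call(rbind, atoms_list)
  ref <- do.call(rbind, coords_list)
  # clash check on the static arrangement
  if (n_chains > 1) {
    for (k1 in 1:(n_chains - 1)) for (k2 in (k1 + 1):n_chains) {
      x1 <- coords_list[[k1]]; x2 <- coords_list[[k2]]
      d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
      if (min(d2) < 0.15^2)
        stop("chains overlap at generation (min distance < 0.15 nm)")
    }
  }
  set.seed(seed)
  nat <- nrow(ref)
  xyz <- array(0, c(n_frames, nat, 3))
  for (f in seq_len(n_frames)) {
    frame <- ref + matrix(rnorm(nat * 3, 0, jitter_sd_nm), nat, 3)
    if (!is.null(dissociation) && f >= dissociation$start &&
        f <= dissociation$end) {
      idx <- which(atoms$chain == dissociation$chain)
      ctr <- colMeans(ref[idx, , drop = FALSE])
      u <- c(ctr[1], ctr[2], 0)
      nu <- sqrt(sum(u^2)); u <- if (nu > 0) u / nu else c(1, 0, 0)
      frame[idx, ] <- frame[idx, ] +
        matrix(dissociation$distance_nm * u, length(idx), 3, byrow = TRUE)
    }
    xyz[f, , ] <- frame
  }
  out <- traj_ensemble(atoms, xyz)
  attr(out, "truth") <- list(arrangement = arrangement,
                             inter_axis_nm = inter_axis_nm,
                             jitter_sd_nm = jitter_sd_nm,
                             dissociation = dissociation, seed = seed)
  out
}

#' Generate a synthetic mutant table with known correlation structure
#'
#' Draws per-variant (x, y) pairs from a bivariate normal with correlation
#' `true_rho` and maps them linearly onto WT-normalized measurement scales
#' (WT anchored at 1.0).  Because the mapping is affine, the population
#' Pearson correlation of the emitted columns equals `true_rho`.
#'
#' @param n_variants number of variants (default 18, the number of
#'   conserved-region positions typically assayed).
#' @param true_rho target correlation in `[-1, 1]`.
#' @param sd_x,sd_y spread of the normalized measures around 1.0.
#' @param seed integer seed.
#' @param x_name,y_name output column names.
#' @return a [mutant_table] with the two measure columns; attribute
#'   `"truth"` records `true_rho` and the seed.
#' @export
gen_mutant_table <- function(n_variants = 18, true_rho, sd_x = 0.2,
                             sd_y = 0.2, seed = 1, x_name = "csat_norm",
                             y_name = "csp_norm") {
  if (!is.finite(true_rho) || abs(true_rho) > 1)
    stop("true_rho must lie in [-1, 1]")
  stopifnot(n_variants >= 3, sd_x >= 0, sd_y >= 0)
  set.seed(seed)
  z1 <- rnorm(n_variants); z2 <- rnorm(n_variants)
  x <- z1
  y <- true_rho * z1 + sqrt(1 - true_rho^2) * z2
  d <- data.frame(variant = sprintf("V%02d", seq_len(n_variants)))
  d[[x_name]] <- 1 + sd_x * x
  d[[y_name]] <- 1 + sd_y * y
  out <- mutant_table(d)
  attr(out, "truth") <- list(true_rho = true_rho, seed = seed,
                             sd_x = sd_x, sd_y = sd_y)
  out
}
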