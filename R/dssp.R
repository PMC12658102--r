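# Kabsch-Sander hydrogen-bond energies and alpha-helix assignment.
#
# A backbone hydrogen bond between donor amide (N-H of residue d) and
# acceptor carbonyl (C=O of residue a) is assigned when the electrostatic
# energy
#
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol
#
# (distances in Angstrom) falls below -0.5 kcal/mol.  A minimal alpha-helix
# (state H) spans residues i..i+3 when i->i+4 turns exist at both i-1 and
# i.  Amide hydrogens absent from the input are placed geometrically
# 1.01 A from N along the bisector pointing away from CA and the previous
# carbonyl carbon.

.ks_hbond_energy <- function(N, H, C, O) {
  # coordinates in nm -> Angstrom
  r <- function(a, b) sqrt(sum((a - b)^2)) * 10
  0.084 * 332 * (1 / r(O, N) + 1 / r(C, H) - 1 / r(O, H) - 1 / r(C, N))
}

# backbone table for one chain in one frame; returns per-residue coordinate
# list or NULL entries where backbone atoms are missing
.chain_backbone <- function(traj, frame, chain) {
  a <- traj$atoms
  idx <- which(a$chain == chain)
  resnos <- sort(unique(a$resno[idx]))
  get <- function(rn, nm) {
    i <- idx[a$resno[idx] == rn & a$name[idx] == nm]
    if (length(i) != 1) return(NULL)
    traj$xyz[frame, i, ]
  }
  bb <- lapply(resnos, function(rn)
    list(N = get(rn, "N"), CA = get(rn, "CA"), C = get(rn, "C"),
         O = get(rn, "O"), H = get(rn, "H")))
  names(bb) <- resnos
  list(resnos = resnos, bb = bb)
}

.place_amide_h <- function(bb, i) {
  # bisector convention, N-H 1.01 A = 0.101 nm
  if (i == 1) return(NULL)
  prev <- bb[[i - 1]]; cur <- bb[[i]]
  if (is.null(cur$N) || is.null(cur$CA) || is.null(prev$C)) return(NULL)
  u1 <- cur$CA - cur$N; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- prev$C - cur$N; u2 <- u2 / sqrt(sum(u2^2))
  u <- -(u1 + u2); u <- u / sqrt(sum(u^2))
  cur$N + 0.101 * u
}

# alpha-helix (H) flags for one chain, one frame; NA = unassignable
.helix_flags <- function(traj, frame, chain, proline_donors = FALSE) {
  cb <- .chain_backbone(traj, frame, chain)
  bb <- cb$bb; L <- length(bb)
  assignable <- vapply(seq_len(L), function(i)
    !is.null(bb[[i]]$N) && !is.null(bb[[i]]$CA) && !is.null(bb[[i]]$C) &&
      !is.null(bb[[i]]$O), TRUE)
  H <- lapply(seq_len(L), function(i) {
    if (!is.null(bb[[i]]$H)) bb[[i]]$H else .place_amide_h(bb, i)
  })
  turn4 <- rep(FALSE, L)
  for (i in seq_len(max(0, L - 4))) {
    d <- i + 4
    if (!assignable[i] || !assignable[d] || is.null(H[[d]])) next
    e <- .ks_hbond_energy(bb[[d]]$N, H[[d]], bb[[i]]$C, bb[[i]]$O)
    turn4[i] <- is.finite(e) && e < -0.5
  }
  hel <- rep(FALSE, L)
  for (i in 2:max(2, L - 4))
    if (i <= L - 4 && turn4[i - 1] && turn4[i]) hel[i:(i + 3)] <- TRUE
  hel[!assignable] <- NA
  setNames(hel, cb$resnos)
}

#' Per-residue alpha-helix fraction
#'
#' Kabsch-Sander hydrogen-bond assignment (see the package vignette for the
#' energy criterion) restricted to the alpha-helix state H: a residue is
#' helical in a frame when it belongs to a stretch of two consecutive
#' i->i+4 turns.  The fraction is the share of frames in which the residue
#' is helical.  Residues with missing backbone atoms are reported `NA`
#' (unassignable), never silently 0.
#'
#' @param traj a [traj_ensemble]; amide hydrogens are used when present
#'   and placed geometrically otherwise.
#' @param resno residues to report (default all).
#' @param chains chains to include (default all); fractions are averaged
#'   over chains sharing a residue number.
#' @return data.frame `resno`, `helix_fraction`.
#' @export
helix_fraction <- function(traj, resno = NULL, chains = NULL) {
  if (is.null(chains)) chains <- unique(traj$atoms$chain)
  nf <- dim(traj$xyz)[1]
  per_chain <- lapply(chains, function(ch) {
    flags <- vapply(seq_len(nf), function(f) .helix_flags(traj, f, ch),
                    logical(length(unique(traj$atoms$resno[traj$atoms$chain == ch]))))
    if (is.null(dim(flags))) flags <- matrix(flags, ncol = nf)
    rn <- sort(unique(traj$atoms$resno[traj$atoms$chain == ch]))
    data.frame(resno = rn, frac = rowMeans(flags))
  })
  all_rn <- sort(unique(unlist(lapply(per_chain, function(d) d$resno))))
  frac <- vapply(all_rn, function(rn) {
    v <- unlist(lapply(per_chain, function(d) d$frac[d$resno == rn]))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  out <- data.frame(resno = all_rn, helix_fraction = frac)
  if (!is.null(resno)) out <- out[out$resno %in% resno, ]
  rownames(out) <- NULL
  out
}
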