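#' Construct a trajectory ensemble
#'
#' Frames x atoms coordinates with chain/residue/atom metadata, coordinates
#' in nm (use `unit = "angstrom"` to convert on input).  Residue numbers
#' are kept verbatim (UniProt-based numbering throughout).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `name` (atom name), `element`; a logical `heavy` column is derived
#'   from `element` when absent.
#' @param xyz numeric array `n_frames x n_atoms x 3`, or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param replica integer replica id per frame (default all 1).
#' @param time_ns optional per-frame timestamps, ns.
#' @param unit `"nm"` (default) or `"angstrom"`.
#' @return object of class `traj_ensemble`.
#' @export
traj_ensemble <- function(atoms, xyz, replica = NULL, time_ns = NULL,
                          unit = c("nm", "angstrom")) {
  unit <- match.arg(unit)
  need <- c("chain", "resno", "resname", "name", "element")
  if (!all(need %in% names(atoms)))
    stop("atoms needs columns: ", paste(need, collapse = ", "))
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(1, nrow(xyz), ncol(xyz)))
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[3] == 3,
            dim(xyz)[2] == nrow(atoms))
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  if (unit == "angstrom") xyz <- xyz / 10
  if (is.null(atoms$heavy)) atoms$heavy <- toupper(atoms$element) != "H"
  if (is.null(replica)) replica <- rep(1L, dim(xyz)[1])
  stopifnot(length(replica) == dim(xyz)[1])
  structure(list(atoms = atoms, xyz = xyz, replica = as.integer(replica),
                 time_ns = time_ns), class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat("trajectory ensemble:", dim(x$xyz)[1], "frames,", dim(x$xyz)[2],
      "atoms,", length(unique(x$atoms$chain)), "chain(s),",
      length(unique(x$replica)), "replica(s)\n")
  invisible(x)
}

#' Select atom indices
#'
#' @param traj a [traj_ensemble].
#' @param resno residue numbers to keep (default all).
#' @param chains chain ids to keep (default all).
#' @param heavy keep heavy atoms only.
#' @param names atom names to keep (e.g. backbone `c("N","CA","C","O")`).
#' @return integer atom indices.
#' @export
select_atoms <- function(traj, resno = NULL, chains = NULL, heavy = TRUE,
                         names = NULL) {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  if (heavy) keep <- keep & a$heavy
  if (!is.null(names)) keep <- keep & a$name %in% names
  which(keep)
}

#' Distance-RMS deviation series
#'
#' Superposition-free structural deviation: for the selected atoms,
#' `dRMS(t) = sqrt( 2/(N(N-1)) * sum_{i<j} (d_ij(t) - d_ij(ref))^2 )`
#' over all intra- and inter-chain atom pairs.  Frames with dRMS above
#' `unstable_above` are flagged unstable (the structural-instability
#' criterion for multimer models).
#'
#' @param traj a [traj_ensemble].
#' @param ref_frame reference frame index (default 1) or an
#'   `n_atoms_sel x 3` reference coordinate matrix in nm.
#' @param resno,chains,heavy selection (default: heavy atoms of residues
#'   320-341, all chains).
#' @param unstable_above instability threshold, nm.
#' @return data.frame with `frame`, `drms_nm`, `unstable`.
#' @export
drms_series <- function(traj, ref_frame = 1, resno = 320:341, chains = NULL,
                        heavy = TRUE, unstable_above = 1.0) {
  sel <- select_atoms(traj, resno = resno, chains = chains, heavy = heavy)
  if (length(sel) < 2) stop("selection is empty or has fewer than 2 atoms")
  n <- length(sel)
  dref <- if (is.matrix(ref_frame)) {
    if (nrow(ref_frame) != n) stop("reference atom set does not match selection")
    stats::dist(ref_frame)
  } else stats::dist(traj$xyz[ref_frame, sel, ])
  npair <- n * (n - 1) / 2
  drms <- vapply(seq_len(dim(traj$xyz)[1]), function(f) {
    d <- stats::dist(traj$xyz[f, sel, ])
    sqrt(sum((d - dref)^2) / npair)
  }, 0)
  data.frame(frame = seq_along(drms), drms_nm = drms,
             unstable = drms > unstable_above)
}

# per-frame residue-residue contact indicator for one traj; returns list of
# eligible pair handling shared by contact_map
.residue_index <- function(traj, sel) {
  a <- traj$atoms[sel, ]
  key <- paste(a$chain, a$resno)
  ukey <- unique(key)
  list(map = match(key, ukey),
       chain = a$chain[match(ukey, key)],
       resno = a$resno[match(ukey, key)],
       ukey = ukey)
}

#' Residue-residue contact map
#'
#' Two residues are in contact in a frame when any two of their heavy atoms
#' lie within `cutoff` (default 0.6 nm).  Within a chain, only pairs with
#' sequence separation greater than `min_sep` are eligible; all inter-chain
#' pairs are eligible.  The map reports, per residue-position pair, the
#' fraction of retained frames in contact (set `count = TRUE` for mean
#' contact counts over eligible chain pairs instead).
#'
#' @param traj a [traj_ensemble].
#' @param cutoff heavy-atom distance cutoff, nm.
#' @param min_sep intra-chain sequence-separation rule `|i-j| > min_sep`.
#' @param mode count inter-chain contacts, intra-chain, or both.
#' @param drop_frames number of leading frames discarded per replica as
#'   equilibration.
#' @param by_replica return one map per replica (list) instead of the
#'   replica average.
#' @param count report mean contact counts rather than any-contact
#'   probability.
#' @return matrix of contact probabilities indexed by residue number
#'   (class `contact_map`, attributes `resno`, `cutoff_nm`, `min_sep`), or
#'   a list of such maps when `by_replica = TRUE`.
#' @export
contact_map <- function(traj, cutoff = 0.6, min_sep = 3,
                        mode = c("inter", "intra", "both"), drop_frames = 0,
                        by_replica = FALSE, count = FALSE) {
  mode <- match.arg(mode)
  stopifnot(cutoff > 0)
  sel <- select_atoms(traj, heavy = TRUE)
  ri <- .residue_index(traj, sel)
  nres_u <- length(ri$ukey)
  resnos <- sort(unique(ri$resno))
  npos <- length(resnos)
  pos_of <- match(ri$resno, resnos)

  # eligibility between residue instances
  elig <- matrix(TRUE, nres_u, nres_u)
  same_chain <- outer(ri$chain, ri$chain, "==")
  sep_ok <- abs(outer(ri$resno, ri$resno, "-")) > min_sep
  elig[same_chain & !sep_ok] <- FALSE
  diag(elig) <- FALSE
  if (mode == "inter") elig[same_chain] <- FALSE
  if (mode == "intra") elig[!same_chain] <- FALSE

  # residue-instance indicator (atoms x instances)
  R <- matrix(0, length(sel), nres_u)
  R[cbind(seq_along(sel), ri$map)] <- 1

  reps <- sort(unique(traj$replica))
  maps <- lapply(reps, function(rep) {
    frames <- which(traj$replica == rep)
    if (drop_frames > 0) frames <- frames[-seq_len(min(drop_frames, length(frames)))]
    if (length(frames) == 0)
      stop("no frames left after the equilibration drop (replica ", rep, ")")
    acc <- matrix(0, npos, npos)
    for (f in frames) {
      x <- traj$xyz[f, sel, , drop = TRUE]
      adj <- as.matrix(stats::dist(x)) < cutoff
      inst <- (t(R) %*% adj %*% R) > 0      # any heavy-atom pair within cutoff
      inst <- inst & elig
      # fold residue instances onto residue positions
      posm <- matrix(0, npos, npos)
      idx <- which(inst, arr.ind = TRUE)
      if (nrow(idx)) {
        pij <- cbind(pos_of[idx[, 1]], pos_of[idx[, 2]])
        if (count) {
          for (r in seq_len(nrow(pij))) posm[pij[r, 1], pij[r, 2]] <-
              posm[pij[r, 1], pij[r, 2]] + 1
        } else posm[pij] <- 1
      }
      acc <- acc + posm
    }
    m <- acc / length(frames)
    m <- (m + t(m)) / 2
    if (!count) m <- pmin(m, 1)
    dimnames(m) <- list(resnos, resnos)
    structure(m, class = c("contact_map", "matrix"), resno = resnos,
              cutoff_nm = cutoff, min_sep = min_sep, mode = mode)
  })
  if (by_replica) return(maps)
  avg <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
  structure(avg, class = c("contact_map", "matrix"), resno = resnos,
            cutoff_nm = cutoff, min_sep = min_sep, mode = mode,
            n_replicas = length(maps))
}

#' Per-residue contact totals with SEM
#'
#' One-dimensional summation of a stack of contact maps:
#' `N_contact(i) = sum_j map(i, j)`, with mean and standard error across
#' replicas (or across contiguous time blocks, see [contact_blocks]).
#'
#' @param maps list of `contact_map` objects (>= 2 for a SEM).
#' @return data.frame with `resno`, `n_contact`, `sem`.
#' @export
contact_totals <- function(maps) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  if (length(maps) < 2)
    stop("need >= 2 replicas or blocks to estimate a SEM")
  tot <- vapply(maps, function(m) rowSums(unclass(m)), numeric(nrow(maps[[1]])))
  data.frame(resno = attr(maps[[1]], "resno"),
             n_contact = rowMeans(tot),
             sem = apply(tot, 1, sd) / sqrt(length(maps)))
}

#' Contact maps over contiguous time blocks
#'
#' Splits a single run into `n_blocks` contiguous, equal blocks of frames
#' (after the equilibration drop) and computes one contact map per block,
#' for block-averaged contact totals.
#'
#' @inheritParams contact_map
#' @param n_blocks number of blocks (default 5).
#' @return list of `contact_map` objects.
#' @export
contact_blocks <- function(traj, n_blocks = 5, cutoff = 0.6, min_sep = 3,
                           mode = c("inter", "intra", "both"),
                           drop_frames = 0) {
  mode <- match.arg(mode)
  nf <- dim(traj$xyz)[1]
  frames <- seq_len(nf)
  if (drop_frames > 0) frames <- frames[-seq_len(min(drop_frames, nf))]
  if (length(frames) < n_blocks) stop("fewer frames than blocks")
  blocks <- split(frames, cut(seq_along(frames), n_blocks, labels = FALSE))
  lapply(blocks, function(fr) {
    sub <- traj_ensemble(traj$atoms, traj$xyz[fr, , , drop = FALSE])
    contact_map(sub, cutoff = cutoff, min_sep = min_sep, mode = mode)
  })
}

#' Minimum inter-chain heavy-atom distance
#'
#' Per-frame minimum distance between the heavy atoms of two chains, plus
#' dissociation episodes: maximal runs of frames above `threshold` lasting
#' at least `min_dwell` frames.
#'
#' @param traj a [traj_ensemble].
#' @param chains the two chain ids.
#' @param threshold episode threshold, nm (default the 0.6 nm contact
#'   cutoff).
#' @param min_dwell minimum episode length, frames.
#' @return data.frame `frame`, `min_dist_nm`; episodes in attribute
#'   `"episodes"` (data.frame `start`, `end`).
#' @export
min_interchain_distance <- function(traj, chains, threshold = 0.6,
                                    min_dwell = 1) {
  stopifnot(length(chains) == 2, chains[1] != chains[2])
  i1 <- select_atoms(traj, chains = chains[1], heavy = TRUE)
  i2 <- select_atoms(traj, chains = chains[2], heavy = TRUE)
  if (!length(i1) || !length(i2)) stop("chain absent: ",
                                       chains[c(length(i1), length(i2)) == 0][1])
  nf <- dim(traj$xyz)[1]
  md <- vapply(seq_len(nf), function(f) {
    x1 <- traj$xyz[f, i1, , drop = FALSE]; dim(x1) <- c(length(i1), 3)
    x2 <- traj$xyz[f, i2, , drop = FALSE]; dim(x2) <- c(length(i2), 3)
    # squared cross distances
    d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
    sqrt(max(0, min(d2)))
  }, 0)
  above <- md > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_dwell
  episodes <- data.frame(start = starts[keep], end = ends[keep])
  structure(data.frame(frame = seq_len(nf), min_dist_nm = md),
            episodes = episodes, threshold_nm = threshold)
}

#' Combined model-confidence score for predicted complexes
#'
#' The weighted interface/global predicted-TM score used to rank predicted
#' multimer models: `0.8 * ipTM + 0.2 * pTM`.
#'
#' @param iptm,ptm interface and global predicted TM-scores, each in
#'   `[0, 1]` (vectorized).
#' @return the combined confidence score.
#' @examples
#' af2_confidence(0.2, 0.7)  # 0.30
#' @export
af2_confidence <- function(iptm, ptm) {
  if (any(!is.finite(iptm)) || any(iptm < 0) || any(iptm > 1) ||
      any(!is.finite(ptm)) || any(ptm < 0) || any(ptm > 1))
    stop("ipTM and pTM must lie in [0, 1]")
  0.8 * iptm + 0.2 * ptm
}
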