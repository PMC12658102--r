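#' Optimal-superposition RMSD between two coordinate sets
#'
#' Least-squares (Kabsch) superposition of `x` onto `y` after centering,
#' with the proper-rotation (reflection-free) correction, returning the
#' coordinate RMSD in the input units.
#'
#' @param x,y `n x 3` coordinate matrices with matching atom order.
#' @return RMSD (same units as input).
#' @export
rmsd_kabsch <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), ncol(x) == 3, all(dim(x) == dim(y)))
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$v %*% t(s$u)))
  sig <- s$d; sig[3] <- sig[3] * d
  msd <- (sum(xc^2) + sum(yc^2) - 2 * sum(sig)) / n
  sqrt(max(0, msd))
}

#' GROMOS conformational clustering
#'
#' Greedy neighbor-count clustering of frames under a pairwise RMSD cutoff
#' (after optimal superposition): repeatedly take the frame with the most
#' neighbors within `cutoff` as a cluster center, assign it and its
#' neighbors to a cluster, remove them, and recurse.  Ties are broken
#' toward the earliest frame index, making the result deterministic.
#'
#' @param traj a [traj_ensemble].
#' @param resno,chains,names selection; default backbone atoms
#'   (N, CA, C, O) of residues 320-341, all chains.
#' @param cutoff RMSD cutoff, nm.
#' @param frames frame window to cluster (default all; e.g. the index range
#'   covering the last microsecond of a run).
#' @return list of clusters sorted by decreasing size, each with `center`
#'   (frame index), `members`, `size`; class `gromos_clusters`.
#' @export
cluster_gromos <- function(traj, resno = 320:341, chains = NULL,
                           names = c("N", "CA", "C", "O"), cutoff = 0.3,
                           frames = NULL) {
  sel <- select_atoms(traj, resno = resno, chains = chains, heavy = TRUE,
                      names = names)
  if (!length(sel)) stop("empty atom selection")
  if (is.null(frames)) frames <- seq_len(dim(traj$xyz)[1])
  if (!length(frames)) stop("empty frame window")
  nf <- length(frames)
  coords <- lapply(frames, function(f) {
    m <- traj$xyz[f, sel, , drop = FALSE]; dim(m) <- c(length(sel), 3); m
  })
  adj <- diag(TRUE, nf)
  if (nf > 1) {
    for (i in 1:(nf - 1)) for (j in (i + 1):nf) {
      hit <- rmsd_kabsch(coords[[i]], coords[[j]]) <= cutoff
      adj[i, j] <- hit; adj[j, i] <- hit
    }
  }
  remaining <- rep(TRUE, nf)
  clusters <- list()
  while (any(remaining)) {
    counts <- colSums(adj[remaining, , drop = FALSE]) * remaining
    center <- which.max(counts)           # which.max takes the earliest tie
    members <- which(adj[center, ] & remaining)
    clusters[[length(clusters) + 1]] <-
      list(center = frames[center], members = frames[members],
           size = length(members))
    remaining[members] <- FALSE
  }
  ord <- order(-vapply(clusters, function(cl) cl$size, 0),
               vapply(clusters, function(cl) cl$center, 0))
  structure(clusters[ord], class = "gromos_clusters")
}

#' @export
print.gromos_clusters <- function(x, ...) {
  cat("GROMOS clustering:", length(x), "cluster(s)\n")
  for (i in seq_along(x))
    cat(sprintf("  #%d size %d, center frame %d\n", i, x[[i]]$size,
                x[[i]]$center))
  invisible(x)
}
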