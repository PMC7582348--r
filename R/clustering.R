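# Pairwise-RMSD matrices, GROMOS (Daura neighbour-count) clustering,
# representative structures, and docking-pose clustering.

#' Pairwise RMSD matrix over trajectory frames
#'
#' @param traj a `Trajectory`
#' @param selection selection expression or index vector (default `"name CA"`)
#' @param superpose least-squares superpose each pair before the RMSD
#'   (default TRUE)
#' @param units unit label recorded on the matrix ("A" or "nm"); values are
#'   converted when "nm" is requested
#' @return symmetric matrix with attributes `units` and `labels` (class
#'   `DistanceMatrix`)
#' @export
rmsd_matrix <- function(traj, selection = "name CA", superpose = TRUE,
                        units = c("A", "nm")) {
  units <- match.arg(units)
  nf <- n_frames(traj)
  if (nf < 2) stopf("rmsd_matrix needs at least 2 frames")
  idx <- if (is.numeric(selection)) as.integer(selection)
         else select_atoms(traj, selection)
  if (length(idx) == 0) stopf("empty selection")
  xs <- lapply(traj$frames, function(f) f[idx, , drop = FALSE])
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
    r <- coord_rmsd(xs[[i]], xs[[j]], superpose = superpose)
    if (units == "nm") r <- r / 10
    m[i, j] <- m[j, i] <- r
  }
  dimnames(m) <- list(seq_len(nf), seq_len(nf))
  structure(m, units = units, class = c("DistanceMatrix", "matrix", "array"))
}

#' GROMOS (neighbour-count greedy) clustering
#'
#' Daura's algorithm: repeatedly take the unassigned label with the most
#' unassigned neighbours within the cutoff as the representative of a new
#' cluster containing it and those neighbours; remove them; repeat. Removed
#' members do not count as neighbours in later rounds. Ties are broken by the
#' lowest label. Clusters are reported in formation order.
#'
#' @param dmat symmetric distance matrix (any units; cutoff must match)
#' @param cutoff neighbour cutoff, same units as `dmat`
#' @return list(clusters = list of member index vectors, representatives,
#'   sizes, cutoff, units) of class `ClusterResult`
#' @export
gromos_cluster <- function(dmat, cutoff) {
  if (cutoff <= 0) stopf("cutoff must be positive")
  m <- unclass(dmat)
  n <- nrow(m)
  labels <- seq_len(n)
  alive <- rep(TRUE, n)
  clusters <- list(); reps <- integer(0)
  while (any(alive)) {
    idx <- which(alive)
    nb <- vapply(idx, function(i) sum(m[i, idx] <= cutoff), numeric(1))
    rep_i <- idx[which.max(nb)]  # which.max takes the first (lowest) on ties
    members <- idx[m[rep_i, idx] <= cutoff]
    clusters[[length(clusters) + 1]] <- members
    reps <- c(reps, rep_i)
    alive[members] <- FALSE
  }
  structure(list(clusters = clusters, representatives = reps,
                 sizes = vapply(clusters, length, integer(1)),
                 cutoff = cutoff, units = attr(dmat, "units") %||% ""),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("<ClusterResult> %d clusters (cutoff %g %s)\n",
              length(x$clusters), x$cutoff, x$units))
  for (k in seq_along(x$clusters))
    cat(sprintf("  cluster %d: size %d, representative %d\n",
                k, x$sizes[k], x$representatives[k]))
  invisible(x)
}

#' Representative frame of the rank-th largest cluster
#'
#' "cluster1" is the largest cluster; its representative is the member that
#' had the most within-cutoff neighbours when the cluster was formed.
#'
#' @param result a `ClusterResult`
#' @param cluster_rank 1 = largest cluster
#' @return the representative label (frame index)
#' @export
representative_structure <- function(result, cluster_rank = 1) {
  if (cluster_rank < 1 || cluster_rank > length(result$clusters))
    stopf("cluster_rank %d out of range (%d clusters)",
          cluster_rank, length(result$clusters))
  ord <- order(-result$sizes, seq_along(result$sizes))
  result$representatives[ord[cluster_rank]]
}

#' Cluster docking poses per ligand at an RMSD cutoff
#'
#' Poses of one ligand share the receptor frame, so the pairwise pose RMSD is
#' computed WITHOUT superposition, on heavy atoms, with no symmetry
#' correction. GROMOS clustering at `rmsd_cutoff` (default 2 Angstroms)
#' yields the most frequent binding conformation; the representative pose is
#' the member of the largest cluster closest to that cluster's coordinate
#' centroid (ties to the lowest pose id).
#'
#' @param poses a `PoseSet` (see [read_sdf()] / [make_pose_library()])
#' @param rmsd_cutoff Angstroms (default 2.0)
#' @return named list per ligand: list(result = `ClusterResult`,
#'   representative = pose index)
#' @export
pose_cluster <- function(poses, rmsd_cutoff = 2.0) {
  stopifnot(inherits(poses, "PoseSet"))
  out <- list()
  for (lig in poses$ligands) {
    np <- length(lig$poses)
    heavy <- lig$poses[[1]]$atoms$element != "H"
    coords <- lapply(lig$poses, function(p) {
      if (nrow(p$atoms) != length(heavy))
        stopf("ligand %s: inconsistent atom counts across poses", lig$id)
      as.matrix(p$atoms[heavy, c("x", "y", "z")])
    })
    if (np == 1) {
      res <- structure(list(clusters = list(1L), representatives = 1L,
                            sizes = 1L, cutoff = rmsd_cutoff, units = "A"),
                       class = "ClusterResult")
      out[[lig$id]] <- list(result = res, representative = 1L)
      next
    }
    m <- matrix(0, np, np)
    for (i in seq_len(np - 1)) for (j in (i + 1):np)
      m[i, j] <- m[j, i] <- coord_rmsd(coords[[i]], coords[[j]],
                                       superpose = FALSE)
    attr(m, "units") <- "A"
    res <- gromos_cluster(m, rmsd_cutoff)
    big <- res$clusters[[order(-res$sizes, seq_along(res$sizes))[1]]]
    cen <- Reduce(`+`, coords[big]) / length(big)
    dev <- vapply(big, function(i) sqrt(mean(rowSums((coords[[i]] - cen)^2))),
                  numeric(1))
    out[[lig$id]] <- list(result = res, representative = big[which.min(dev)])
  }
  out
}

#' Write a ClusterResult to JSON
#' @param result a `ClusterResult`
#' @param path output path
#' @return invisibly, the path
#' @export
write_clusters_json <- function(result, path) {
  jsonlite::write_json(list(
    cutoff = result$cutoff, units = result$units,
    n_clusters = length(result$clusters),
    sizes = result$sizes, representatives = result$representatives,
    clusters = result$clusters), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
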