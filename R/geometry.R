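# Helix axes, TM rotation-angle series, Kabsch superposition, COM distances.

#' Transmembrane segment table
#'
#' Defaults are the CXCR3 assignments: TM1 54-80, TM2 90-110, TM3 126-147
#' (optionally extended by the DRY motif 148-150), TM4 170-189, TM5 213-233
#' (optionally extended by 234-235), TM6 256-277, TM7 299-321. Ranges are
#' inclusive on both ends and use the residue numbers of the source file.
#'
#' @param chain chain id the segments live on
#' @param extend_tm3 include the DRY residues 148-150 with TM3
#' @param extend_tm5 include residues 234-235 with TM5
#' @return data.frame with columns tm, chain, first, last (class
#'   `TMSegmentSet`)
#' @export
tm_segments_default <- function(chain = "R", extend_tm3 = FALSE,
                                extend_tm5 = FALSE) {
  seg <- data.frame(
    tm = paste0("TM", 1:7),
    chain = chain,
    first = c(54, 90, 126, 170, 213, 256, 299),
    last  = c(80, 110, 147, 189, 233, 277, 321),
    stringsAsFactors = FALSE
  )
  if (extend_tm3) seg$last[3] <- 150
  if (extend_tm5) seg$last[5] <- 235
  validate_tm_segments(seg)
}

#' Validate / construct a TMSegmentSet
#' @param seg data.frame with tm, chain, first, last
#' @return the validated segment table
#' @export
validate_tm_segments <- function(seg) {
  stopifnot(all(c("tm", "chain", "first", "last") %in% names(seg)))
  if (any(seg$first > seg$last)) stopf("segment with first > last")
  for (ch in unique(seg$chain)) {
    s <- seg[seg$chain == ch, ]
    s <- s[order(s$first), ]
    if (nrow(s) > 1 && any(s$first[-1] <= s$last[-nrow(s)]))
      stopf("overlapping TM segments on chain %s", ch)
  }
  class(seg) <- c("TMSegmentSet", "data.frame")
  seg
}

# CA indices of one segment, in residue order
.segment_ca_idx <- function(atoms, seg_row) {
  idx <- which(atoms$chain == seg_row$chain & atoms$name == "CA" &
               atoms$resid >= seg_row$first & atoms$resid <= seg_row$last)
  idx[order(atoms$resid[idx])]
}

#' Fit a helix axis
#'
#' The axis is the first principal component of the centred C-alpha
#' coordinates, oriented from the N- to the C-terminal end (positive dot
#' product with last minus first point).
#'
#' @param coords n x 3 matrix of C-alpha coordinates in residue order (n >= 4)
#' @return list(axis = unit 3-vector, centroid = 3-vector)
#' @export
helix_axis <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4) stopf("helix_axis needs at least 4 points")
  centroid <- colMeans(coords)
  x <- sweep(coords, 2, centroid)
  sv <- svd(x, nu = 0, nv = 1)
  if (sv$d[1] < 1e-9) stopf("degenerate coordinates: no principal axis")
  axis <- sv$v[, 1]
  if (sum(axis * (coords[nrow(coords), ] - coords[1, ])) < 0) axis <- -axis
  list(axis = unitize(axis), centroid = centroid)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation (det = +1, reflections sign-corrected) and
#' translation mapping `mobile` onto `target`.
#'
#' @param mobile,target n x 3 coordinate matrices (n >= 3)
#' @param fit_idx optional indices of the points used for the fit (default
#'   all); the returned transform still applies to all points
#' @return list(R = 3x3 rotation, t = translation, rmsd = post-fit RMSD over
#'   the fit points, transform = function(coords))
#' @export
kabsch_superpose <- function(mobile, target, fit_idx = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) stopf("point count mismatch")
  fm <- if (is.null(fit_idx)) mobile else mobile[fit_idx, , drop = FALSE]
  ft <- if (is.null(fit_idx)) target else target[fit_idx, , drop = FALSE]
  if (nrow(fm) < 3) stopf("kabsch needs at least 3 fit points")
  cm <- colMeans(fm); ct <- colMeans(ft)
  H <- t(sweep(fm, 2, cm)) %*% sweep(ft, 2, ct)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tvec <- ct - as.vector(R %*% cm)
  fitted <- sweep(fm %*% t(R), 2, tvec, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - ft)^2)))
  list(R = R, t = tvec, rmsd = rmsd,
       transform = function(coords) sweep(as.matrix(coords) %*% t(R), 2, tvec, `+`))
}

#' RMSD between two coordinate sets
#' @param a,b n x 3 matrices
#' @param superpose superpose first (default TRUE)
#' @return RMSD in the input units
#' @export
coord_rmsd <- function(a, b, superpose = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stopf("point count mismatch")
  if (superpose) return(kabsch_superpose(a, b)$rmsd)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Rotation angle of one TM segment relative to a reference frame
#'
#' The frame is first globally superposed onto the reference using the
#' C-alphas of all TM segments (removing whole-body motion), then each
#' segment residue's C-alpha is projected onto the plane perpendicular to the
#' reference helix axis through the reference centroid; the returned angle is
#' the circular mean of the per-residue signed angles (right-hand rule about
#' the axis), wrapped to (-180, 180].
#'
#' @param frame_coords,ref_coords full-topology n x 3 coordinate matrices
#' @param atoms the shared atom table
#' @param segments `TMSegmentSet` (all segments; defines the global fit set)
#' @param tm name of the segment to measure
#' @param method `"projection"` (default) or `"kabsch_twist"` (cross-check:
#'   twist component of the per-helix Kabsch rotation about the helix axis)
#' @return signed angle in degrees in (-180, 180]
#' @export
tm_rotation_angle <- function(frame_coords, ref_coords, atoms, segments, tm,
                              method = c("projection", "kabsch_twist")) {
  method <- match.arg(method)
  seg_row <- segments[segments$tm == tm, ]
  if (nrow(seg_row) != 1) stopf("unknown TM segment '%s'", tm)
  fit_idx <- unlist(lapply(seq_len(nrow(segments)), function(i)
    .segment_ca_idx(atoms, segments[i, ])))
  seg_idx <- .segment_ca_idx(atoms, seg_row)
  if (length(seg_idx) < 4) stopf("segment %s resolves to <4 C-alphas", tm)

  sup <- kabsch_superpose(frame_coords, ref_coords, fit_idx = fit_idx)
  fc <- sup$transform(frame_coords)[seg_idx, , drop = FALSE]
  rc <- ref_coords[seg_idx, , drop = FALSE]

  ax <- helix_axis(rc)
  u <- ax$axis; cen <- ax$centroid
  proj <- function(p) {
    d <- sweep(p, 2, cen)
    d - outer(as.vector(d %*% u), u)
  }
  if (method == "kabsch_twist") {
    # decompose the per-helix rotation into a twist about the reference axis
    hs <- kabsch_superpose(rc, fc)
    Ru <- as.vector(hs$R %*% u)
    # project a vector perpendicular to u and see how R moves it around u
    ref_v <- proj(rc)
    ref_v <- ref_v[which.max(rowSums(ref_v^2)), ]
    w <- as.vector(hs$R %*% ref_v)
    w <- w - sum(w * u) * u
    ang <- atan2(sum(vcross(ref_v, w) * u), sum(ref_v * w))
    return(wrap_angle(rad2deg(ang)))
  }
  pr <- proj(rc); pf <- proj(fc)
  nr <- sqrt(rowSums(pr^2)); nf <- sqrt(rowSums(pf^2))
  ok <- nr > 1e-6 & nf > 1e-6
  if (!any(ok)) stopf("all residues project onto the axis; angle undefined")
  pr <- pr[ok, , drop = FALSE]; pf <- pf[ok, , drop = FALSE]
  sines <- vapply(seq_len(nrow(pr)), function(i)
    sum(vcross(pr[i, ], pf[i, ]) * u), numeric(1))
  cosines <- rowSums(pr * pf)
  ang_i <- atan2(sines, cosines)
  # circular mean of the per-residue angles
  wrap_angle(rad2deg(atan2(mean(sin(ang_i)), mean(cos(ang_i)))))
}

#' Per-frame, per-TM rotation-angle series
#'
#' @param traj a `Trajectory`
#' @param segments a `TMSegmentSet` (default [tm_segments_default()])
#' @param ref_frame index of the reference frame (default 1, the 0-ns
#'   conformation)
#' @param stride keep every stride-th frame (default 1)
#' @param mode `"reference"` (angle vs the reference frame) or `"delta"`
#'   (frame-to-frame change)
#' @param method passed to [tm_rotation_angle()]
#' @return data.frame frame x TM of signed angles in degrees (class
#'   `RotationSeries`); the reference row is all zeros
#' @export
rotation_series <- function(traj, segments = tm_segments_default(),
                            ref_frame = 1, stride = 1,
                            mode = c("reference", "delta"),
                            method = "projection") {
  mode <- match.arg(mode)
  nf <- n_frames(traj)
  if (ref_frame < 1 || ref_frame > nf) stopf("ref_frame out of range")
  frames <- seq(1, nf, by = max(1, stride))
  ref <- traj$frames[[ref_frame]]
  tms <- segments$tm
  out <- matrix(0, length(frames), length(tms),
                dimnames = list(NULL, tms))
  for (k in seq_along(frames)) {
    f <- frames[k]
    base <- if (mode == "reference") ref else
      traj$frames[[frames[max(1, k - 1)]]]
    if (f == ref_frame && mode == "reference") { out[k, ] <- 0; next }
    for (tm in tms)
      out[k, tm] <- tm_rotation_angle(traj$frames[[f]], base, traj$atoms,
                                      segments, tm, method = method)
  }
  res <- data.frame(frame = frames, out, check.names = FALSE)
  if (!is.null(traj$times)) res$time_ns <- traj$times[frames]
  class(res) <- c("RotationSeries", "data.frame")
  res
}

#' Centre-of-mass distance series between two selections
#'
#' @param traj a `Trajectory`
#' @param selA,selB selection expressions (or integer index vectors)
#' @param mass_weighted use atomic masses (default TRUE); unknown elements get
#'   unit mass so coarse-grained beads work
#' @return data.frame(frame, distance_A)
#' @export
com_distance <- function(traj, selA, selB, mass_weighted = TRUE) {
  traj <- as_trajectory(traj)
  ia <- if (is.numeric(selA)) as.integer(selA) else select_atoms(traj, selA)
  ib <- if (is.numeric(selB)) as.integer(selB) else select_atoms(traj, selB)
  if (length(ia) == 0) stopf("selection A matches no atoms")
  if (length(ib) == 0) stopf("selection B matches no atoms")
  wa <- if (mass_weighted) element_mass(traj$atoms$element[ia]) else rep(1, length(ia))
  wb <- if (mass_weighted) element_mass(traj$atoms$element[ib]) else rep(1, length(ib))
  d <- vapply(traj$frames, function(xyz) {
    ca <- colSums(xyz[ia, , drop = FALSE] * wa) / sum(wa)
    cb <- colSums(xyz[ib, , drop = FALSE] * wb) / sum(wb)
    vnorm(ca - cb)
  }, numeric(1))
  data.frame(frame = seq_along(d), distance_A = d)
}

# mass-weighted COM of a coordinate block
.com <- function(xyz, elements, mass_weighted = TRUE) {
  w <- if (mass_weighted) element_mass(elements) else rep(1, nrow(xyz))
  colSums(xyz * w) / sum(w)
}
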