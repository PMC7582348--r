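# Synthetic fixtures with planted ground truth: ideal helices, 7-TM bundles,
# rotation-schedule trajectories, receptor-chemokine complexes with planted
# contacts and approach schedules, and ligand pose libraries with planted
# pharmacophoric clusters. All generators are deterministic under a fixed
# seed and return their truth tables alongside the fixture.

#' Build an ideal alpha-helix
#'
#' C-alpha trace on a cylinder (default), or a full N-CA-C-O backbone built
#' from ideal internal coordinates with phi = -57, psi = -47 degrees. Rise
#' 1.5 Angstroms/residue and twist 100 degrees/residue are the canonical
#' alpha-helix values; the C-alpha radius defaults to the canonical 2.3.
#'
#' @param n_res number of residues (>= 4)
#' @param rise Angstroms per residue along the axis
#' @param twist degrees per residue about the axis
#' @param radius C-alpha distance from the axis (trace mode)
#' @param axis_origin,axis_direction helix axis placement (direction is
#'   normalised)
#' @param chain chain id
#' @param start_resid first residue number
#' @param resname residue name given to every residue
#' @param mode `"ca"` (trace) or `"backbone"` (N, CA, C, O per residue)
#' @param phi,psi backbone dihedrals for backbone mode (degrees)
#' @param phase starting phase angle (degrees) of residue 1 about the axis
#' @return a `Structure`
#' @export
make_ideal_helix <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                             axis_origin = c(0, 0, 0),
                             axis_direction = c(0, 0, 1),
                             chain = "R", start_resid = 1L, resname = "ALA",
                             mode = c("ca", "backbone"),
                             phi = -57, psi = -47, phase = 0) {
  mode <- match.arg(mode)
  if (n_res < 4) stopf("a helix needs at least 4 residues")
  u <- unitize(axis_direction)
  if (mode == "ca") {
    # orthonormal frame perpendicular to u
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- unitize(vcross(u, ref)); e2 <- vcross(u, e1)
    i <- seq_len(n_res)
    th <- deg2rad(phase + (i - 1) * twist)
    xyz <- matrix(axis_origin, n_res, 3, byrow = TRUE) +
      outer((i - 1) * rise, u) +
      radius * (outer(cos(th), e1) + outer(sin(th), e2))
    atoms <- data.frame(serial = i, name = "CA", resname = resname,
                        chain = chain, resid = start_resid + i - 1L,
                        element = "C", het = FALSE)
    return(new_structure(atoms, xyz, title = "ideal helix (CA trace)"))
  }
  bb <- .build_backbone(n_res, phi, psi)
  ax <- helix_axis(bb$xyz[bb$atoms$name == "CA", , drop = FALSE])
  # rotate the fitted axis onto the requested direction
  v <- vcross(ax$axis, u); s <- vnorm(v); c_ <- sum(ax$axis * u)
  R <- if (s < 1e-12) {
    if (c_ > 0) diag(3) else rotation_about_axis(
      if (abs(u[1]) < 0.9) vcross(u, c(1, 0, 0)) else vcross(u, c(0, 1, 0)), 180)
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
  }
  xyz <- sweep(bb$xyz, 2, ax$centroid) %*% t(R)
  xyz <- sweep(xyz, 2, axis_origin + u * (n_res - 1) * rise / 2, `+`)
  a <- bb$atoms
  a$resname <- resname; a$chain <- chain
  a$resid <- start_resid + a$resid - 1L
  new_structure(a, xyz, title = "ideal helix (backbone)")
}

# NeRF chain building with standard bond geometry
.place_atom <- function(p1, p2, p3, bond, angle_deg, torsion_deg) {
  b <- deg2rad(angle_deg); t <- -deg2rad(torsion_deg)
  d <- c(-bond * cos(b), bond * sin(b) * cos(t), bond * sin(b) * sin(t))
  bc <- unitize(p3 - p2)
  n <- unitize(vcross(p2 - p1, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.vector(m %*% d) + p3
}

.build_backbone <- function(n_res, phi, psi, omega = 180) {
  # bond lengths / angles: N-CA 1.458, CA-C 1.525, C-N 1.329;
  # N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7
  xyz <- matrix(NA_real_, 4 * n_res, 3)
  nm <- rep(c("N", "CA", "C", "O"), n_res)
  rid <- rep(seq_len(n_res), each = 4)
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(1.458, 0, 0)
  xyz[3, ] <- .place_atom(c(0, 1, 0), xyz[1, ], xyz[2, ], 1.525, 111.2, 0)
  at <- function(r, name) xyz[(r - 1) * 4 + match(name, c("N", "CA", "C", "O")), ]
  set <- function(r, name, p)
    xyz[(r - 1) * 4 + match(name, c("N", "CA", "C", "O")), ] <<- p
  for (r in seq_len(n_res)) {
    if (r > 1) {
      set(r, "N", .place_atom(at(r - 1, "N"), at(r - 1, "CA"), at(r - 1, "C"),
                              1.329, 116.2, psi))
      set(r, "CA", .place_atom(at(r - 1, "CA"), at(r - 1, "C"), at(r, "N"),
                               1.458, 121.7, omega))
      set(r, "C", .place_atom(at(r - 1, "C"), at(r, "N"), at(r, "CA"),
                              1.525, 111.2, phi))
    }
    # carbonyl O in the peptide plane: torsion N-CA-C-O = psi + 180
    set(r, "O", .place_atom(at(r, "N"), at(r, "CA"), at(r, "C"),
                            1.231, 120.8, psi + 180))
  }
  atoms <- data.frame(serial = seq_len(4 * n_res), name = nm, resname = "ALA",
                      chain = "R", resid = rid,
                      element = substr(nm, 1, 1), het = FALSE)
  list(atoms = atoms, xyz = xyz)
}

#' Build a 7-TM-style helix bundle
#'
#' One helix per segment row, placed on a circle, with alternating axis
#' orientation (up/down, as in a serpentine membrane bundle); residue numbers
#' follow the segment table's inclusive ranges. Optional straight-line
#' C-alpha linkers fill the loop residue numbers between consecutive
#' segments. Any inter-helix atom pair closer than 2 Angstroms is an error.
#'
#' @param segments a `TMSegmentSet` (default the CXCR3-style table); at
#'   least 2 rows
#' @param circle_radius bundle circle radius, Angstroms
#' @param rise,twist,radius helix geometry (see [make_ideal_helix()])
#' @param mode `"ca"` or `"backbone"`
#' @param loops also build straight-line loop traces between segments
#' @return list(structure = `Structure`, segments) of the bundle
#' @export
make_tm_bundle <- function(segments = tm_segments_default(),
                           circle_radius = 12, rise = 1.5, twist = 100,
                           radius = 2.3, mode = "ca", loops = FALSE) {
  segments <- validate_tm_segments(segments)
  nseg <- nrow(segments)
  if (nseg < 2) stopf("a bundle needs at least 2 helices")
  parts <- list()
  max_len <- max(segments$last - segments$first + 1)
  for (i in seq_len(nseg)) {
    n_res <- segments$last[i] - segments$first[i] + 1
    ang <- 2 * pi * (i - 1) / nseg
    up <- i %% 2 == 1
    origin <- c(circle_radius * cos(ang), circle_radius * sin(ang),
                if (up) -(n_res - 1) * rise / 2 else (n_res - 1) * rise / 2)
    h <- make_ideal_helix(n_res, rise = rise, twist = twist, radius = radius,
                          axis_origin = origin,
                          axis_direction = if (up) c(0, 0, 1) else c(0, 0, -1),
                          chain = segments$chain[i],
                          start_resid = segments$first[i], mode = mode)
    parts[[i]] <- h
  }
  # clash check between helices
  for (i in seq_len(nseg - 1)) for (j in (i + 1):nseg) {
    A <- parts[[i]]$coords; B <- parts[[j]]$coords
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
    if (min(d2) < 4) stopf("clashing helix placements (%s vs %s)",
                           segments$tm[i], segments$tm[j])
  }
  if (loops) {
    for (i in seq_len(nseg - 1)) {
      gap <- (segments$last[i] + 1):(segments$first[i + 1] - 1)
      if (length(gap) == 0 || segments$last[i] + 1 > segments$first[i + 1] - 1)
        next
      a_end <- parts[[i]]$coords[nrow(parts[[i]]$coords), ]
      b_start <- parts[[i + 1]]$coords[1, ]
      frac <- seq_along(gap) / (length(gap) + 1)
      xyz <- t(vapply(frac, function(f) a_end + f * (b_start - a_end),
                      numeric(3)))
      atoms <- data.frame(serial = seq_along(gap), name = "CA",
                          resname = "GLY", chain = segments$chain[i],
                          resid = gap, element = "C", het = FALSE)
      parts[[length(parts) + 1]] <- new_structure(atoms, xyz)
    }
  }
  all_atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  all_xyz <- do.call(rbind, lapply(parts, `[[`, "coords"))
  ord <- order(all_atoms$chain, all_atoms$resid,
               match(all_atoms$name, c("N", "CA", "C", "O")))
  all_atoms <- all_atoms[ord, ]; all_xyz <- all_xyz[ord, , drop = FALSE]
  all_atoms$serial <- seq_len(nrow(all_atoms))
  list(structure = new_structure(all_atoms, all_xyz, title = "synthetic TM bundle"),
       segments = segments)
}

#' Trajectory with planted per-TM rotations
#'
#' Frame f applies the scheduled rotation of each TM about that helix's own
#' fitted axis (through its centroid), then an optional whole-body rigid
#' transform, then i.i.d. Gaussian coordinate noise. Frame 1 must be all
#' zeros (the reference conformation). Deterministic given `seed`.
#'
#' @param bundle a `Structure` from [make_tm_bundle()]
#' @param segments the bundle's `TMSegmentSet`
#' @param schedule matrix/data.frame (frames x TM names) of planted rotation
#'   angles in degrees; row 1 all zeros
#' @param noise_sd Gaussian coordinate noise sd, Angstroms
#' @param global_motion apply a random rigid transform per frame (frame 1
#'   kept fixed); alternatively a list of `list(R =, t =)` per frame
#' @param seed RNG seed
#' @return list(traj = `Trajectory`, truth = data.frame(frame, tm, angle_deg))
#' @export
make_rotated_trajectory <- function(bundle, segments, schedule, noise_sd = 0,
                                    global_motion = FALSE, seed = 1) {
  schedule <- as.matrix(schedule)
  if (is.null(colnames(schedule)) ||
      !all(colnames(schedule) %in% segments$tm))
    stopf("schedule columns must be TM names from the segment set")
  if (any(abs(schedule[1, ]) > 1e-12))
    stopf("schedule row 1 (the reference frame) must be all zeros")
  set.seed(seed)
  atoms <- bundle$atoms
  base <- bundle$coords
  axes <- lapply(colnames(schedule), function(tm) {
    row <- segments[segments$tm == tm, ]
    ca <- .segment_ca_idx(atoms, row)
    all_idx <- which(atoms$chain == row$chain & atoms$resid >= row$first &
                     atoms$resid <= row$last)
    c(helix_axis(base[ca, , drop = FALSE]), list(idx = all_idx))
  })
  names(axes) <- colnames(schedule)
  nf <- nrow(schedule)
  frames <- vector("list", nf)
  truth <- list()
  for (f in seq_len(nf)) {
    xyz <- base
    for (tm in colnames(schedule)) {
      ang <- schedule[f, tm]
      truth[[length(truth) + 1]] <- data.frame(frame = f, tm = tm,
                                               angle_deg = wrap_angle(ang))
      if (abs(ang) < 1e-12) next
      ax <- axes[[tm]]
      R <- rotation_about_axis(ax$axis, ang)
      idx <- ax$idx
      xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, ax$centroid) %*%
                            t(R), 2, ax$centroid, `+`)
    }
    if (is.list(global_motion)) {
      gm <- global_motion[[f]]
      if (!is.null(gm)) xyz <- apply_rigid(xyz, gm$R, gm$t)
    } else if (isTRUE(global_motion) && f > 1) {
      xyz <- apply_rigid(xyz, random_rotation(), stats::runif(3, -20, 20))
    }
    if (noise_sd > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd),
                          nrow(xyz), 3)
    frames[[f]] <- xyz
  }
  list(traj = new_trajectory(bundle, frames),
       truth = do.call(rbind, truth))
}

# element guessed from a protein atom name
.plant_element <- function(name) infer_element(name)

# distances used to realise planted contacts (safely inside the default
# detector cutoffs) and to park them when absent (cutoff + 1.5 A)
.PLANT_DIST <- c(saltbridge = 3.0, hbond = 2.9, hydrophobic = 3.6)
.PLANT_CUTOFF <- c(saltbridge = 4.0, hbond = 3.5, hydrophobic = 3.9)

#' Receptor-chemokine complex trajectory with planted contacts
#'
#' The second chain is rigidly placed so its mass-weighted centre of mass
#' sits at the scheduled distance from the receptor COM along `direction`
#' (to within 0.01 Angstroms). Planted contacts are realised by moving the
#' named partner atom to a kind-specific distance (salt bridge 3.0, H-bond
#' 2.9, hydrophobic 3.6 Angstroms) in the listed frames and to cutoff + 1.5
#' elsewhere; when the moved atom belongs to the mobile chain the remaining
#' chain atoms are translated to keep the COM on schedule. Atoms named in a
#' plant that do not exist yet are added next to the residue's C-alpha, and
#' the residue is renamed to the plant's residue type.
#'
#' @param receptor a `Structure` (e.g. a bundle)
#' @param ligand_chain a `Structure` for the approaching chain (distinct
#'   chain id)
#' @param approach numeric vector of per-frame COM distances, Angstroms
#' @param plants list of plants: `list(a = list(chain, resid, resname, atom),
#'   b = list(...), kind, frames)` with kind in hbond / saltbridge /
#'   hydrophobic and `frames` the 1-based frames where the contact is present
#' @param direction unit vector from receptor COM to ligand COM
#' @param seed RNG seed (used for placement of added plant atoms)
#' @return list(traj, truth = data.frame of planted contacts per frame)
#' @export
make_complex_trajectory <- function(receptor, ligand_chain, approach,
                                    plants = list(),
                                    direction = c(1, 0, 0), seed = 1) {
  if (any(approach <= 0)) stopf("approach distances must be positive")
  set.seed(seed)
  dir <- unitize(direction)
  lig_chains <- unique(ligand_chain$atoms$chain)
  if (any(lig_chains %in% unique(receptor$atoms$chain)))
    stopf("ligand chain id collides with a receptor chain")

  atoms <- rbind(receptor$atoms, ligand_chain$atoms)
  xyz <- rbind(receptor$coords, ligand_chain$coords)
  atoms$serial <- seq_len(nrow(atoms))

  # ensure plant atoms exist; rename residues to the plant residue type
  ensure_atom <- function(side) {
    sel <- atoms$chain == side$chain & atoms$resid == side$resid
    if (!any(sel)) stopf("plant residue %s%d not found", side$chain, side$resid)
    if (!is.null(side$resname)) atoms$resname[sel] <<- side$resname
    hit <- which(sel & atoms$name == side$atom)
    if (length(hit) == 1) return(hit)
    ca <- which(sel & atoms$name %in% c("CA", "BB"))[1]
    if (is.na(ca)) ca <- which(sel)[1]
    newrow <- atoms[ca, ]
    newrow$name <- side$atom
    newrow$element <- .plant_element(side$atom)
    atoms <<- rbind(atoms, newrow)
    off <- unitize(stats::rnorm(3)) * 1.2
    xyz <<- rbind(xyz, xyz[ca, ] + off)
    nrow(atoms)
  }
  plant_idx <- lapply(plants, function(p)
    list(ia = ensure_atom(p$a), ib = ensure_atom(p$b)))
  atoms$serial <- seq_len(nrow(atoms))

  # conflicting plants: one atom driven by two plants with different schedules
  if (length(plants) > 1) {
    moved <- vapply(seq_along(plants), function(k) plant_idx[[k]]$ib, integer(1))
    for (i in seq_len(length(plants) - 1)) for (j in (i + 1):length(plants)) {
      if (moved[i] == moved[j] &&
          !identical(sort(plants[[i]]$frames), sort(plants[[j]]$frames)))
        stopf("infeasible plant: atom driven by two plants with conflicting frames")
    }
  }

  is_lig <- atoms$chain %in% lig_chains
  rec_idx <- which(!is_lig); lig_idx <- which(is_lig)
  mass <- element_mass(atoms$element)
  nf <- length(approach)
  frames <- vector("list", nf)
  truth <- list()
  for (f in seq_len(nf)) {
    fx <- xyz
    # receptor-internal plants first (they shift the receptor COM slightly)
    for (k in seq_along(plants)) {
      p <- plants[[k]]; pi_ <- plant_idx[[k]]
      if (is_lig[pi_$ib]) next
      fx[pi_$ib, ] <- .plant_position(fx, pi_, p, f, rec_idx, mass)
    }
    rec_com <- colSums(fx[rec_idx, , drop = FALSE] * mass[rec_idx]) /
      sum(mass[rec_idx])
    lig_com <- colSums(fx[lig_idx, , drop = FALSE] * mass[lig_idx]) /
      sum(mass[lig_idx])
    fx[lig_idx, ] <- sweep(fx[lig_idx, , drop = FALSE], 2,
                           rec_com + approach[f] * dir - lig_com, `+`)
    # ligand-side plants: move every planted atom first, then one
    # compensating shift of the remaining ligand atoms restores the COM
    lig_planted <- integer(0)
    total_shift <- c(0, 0, 0)
    for (k in seq_along(plants)) {
      p <- plants[[k]]; pi_ <- plant_idx[[k]]
      if (!is_lig[pi_$ib]) next
      old <- fx[pi_$ib, ]
      new <- .plant_position(fx, pi_, p, f, rec_idx, mass)
      fx[pi_$ib, ] <- new
      total_shift <- total_shift + mass[pi_$ib] * (new - old)
      lig_planted <- c(lig_planted, pi_$ib)
    }
    if (length(lig_planted)) {
      rest <- setdiff(lig_idx, lig_planted)
      fx[rest, ] <- sweep(fx[rest, , drop = FALSE], 2,
                          -total_shift / sum(mass[rest]), `+`)
    }
    frames[[f]] <- fx
    for (k in seq_along(plants)) {
      p <- plants[[k]]
      truth[[length(truth) + 1]] <- data.frame(
        frame = f, kind = p$kind,
        chainA = p$a$chain, residA = p$a$resid, atomA = p$a$atom,
        chainB = p$b$chain, residB = p$b$resid, atomB = p$b$atom,
        present = f %in% p$frames)
    }
  }
  topo <- new_structure(atoms, frames[[1]], title = "synthetic complex")
  list(traj = new_trajectory(topo, frames),
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

# target position for the moved plant atom in frame f
.plant_position <- function(fx, pi_, p, f, rec_idx, mass) {
  anchor <- fx[pi_$ia, ]
  d <- if (f %in% p$frames) .PLANT_DIST[[p$kind]]
       else .PLANT_CUTOFF[[p$kind]] + 1.5
  rec_com <- colSums(fx[rec_idx, , drop = FALSE] * mass[rec_idx]) /
    sum(mass[rec_idx])
  out_dir <- anchor - rec_com
  if (vnorm(out_dir) < 1e-6) out_dir <- c(0, 0, 1)
  anchor + unitize(out_dir) * d
}

# ligand templates: fragment carrying exactly the requested feature type,
# feature centroid at the origin; extra co-located features listed in truth
.TEMPLATES <- list(
  HAc = function() new_pose(
    data.frame(element = c("O", "C", "C", "C"),
               x = c(0, 1.23, 2.0, 2.0),
               y = c(0, 0, 1.3, -1.3),
               z = 0, charge = 0L, aromatic = FALSE),
    data.frame(from = c(1, 2, 2), to = c(2, 3, 4), order = c(2, 1, 1))),
  HDn = function() new_pose(
    data.frame(element = c("N", "C"),
               x = c(0, 1.47), y = 0, z = 0, charge = 0L, aromatic = FALSE),
    data.frame(from = 1, to = 2, order = 1)),
  Arm = function() {
    th <- deg2rad(seq(0, 300, by = 60))
    new_pose(
      data.frame(element = "C", x = 1.39 * cos(th), y = 1.39 * sin(th),
                 z = 0, charge = 0L, aromatic = TRUE),
      data.frame(from = 1:6, to = c(2:6, 1), order = 4))
  },
  Hph = function() {
    x <- c(-1.9, -0.64, 0.64, 1.9); y <- c(0.4, -0.4, 0.4, -0.4)
    new_pose(
      data.frame(element = "C", x = x - mean(x), y = y - mean(y), z = 0,
                 charge = 0L, aromatic = FALSE),
      data.frame(from = 1:3, to = 2:4, order = 1))
  },
  PIn = function() new_pose(
    data.frame(element = c("N", "C"),
               x = c(0, 1.47), y = 0, z = 0,
               charge = c(1L, 0L), aromatic = FALSE),
    data.frame(from = 1, to = 2, order = 1)),
  NIn = function() new_pose(
    data.frame(element = c("O", "O", "C", "C"),
               x = c(0, 0, 0.6, 2.1), y = c(1.1, -1.1, 0, 0),
               z = 0, charge = c(0L, -1L, 0L, 0L), aromatic = FALSE),
    data.frame(from = c(3, 3, 3), to = c(1, 2, 4), order = c(2, 1, 1)))
)

# features each template carries (offsets from the planted centroid are 0)
.TEMPLATE_FEATURES <- list(
  HAc = "HAc", HDn = c("HDn", "HAc"), Arm = "Arm", Hph = "Hph",
  PIn = "PIn", NIn = "NIn")

#' Pose library with planted pharmacophoric clusters
#'
#' Each cluster contributes `n_members` ligands, each a small template
#' fragment carrying the requested feature type (carbonyl for HAc, amine for
#' HDn, benzene for Arm, alkyl chain for Hph, charged amine for PIn,
#' carboxylate for NIn). A ligand's reference placement is its cluster
#' centroid plus isotropic Gaussian scatter (sd = cluster sd) and a random
#' orientation; its poses are translational jitters (sd = `pose_jitter_sd`)
#' of the reference, plus optionally one decoy pose displaced by
#' `decoy_shift`. Deterministic given `seed`.
#'
#' @param clusters list of `list(type, centroid, sd, n_members)`
#' @param n_poses poses per ligand (before the decoy)
#' @param pose_jitter_sd translational pose jitter, Angstroms
#' @param decoy_shift displacement of one extra decoy pose per ligand
#'   (NULL = no decoy)
#' @param pki_range pKi range sampled uniformly per ligand
#' @param seed RNG seed
#' @return list(poses = `PoseSet`, truth = list(clusters, ligand_features,
#'   pose_truth))
#' @export
make_pose_library <- function(clusters, n_poses = 5, pose_jitter_sd = 0.3,
                              decoy_shift = NULL, pki_range = c(5, 9.7),
                              seed = 1) {
  set.seed(seed)
  for (cl in clusters) {
    if (!cl$type %in% .FEATURE_TYPES) stopf("unknown feature type '%s'", cl$type)
    if (is.null(cl$n_members) || cl$n_members < 1)
      stopf("n_members must be >= 1")
    if (cl$sd < 0) stopf("cluster sd must be >= 0")
  }
  ligs <- list(); lig_feats <- list(); cl_rows <- list(); pose_truth <- list()
  lig_no <- 0L
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    cen <- cl$centroid
    cl_rows[[ci]] <- data.frame(cluster = ci, type = cl$type,
                                x = cen[1], y = cen[2], z = cen[3],
                                sd = cl$sd, n_members = cl$n_members)
    for (m in seq_len(cl$n_members)) {
      lig_no <- lig_no + 1L
      id <- sprintf("LIG%03d", lig_no)
      tpl <- .TEMPLATES[[cl$type]]()
      ref_cen <- cen + stats::rnorm(3, sd = cl$sd)
      R <- random_rotation()
      base_xyz <- as.matrix(tpl$atoms[, c("x", "y", "z")]) %*% t(R)
      base_xyz <- sweep(base_xyz, 2, ref_cen, `+`)
      for (ft in .TEMPLATE_FEATURES[[cl$type]])
        lig_feats[[length(lig_feats) + 1]] <- data.frame(
          ligand = id, cluster = ci, type = ft,
          x = ref_cen[1], y = ref_cen[2], z = ref_cen[3])
      poses <- list()
      for (pp in seq_len(n_poses)) {
        shift <- stats::rnorm(3, sd = pose_jitter_sd)
        at <- tpl$atoms
        at[, c("x", "y", "z")] <- sweep(base_xyz, 2, shift, `+`)
        poses[[pp]] <- new_pose(at, tpl$bonds)
        pose_truth[[length(pose_truth) + 1]] <- data.frame(
          ligand = id, pose = pp, decoy = FALSE)
      }
      if (!is.null(decoy_shift)) {
        at <- tpl$atoms
        at[, c("x", "y", "z")] <- sweep(base_xyz, 2,
          unitize(stats::rnorm(3)) * decoy_shift, `+`)
        poses[[n_poses + 1]] <- new_pose(at, tpl$bonds)
        pose_truth[[length(pose_truth) + 1]] <- data.frame(
          ligand = id, pose = n_poses + 1L, decoy = TRUE)
      }
      ligs[[length(ligs) + 1]] <- list(
        id = id, pKi = stats::runif(1, pki_range[1], pki_range[2]),
        poses = poses)
    }
  }
  list(poses = new_pose_set(ligs),
       truth = list(clusters = do.call(rbind, cl_rows),
                    ligand_features = do.call(rbind, lig_feats),
                    pose_truth = do.call(rbind, pose_truth)))
}
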