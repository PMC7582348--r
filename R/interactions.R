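# Hydrogen-bond, hydrophobic-contact and salt-bridge detection; arginine-cage
# state; contact time-tables.
#
# Criteria follow the published conventions of the contact-enumeration tools
# common in the field (LigPlot-style H-bond/hydrophobic cutoffs, a 4 A
# charged-pair criterion for salt bridges); every cutoff is config-exposed.

#' Interaction criteria
#'
#' @param hbond_da_max donor-acceptor heavy-atom cutoff, Angstroms
#' @param hbond_angle_min D-H...A angle minimum, degrees; applied only when an
#'   explicit hydrogen is bonded to the donor (models without hydrogens fall
#'   back to the distance criterion alone)
#' @param hydrophobic_cc_max nonpolar carbon-carbon cutoff, Angstroms
#' @param saltbridge_max charged-group nitrogen-oxygen cutoff, Angstroms
#' @param his_positive treat His ND1/NE2 as positively charged (default FALSE;
#'   protonation is ambiguous)
#' @return list of class `InteractionCriteria`
#' @export
interaction_criteria <- function(hbond_da_max = 3.5, hbond_angle_min = 120,
                                 hydrophobic_cc_max = 3.9,
                                 saltbridge_max = 4.0,
                                 his_positive = FALSE) {
  stopifnot(hbond_da_max > 0, hydrophobic_cc_max > 0, saltbridge_max > 0)
  structure(list(hbond_da_max = hbond_da_max,
                 hbond_angle_min = hbond_angle_min,
                 hydrophobic_cc_max = hydrophobic_cc_max,
                 saltbridge_max = saltbridge_max,
                 his_positive = his_positive),
            class = "InteractionCriteria")
}

# charged-group atom tables (standard amino-acid chemistry)
.NEG_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.POS_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
.HIS_POS <- c("ND1", "NE2")

# name-inferred donor table: protein N/O sites that carry at least one H
.DONOR_SIDE <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2", ARG = c("NE", "NH1", "NH2"),
  LYS = "NZ", TRP = "NE1", HIS = c("ND1", "NE2")
)

.is_negative <- function(a) {
  (a$resname %in% names(.NEG_ATOMS) &
     mapply(function(rn, nm) nm %in% .NEG_ATOMS[[rn]], a$resname, a$name)) |
    a$name == "OXT"
}

.is_positive <- function(a, his_positive = FALSE) {
  pos <- a$resname %in% names(.POS_ATOMS) &
    mapply(function(rn, nm) nm %in% .POS_ATOMS[[rn]], a$resname, a$name)
  if (his_positive) pos <- pos | (a$resname == "HIS" & a$name %in% .HIS_POS)
  pos
}

.is_donor <- function(a, his_positive = FALSE) {
  side <- a$resname %in% names(.DONOR_SIDE) &
    mapply(function(rn, nm) nm %in% .DONOR_SIDE[[rn]], a$resname, a$name)
  backbone_n <- a$name == "N" & a$resname != "PRO"
  (side | backbone_n) & a$element %in% c("N", "O")
}

.is_acceptor <- function(a, his_positive = FALSE) {
  ox <- a$element == "O"
  his_n <- !his_positive & a$resname == "HIS" & a$name %in% .HIS_POS
  (ox | his_n) & !.is_positive(a, his_positive)
}

# nonpolar carbon: C with no N/O of the same residue within bond distance
.is_nonpolar_carbon <- function(a, xyz) {
  out <- rep(FALSE, nrow(a))
  cand <- which(a$element == "C" & !(a$name %in% c("C", "CA")))
  if (length(cand) == 0) {
    # CA-only / coarse-grained data: any C-typed site counts (documented)
    cand <- which(a$element == "C")
    out[cand] <- TRUE
    return(out)
  }
  no_atoms <- which(a$element %in% c("N", "O"))
  for (i in cand) {
    same_res <- no_atoms[a$chain[no_atoms] == a$chain[i] &
                         a$resid[no_atoms] == a$resid[i]]
    if (length(same_res) == 0) { out[i] <- TRUE; next }
    d2 <- rowSums((xyz[same_res, , drop = FALSE] -
                     matrix(xyz[i, ], length(same_res), 3, byrow = TRUE))^2)
    out[i] <- all(d2 > 1.75^2)
  }
  # pure CA traces (no side chains at all): fall back to every carbon
  if (!any(out) && all(a$name[a$element == "C"] %in% c("CA", "BB")))
    out[a$element == "C"] <- TRUE
  out
}

# pair enumeration within a cutoff between two index sets; returns data.frame
.pairs_within <- function(xyz, ia, ib, cutoff) {
  if (length(ia) == 0 || length(ib) == 0)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  A <- xyz[ia, , drop = FALSE]; B <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  data.frame(i = ia[hit[, 1]], j = ib[hit[, 2]],
             d = sqrt(pmax(0, d2[hit])))
}

.res_label <- function(a, idx)
  sprintf("%s:%s%d", a$chain[idx], a$resname[idx], a$resid[idx])

# canonical ordering of a record pair by (chain, resid, name)
.order_pair <- function(a, rec) {
  keyi <- sprintf("%s|%06d|%s", a$chain[rec$i], a$resid[rec$i], a$name[rec$i])
  keyj <- sprintf("%s|%06d|%s", a$chain[rec$j], a$resid[rec$j], a$name[rec$j])
  flip <- keyj < keyi
  tmp <- rec$i[flip]; rec$i[flip] <- rec$j[flip]; rec$j[flip] <- tmp
  rec
}

.records_df <- function(a, rec, kind, frame, angle = NA_real_) {
  if (nrow(rec) == 0)
    return(data.frame(frame = integer(0), kind = character(0),
                      chainA = character(0), residA = integer(0),
                      resnameA = character(0), atomA = character(0),
                      chainB = character(0), residB = integer(0),
                      resnameB = character(0), atomB = character(0),
                      distance_A = numeric(0), angle_deg = numeric(0)))
  data.frame(frame = frame, kind = kind,
             chainA = a$chain[rec$i], residA = a$resid[rec$i],
             resnameA = a$resname[rec$i], atomA = a$name[rec$i],
             chainB = a$chain[rec$j], residB = a$resid[rec$j],
             resnameB = a$resname[rec$j], atomB = a$name[rec$j],
             distance_A = rec$d, angle_deg = angle,
             stringsAsFactors = FALSE)
}

# resolve group selections to index vectors on a frame Structure
.resolve_groups <- function(s, groupA, groupB) {
  ia <- if (is.numeric(groupA)) as.integer(groupA) else select_atoms(s, groupA)
  ib <- if (is.numeric(groupB)) as.integer(groupB) else select_atoms(s, groupB)
  list(ia = ia, ib = ib)
}

#' Find hydrogen bonds in one frame
#'
#' Donors are N/O sites bearing a hydrogen (explicit, or name-inferred from
#' standard residue chemistry); acceptors are oxygens (and neutral His ring
#' nitrogens), never positively charged sites. A pair is reported when the
#' donor-acceptor distance is within `hbond_da_max`; when an explicit H is
#' bonded to the donor the D-H...A angle must also exceed `hbond_angle_min`.
#' Symmetric duplicates are removed. Oppositely charged donor/acceptor pairs
#' are the province of [find_salt_bridges()] and are not double-reported
#' here.
#'
#' @param s a `Structure` (one frame)
#' @param groupA,groupB selection expressions or index vectors; identical
#'   groups run in intra-molecular mode
#' @param criteria an [interaction_criteria()] object
#' @param frame frame index recorded in the output
#' @return record data.frame (one row per H-bond)
#' @export
find_hbonds <- function(s, groupA, groupB, criteria = interaction_criteria(),
                        frame = 1L) {
  a <- s$atoms; xyz <- s$coords
  g <- .resolve_groups(s, groupA, groupB)
  don <- .is_donor(a, criteria$his_positive)
  acc <- .is_acceptor(a, criteria$his_positive)
  recs <- rbind(
    .pairs_within(xyz, g$ia[don[g$ia]], g$ib[acc[g$ib]], criteria$hbond_da_max),
    .pairs_within(xyz, g$ib[don[g$ib]], g$ia[acc[g$ia]], criteria$hbond_da_max)
  )
  recs <- recs[a$element[recs$i] %in% c("N", "O") &
               !(a$chain[recs$i] == a$chain[recs$j] &
                 a$resid[recs$i] == a$resid[recs$j]), , drop = FALSE]
  # an oppositely charged donor/acceptor pair is classified as a salt
  # bridge, not reported again as a hydrogen bond
  if (nrow(recs)) {
    pos <- .is_positive(a, criteria$his_positive)
    neg <- .is_negative(a)
    charged <- (pos[recs$i] & neg[recs$j]) | (neg[recs$i] & pos[recs$j])
    recs <- recs[!charged, , drop = FALSE]
  }
  if (nrow(recs)) {
    # explicit-H angle criterion: only when the donor has a bonded H
    hs <- which(a$element == "H")
    if (length(hs)) {
      keep <- vapply(seq_len(nrow(recs)), function(k) {
        di <- recs$i[k]
        hb <- hs[a$chain[hs] == a$chain[di] & a$resid[hs] == a$resid[di]]
        hb <- hb[sqrt(rowSums((xyz[hb, , drop = FALSE] -
                  matrix(xyz[di, ], length(hb), 3, byrow = TRUE))^2)) < 1.25]
        if (length(hb) == 0) return(TRUE)
        angs <- vapply(hb, function(h) {
          v1 <- xyz[di, ] - xyz[h, ]; v2 <- xyz[recs$j[k], ] - xyz[h, ]
          rad2deg(acos(pmin(1, pmax(-1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))))
        }, numeric(1))
        any(angs >= criteria$hbond_angle_min)
      }, logical(1))
      recs <- recs[keep, , drop = FALSE]
    }
  }
  recs <- .order_pair(a, recs)
  recs <- recs[!duplicated(recs[c("i", "j")]), , drop = FALSE]
  .records_df(a, recs, "hbond", frame)
}

#' Find hydrophobic contacts in one frame
#'
#' Nonpolar carbons (no bonded N/O; carbonyl C and C-alpha excluded) within
#' `hydrophobic_cc_max` of each other, aggregated to one record per residue
#' pair keeping the minimum distance.
#'
#' @inheritParams find_hbonds
#' @return record data.frame (one row per residue pair)
#' @export
find_hydrophobic <- function(s, groupA, groupB,
                             criteria = interaction_criteria(), frame = 1L) {
  a <- s$atoms; xyz <- s$coords
  g <- .resolve_groups(s, groupA, groupB)
  np <- .is_nonpolar_carbon(a, xyz)
  recs <- .pairs_within(xyz, g$ia[np[g$ia]], g$ib[np[g$ib]],
                        criteria$hydrophobic_cc_max)
  recs <- recs[!(a$chain[recs$i] == a$chain[recs$j] &
                 a$resid[recs$i] == a$resid[recs$j]), , drop = FALSE]
  recs <- .order_pair(a, recs)
  if (nrow(recs)) {
    respair <- paste(.res_label(a, recs$i), .res_label(a, recs$j))
    recs <- do.call(rbind, lapply(split(recs, respair),
                                  function(x) x[which.min(x$d), ]))
  }
  .records_df(a, recs, "hydrophobic", frame)
}

#' Find salt bridges in one frame
#'
#' Any negative-group oxygen (Asp OD1/OD2, Glu OE1/OE2, C-terminal OXT)
#' within `saltbridge_max` of any positive-group nitrogen (Lys NZ, Arg
#' NH1/NH2/NE, optionally His ND1/NE2), one record per residue pair keeping
#' the minimum distance.
#'
#' @inheritParams find_hbonds
#' @return record data.frame (one row per residue pair)
#' @export
find_salt_bridges <- function(s, groupA, groupB,
                              criteria = interaction_criteria(), frame = 1L) {
  a <- s$atoms; xyz <- s$coords
  g <- .resolve_groups(s, groupA, groupB)
  neg <- .is_negative(a); pos <- .is_positive(a, criteria$his_positive)
  recs <- rbind(
    .pairs_within(xyz, g$ia[neg[g$ia]], g$ib[pos[g$ib]], criteria$saltbridge_max),
    .pairs_within(xyz, g$ib[neg[g$ib]], g$ia[pos[g$ia]], criteria$saltbridge_max)
  )
  recs <- recs[!(a$chain[recs$i] == a$chain[recs$j] &
                 a$resid[recs$i] == a$resid[recs$j]), , drop = FALSE]
  recs <- .order_pair(a, recs)
  if (nrow(recs)) {
    respair <- paste(.res_label(a, recs$i), .res_label(a, recs$j))
    recs <- do.call(rbind, lapply(split(recs, respair),
                                  function(x) x[which.min(x$d), ]))
    rownames(recs) <- NULL
  }
  .records_df(a, recs, "saltbridge", frame)
}

#' Arginine-cage presence per frame
#'
#' True in a frame iff a salt bridge is present between the two named
#' residues (default: the Asp-Arg pair of the DRY motif, residues 148-149).
#' Warns (and reports all-absent) when the residues are not an
#' acidic / basic pair.
#'
#' @param traj a `Trajectory`
#' @param d_res,r_res `list(chain =, resid =)` for the acidic and basic
#'   residue
#' @param criteria an [interaction_criteria()] object
#' @param stride sample every stride-th frame
#' @return data.frame(frame, present) of class `ArginineCageSeries`
#' @export
arginine_cage_state <- function(traj, d_res = list(chain = "R", resid = 148),
                                r_res = list(chain = "R", resid = 149),
                                criteria = interaction_criteria(),
                                stride = 1) {
  a <- traj$atoms
  id <- which(a$chain == d_res$chain & a$resid == d_res$resid)
  ir <- which(a$chain == r_res$chain & a$resid == r_res$resid)
  if (length(id) == 0 || length(ir) == 0)
    stopf("arginine-cage residues not found in topology")
  ok_types <- TRUE
  if (!any(a$resname[id] %in% c("ASP", "GLU"))) {
    warnf("residue %s%d is %s, not Asp/Glu", d_res$chain, d_res$resid,
          a$resname[id][1]); ok_types <- FALSE
  }
  if (!any(a$resname[ir] %in% c("ARG", "LYS"))) {
    warnf("residue %s%d is %s, not Arg/Lys", r_res$chain, r_res$resid,
          a$resname[ir][1]); ok_types <- FALSE
  }
  frames <- seq(1, n_frames(traj), by = max(1, stride))
  present <- vapply(frames, function(f) {
    if (!ok_types) return(FALSE)
    nrow(find_salt_bridges(get_frame(traj, f), id, ir, criteria, frame = f)) > 0
  }, logical(1))
  out <- data.frame(frame = frames, present = present)
  if (!is.null(traj$times)) out$time_ns <- traj$times[frames]
  class(out) <- c("ArginineCageSeries", "data.frame")
  out
}

#' Contact time-table over a trajectory
#'
#' Unions the three detectors per sampled frame. Interactions are named
#' `"kind:chainA:RES1-chainB:RES2"`; the wide table marks presence per frame,
#' and per-frame counts by kind are attached.
#'
#' @param traj a `Trajectory`
#' @param groupA,groupB selections
#' @param criteria an [interaction_criteria()] object
#' @param stride sample every stride-th frame (a stride larger than the
#'   trajectory keeps frame 1 only)
#' @return list(records, table = frame x interaction logical table, counts =
#'   per-frame counts by kind) of class `ContactTimetable`
#' @export
contact_timetable <- function(traj, groupA, groupB,
                              criteria = interaction_criteria(), stride = 1) {
  frames <- seq(1, n_frames(traj), by = max(1, stride))
  recs <- list()
  for (f in frames) {
    s <- get_frame(traj, f)
    recs[[length(recs) + 1]] <- rbind(
      find_hbonds(s, groupA, groupB, criteria, frame = f),
      find_hydrophobic(s, groupA, groupB, criteria, frame = f),
      find_salt_bridges(s, groupA, groupB, criteria, frame = f))
  }
  records <- do.call(rbind, recs)
  key <- if (nrow(records)) sprintf("%s:%s:%s%d-%s:%s%d", records$kind,
    records$chainA, records$resnameA, records$residA,
    records$chainB, records$resnameB, records$residB) else character(0)
  cols <- sort(unique(key))
  tab <- matrix(FALSE, length(frames), length(cols),
                dimnames = list(as.character(frames), cols))
  if (length(cols))
    for (k in seq_len(nrow(records)))
      tab[as.character(records$frame[k]), key[k]] <- TRUE
  counts <- data.frame(frame = frames)
  for (kd in c("hbond", "hydrophobic", "saltbridge"))
    counts[[kd]] <- vapply(frames, function(f)
      sum(records$frame == f & records$kind == kd), integer(1))
  counts$total <- counts$hbond + counts$hydrophobic + counts$saltbridge
  structure(list(records = records, table = tab, counts = counts),
            class = "ContactTimetable")
}

#' Write a presence table in the wide X/blank layout
#'
#' Rows are time frames, columns named interactions, cells "X" when present.
#'
#' @param tt a `ContactTimetable` or `ArginineCageSeries`
#' @param path output CSV path
#' @return invisibly, the path
#' @export
write_timetable_csv <- function(tt, path) {
  if (inherits(tt, "ArginineCageSeries")) {
    df <- data.frame(frame = tt$frame,
                     arginine_cage = ifelse(tt$present, "X", ""))
    if (!is.null(tt$time_ns)) df$time_ns <- tt$time_ns
  } else {
    m <- ifelse(tt$table, "X", "")
    df <- data.frame(frame = rownames(tt$table), m, check.names = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
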