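# Pharmacophoric feature typing, deterministic k-medoids (PAM), silhouette
# model selection, consensus model construction and comparison.
#
# Feature types: HAc (H-bond acceptor), HDn (H-bond donor), Arm (aromatic
# ring), Hph (hydrophobic group), PIn (positive ionisable), NIn (negative
# ionisable). "Nature" is enforced by clustering each type separately;
# "position" is the Euclidean centroid distance; "size" enters the metric as
# the absolute radius difference with weight lambda.

.FEATURE_TYPES <- c("HAc", "HDn", "Arm", "Hph", "PIn", "NIn")

#' Default feature radii (Angstroms)
#' @return named numeric vector
#' @export
feature_radii_default <- function() {
  c(HAc = 1.0, HDn = 1.0, PIn = 1.0, NIn = 1.0, Arm = 1.5, Hph = 1.5)
}

# adjacency list from a bond table
.adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$from[k]; j <- bonds$to[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# smallest ring through each aromatic bond: shortest path in graph minus edge
.aromatic_rings <- function(atoms, bonds) {
  arom_b <- which(bonds$order == 4 |
                  (atoms$aromatic[bonds$from] & atoms$aromatic[bonds$to]))
  if (length(arom_b) == 0) return(list())
  n <- nrow(atoms)
  rings <- list()
  for (bi in arom_b) {
    src <- bonds$from[bi]; dst <- bonds$to[bi]
    # BFS from src to dst avoiding the direct edge, aromatic atoms only
    adj <- .adjacency(n, bonds[-bi, , drop = FALSE])
    prev <- rep(NA_integer_, n)
    seen <- rep(FALSE, n); seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (!seen[v] && atoms$aromatic[v]) {
          seen[v] <- TRUE; prev[v] <- u
          if (v == dst) { queue <- integer(0); break }
          queue <- c(queue, v)
        }
      }
    }
    if (!seen[dst]) next
    ring <- dst
    while (!is.na(prev[ring[1]])) ring <- c(prev[ring[1]], ring)
    if (length(ring) >= 3) rings[[length(rings) + 1]] <- sort(ring)
  }
  unique(rings)
}

# implicit hydrogen count from standard valence (N: 3 + charge, O: 2 + charge)
.implicit_h <- function(atoms, bonds, i) {
  base <- switch(atoms$element[i], N = 3, O = 2, C = 4, S = 2, 0)
  target <- base + if (atoms$element[i] %in% c("N", "O")) atoms$charge[i] else 0
  ord <- bonds$order[bonds$from == i | bonds$to == i]
  ord[ord == 4] <- 1.5
  max(0, round(target - sum(ord)))
}

#' Extract typed pharmacophoric features from one pose
#'
#' Rules: HAc = N/O with an available lone pair, not positively charged, not
#' an amide nitrogen; HDn = N/O bearing at least one hydrogen (explicit or
#' implied by valence); PIn = protonatable amine / guanidinium / amidinium
#' group or formal charge > 0 (one feature per group at the charged-atom
#' centroid); NIn = carboxylate / sulfonate / phosphate oxygens or formal
#' charge < 0 (feature at the oxygen-set centroid); Arm = centroid of each
#' smallest aromatic ring; Hph = centroid of each connected set of >= 3
#' nonpolar, non-aromatic carbons. Atoms consumed by a charged group are not
#' re-typed as HAc/HDn.
#'
#' @param pose a `LigandPose`
#' @param radii named radii per type (default [feature_radii_default()])
#' @return data.frame(type, x, y, z, radius, atoms) - `atoms` is a
#'   comma-separated atom-index list
#' @export
extract_features <- function(pose, radii = feature_radii_default()) {
  a <- pose$atoms; b <- pose$bonds
  n <- nrow(a)
  adj <- .adjacency(n, b)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  feats <- list()
  add <- function(type, idx) {
    cen <- colMeans(xyz[idx, , drop = FALSE])
    feats[[length(feats) + 1]] <<- data.frame(
      type = type, x = cen[1], y = cen[2], z = cen[3],
      radius = unname(radii[type]),
      atoms = paste(idx, collapse = ","), stringsAsFactors = FALSE)
  }

  charged_members <- integer(0)

  # NIn: oxy-anion groups (carboxylate/sulfonate/phosphate) or charge < 0
  for (i in which(a$element %in% c("C", "S", "P"))) {
    os <- adj[[i]][a$element[adj[[i]]] == "O"]
    if (length(os) >= 2 && any(a$charge[os] < 0)) {
      add("NIn", os)
      charged_members <- c(charged_members, i, os)
    }
  }
  for (i in which(a$charge < 0)) {
    if (i %in% charged_members) next
    add("NIn", i)
    charged_members <- c(charged_members, i)
  }

  # PIn: guanidinium/amidinium (C bonded to >=2 N, one charged) or N+ amine
  for (i in which(a$element == "C")) {
    ns <- adj[[i]][a$element[adj[[i]]] == "N"]
    if (length(ns) >= 2 && any(a$charge[ns] > 0)) {
      add("PIn", i)
      charged_members <- c(charged_members, i, ns)
    }
  }
  for (i in which(a$charge > 0)) {
    if (i %in% charged_members) next
    add("PIn", i)
    charged_members <- c(charged_members, i)
  }

  # amide nitrogens: N bonded to a carbonyl carbon
  amide_n <- vapply(seq_len(n), function(i) {
    if (a$element[i] != "N") return(FALSE)
    any(vapply(adj[[i]], function(c_) {
      if (a$element[c_] != "C") return(FALSE)
      dbl_o <- b$order == 2 &
        ((b$from == c_ & a$element[b$to] == "O") |
         (b$to == c_ & a$element[b$from] == "O"))
      any(dbl_o)
    }, logical(1)))
  }, logical(1))

  for (i in setdiff(which(a$element %in% c("N", "O")), charged_members)) {
    hac <- !amide_n[i] && a$charge[i] <= 0
    if (hac) add("HAc", i)
    if (.implicit_h(a, b, i) >= 1 ||
        any(a$element[adj[[i]]] == "H")) add("HDn", i)
  }

  for (ring in .aromatic_rings(a, b)) add("Arm", ring)

  # Hph: connected components of nonpolar, non-aromatic carbons, size >= 3
  nonpolar <- vapply(seq_len(n), function(i)
    a$element[i] == "C" && !a$aromatic[i] &&
      !any(a$element[adj[[i]]] %in% c("N", "O")), logical(1))
  comp <- rep(0L, n); cid <- 0L
  for (i in which(nonpolar)) {
    if (comp[i] > 0) next
    cid <- cid + 1L
    queue <- i; comp[i] <- cid
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (nonpolar[v] && comp[v] == 0) {
        comp[v] <- cid; queue <- c(queue, v)
      }
    }
  }
  for (k in seq_len(cid)) {
    idx <- which(comp == k)
    if (length(idx) >= 3) add("Hph", idx)
  }

  if (length(feats) == 0)
    return(data.frame(type = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), radius = numeric(0),
                      atoms = character(0)))
  out <- do.call(rbind, feats)
  rownames(out) <- NULL
  out
}

# distance between features: Euclidean position + lambda * |radius diff|
.feature_dist_matrix <- function(pos, rad, lambda = 1.0) {
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  d + lambda * abs(outer(rad, rad, `-`))
}

#' Deterministic PAM (partition around medoids)
#'
#' BUILD: greedily add the medoid giving the largest cost reduction (first
#' medoid minimises total distance). SWAP: repeatedly apply the single best
#' cost-reducing (medoid, non-medoid) swap until a local optimum. All ties
#' break to the lowest index, making the result deterministic.
#'
#' @param dmat symmetric distance matrix
#' @param k number of medoids (1 <= k <= n)
#' @return list(medoids, assignment, cost, trace = cost after each SWAP step)
#' @export
pam_kmedoids <- function(dmat, k) {
  m <- unclass(as.matrix(dmat))
  n <- nrow(m)
  if (k < 1 || k > n) stopf("k must be in [1, %d]", n)
  cost_of <- function(med) sum(apply(m[, med, drop = FALSE], 1, min))

  # BUILD
  medoids <- unname(which.min(colSums(m))[1])
  while (length(medoids) < k) {
    best <- NULL; best_cost <- Inf
    for (c_ in setdiff(seq_len(n), medoids)) {
      cc <- cost_of(c(medoids, c_))
      if (cc < best_cost - 1e-12) { best_cost <- cc; best <- c_ }
    }
    medoids <- c(medoids, best)
  }
  cost <- cost_of(medoids)
  trace <- cost

  # SWAP
  repeat {
    best_cost <- cost; best_swap <- NULL
    for (mi in seq_along(medoids)) {
      for (c_ in setdiff(seq_len(n), medoids)) {
        cand <- medoids; cand[mi] <- c_
        cc <- cost_of(cand)
        if (cc < best_cost - 1e-12) { best_cost <- cc; best_swap <- c(mi, c_) }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
    cost <- best_cost
    trace <- c(trace, cost)
  }
  medoids <- sort(unname(medoids))
  assignment <- unname(apply(m[, medoids, drop = FALSE], 1, which.min))
  list(medoids = medoids, assignment = as.integer(assignment),
       cost = cost_of(medoids), trace = trace)
}

# mean silhouette width from a distance matrix and an assignment
.mean_silhouette <- function(m, assignment) {
  n <- nrow(m)
  ks <- sort(unique(assignment))
  if (length(ks) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignment == assignment[i])
    a_i <- if (length(own) == 1) 0 else mean(m[i, setdiff(own, i)])
    b_i <- min(vapply(setdiff(ks, assignment[i]), function(kk)
      mean(m[i, assignment == kk]), numeric(1)))
    s[i] <- if (length(own) == 1) 0 else (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

#' Choose k for PAM by mean silhouette
#'
#' Runs [pam_kmedoids()] for each k in range and returns the k with the
#' highest mean silhouette width (ties to the smallest k). Falls back to
#' k = 1 when fewer than 4 points make silhouette selection meaningless, or
#' when the best silhouette is below `min_sil` (default 0.7, the
#' strong-structure bound of Kaufman & Rousseeuw): splitting a single
#' Gaussian blob rarely exceeds ~0.6 while genuinely separated feature
#' clusters score >= ~0.85 even at 10 sigma separation, so the rule prefers a
#' false merge over a false split -- the right bias for consensus elements.
#'
#' @param dmat distance matrix
#' @param k_range candidate k values (clipped to [2, n-1])
#' @param min_sil silhouette below which no cluster structure is declared
#' @return chosen k
#' @export
choose_k <- function(dmat, k_range = 2:8, min_sil = 0.7) {
  m <- unclass(as.matrix(dmat))
  n <- nrow(m)
  if (n < 2) stopf("choose_k needs at least 2 points")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (n < 4 || length(k_range) == 0) return(1L)
  sil <- vapply(k_range, function(k)
    .mean_silhouette(m, pam_kmedoids(m, k)$assignment), numeric(1))
  if (max(sil) < min_sil) return(1L)
  k_range[which.max(sil)]
}

#' Build the consensus protein-ligand interaction model
#'
#' Pipeline: representative pose per ligand -> [extract_features()] ->
#' per-type PAM with [choose_k()] -> elements (centroid, radius = medoid
#' radius plus cluster spatial spread, support = number of distinct
#' contributing ligands) -> drop support below `min_support` -> annotate each
#' element with the receptor residues having any atom within
#' `annotation_radius`.
#'
#' @param poses a `PoseSet`
#' @param receptor a `Structure` (or `Trajectory`; first frame used)
#' @param representatives optional named pose indices from [pose_cluster()];
#'   computed at `pose_cutoff` when missing
#' @param pose_cutoff RMSD cutoff for pose clustering (default 2 Angstroms)
#' @param min_support minimum number of contributing ligands (default 10% of
#'   ligands, at least 1)
#' @param annotation_radius residue annotation radius (default 5 Angstroms)
#' @param lambda weight of the radius-difference term in the feature metric
#' @param k_range candidate cluster counts per feature type
#' @return list(elements = data.frame(type, x, y, z, radius, support,
#'   residues), features, k_by_type) of class `ConsensusModel`
#' @export
build_consensus <- function(poses, receptor, representatives = NULL,
                            pose_cutoff = 2.0, min_support = NULL,
                            annotation_radius = 5.0, lambda = 1.0,
                            k_range = 2:8) {
  stopifnot(inherits(poses, "PoseSet"))
  if (length(poses$ligands) == 0) stopf("empty library: no ligands")
  rec <- if (inherits(receptor, "Trajectory")) get_frame(receptor, 1) else receptor
  if (is.null(rec)) stopf("a receptor structure is required")
  if (is.null(representatives)) {
    pc <- pose_cluster(poses, rmsd_cutoff = pose_cutoff)
    representatives <- vapply(pc, function(x) x$representative, integer(1))
  }
  n_lig <- length(poses$ligands)
  if (is.null(min_support)) min_support <- max(1, ceiling(0.1 * n_lig))

  feats <- do.call(rbind, lapply(names(poses$ligands), function(id) {
    f <- extract_features(poses$ligands[[id]]$poses[[representatives[[id]]]])
    if (nrow(f)) f$ligand <- id
    f
  }))
  if (is.null(feats) || nrow(feats) == 0)
    return(structure(list(elements = .empty_elements(), features = feats,
                          k_by_type = integer(0)), class = "ConsensusModel"))

  elements <- list(); k_by_type <- integer(0)
  for (tp in intersect(.FEATURE_TYPES, unique(feats$type))) {
    ft <- feats[feats$type == tp, , drop = FALSE]
    pos <- as.matrix(ft[, c("x", "y", "z")])
    if (nrow(ft) == 1) {
      asg <- 1L; meds <- 1L; kk <- 1L
    } else {
      dm <- .feature_dist_matrix(pos, ft$radius, lambda)
      kk <- choose_k(dm, k_range)
      fit <- pam_kmedoids(dm, kk)
      asg <- fit$assignment; meds <- fit$medoids
    }
    k_by_type[tp] <- kk
    for (cl in seq_along(meds)) {
      mem <- which(asg == cl)
      cen <- colMeans(pos[mem, , drop = FALSE])
      spread <- if (length(mem) > 1)
        sqrt(mean(rowSums(sweep(pos[mem, , drop = FALSE], 2, cen)^2))) else 0
      elements[[length(elements) + 1]] <- data.frame(
        type = tp, x = cen[1], y = cen[2], z = cen[3],
        radius = ft$radius[meds[cl]] + spread,
        support = length(unique(ft$ligand[mem])),
        stringsAsFactors = FALSE)
    }
  }
  el <- do.call(rbind, elements)
  el <- el[el$support >= min_support, , drop = FALSE]
  if (nrow(el) == 0)
    warnf("no consensus element reaches min_support = %d", min_support)
  el <- el[order(-el$support, el$type), , drop = FALSE]
  rownames(el) <- NULL

  # 5-A receptor-residue annotation
  el$residues <- vapply(seq_len(nrow(el)), function(i) {
    p <- c(el$x[i], el$y[i], el$z[i])
    d <- sqrt(rowSums(sweep(rec$coords, 2, p)^2))
    hit <- d <= annotation_radius
    if (!any(hit)) return("")
    res <- unique(sprintf("%s%d", .aa1(rec$atoms$resname[hit]),
                          rec$atoms$resid[hit]))
    paste(res[order(unique(rec$atoms$resid[hit]))], collapse = ", ")
  }, character(1))

  structure(list(elements = el, features = feats, k_by_type = k_by_type,
                 min_support = min_support,
                 annotation_radius = annotation_radius),
            class = "ConsensusModel")
}

.empty_elements <- function()
  data.frame(type = character(0), x = numeric(0), y = numeric(0),
             z = numeric(0), radius = numeric(0), support = integer(0),
             residues = character(0))

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.aa1 <- function(resname) {
  one <- .AA3TO1[toupper(resname)]
  ifelse(is.na(one), toupper(resname), one)
}

#' @export
print.ConsensusModel <- function(x, ...) {
  cat(sprintf("<ConsensusModel> %d elements (min_support %d, annotation %g A)\n",
              nrow(x$elements), x$min_support %||% NA,
              x$annotation_radius %||% NA))
  if (nrow(x$elements))
    print(x$elements[, c("type", "radius", "support", "residues")])
  invisible(x)
}

#' Compare two consensus models
#'
#' Greedy same-type nearest-centroid matching under `match_radius`.
#'
#' @param modelA,modelB `ConsensusModel`s
#' @param match_radius maximum centroid distance for a match (Angstroms)
#' @return list(matched = data.frame(type, shift_A, idxA, idxB),
#'   unmatched_A, unmatched_B)
#' @export
compare_models <- function(modelA, modelB, match_radius = 2.0) {
  ea <- modelA$elements; eb <- modelB$elements
  matched <- list()
  usedB <- rep(FALSE, nrow(eb))
  for (i in seq_len(nrow(ea))) {
    cand <- which(!usedB & eb$type == ea$type[i])
    if (length(cand) == 0) next
    d <- sqrt((eb$x[cand] - ea$x[i])^2 + (eb$y[cand] - ea$y[i])^2 +
              (eb$z[cand] - ea$z[i])^2)
    j <- cand[which.min(d)]
    if (min(d) <= match_radius) {
      matched[[length(matched) + 1]] <- data.frame(
        type = ea$type[i], shift_A = min(d), idxA = i, idxB = j)
      usedB[j] <- TRUE
    }
  }
  matched <- if (length(matched)) do.call(rbind, matched) else
    data.frame(type = character(0), shift_A = numeric(0),
               idxA = integer(0), idxB = integer(0))
  list(matched = matched,
       unmatched_A = setdiff(seq_len(nrow(ea)), matched$idxA),
       unmatched_B = setdiff(seq_len(nrow(eb)), matched$idxB))
}

#' Write a consensus model as the element -> residue table plus JSON
#'
#' The CSV mirrors the published layout: one row per pharmacophoric element
#' with its annotated residues within the annotation radius.
#'
#' @param model a `ConsensusModel`
#' @param csv_path,json_path output paths (either may be NULL)
#' @return invisibly, the model
#' @export
write_consensus <- function(model, csv_path = NULL, json_path = NULL) {
  el <- model$elements
  if (!is.null(csv_path)) {
    out <- data.frame(element_type = el$type,
                      centroid_x = el$x, centroid_y = el$y, centroid_z = el$z,
                      radius = el$radius, support = el$support,
                      residues_within_5A = el$residues)
    utils::write.csv(out, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(el, json_path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}
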