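# shared fixtures and independent oracles, built in code at test time

fix_bundle <- function(extended = FALSE) {
  seg <- tm_segments_default(extend_tm3 = extended, extend_tm5 = extended)
  make_tm_bundle(seg)
}

# small 2-helix bundle for cheap tests
fix_mini_bundle <- function() {
  seg <- validate_tm_segments(data.frame(
    tm = c("TM1", "TM2"), chain = "R",
    first = c(1, 30), last = c(12, 41)))
  make_tm_bundle(seg, circle_radius = 8)
}

# a tiny ad-hoc structure from atom spec rows: list(name, resname, resid,
# chain, element, x, y, z)
fix_structure <- function(...) {
  rows <- list(...)
  atoms <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(serial = i, name = r$name, resname = r$resname,
               chain = r$chain %||% "A", resid = r$resid,
               element = r$element %||% substr(r$name, 1, 1), het = FALSE)
  }))
  xyz <- do.call(rbind, lapply(rows, function(r) c(r$x, r$y, r$z)))
  new_structure(atoms, xyz)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# local rotation matrix (independent of the package's internals)
rot_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (u %o% u)
}

# random proper rigid motion applied to an n x 3 matrix
apply_rigid_test <- function(coords) {
  th <- stats::runif(3, -180, 180)
  R <- rot_axis(c(0, 0, 1), th[1]) %*% rot_axis(c(0, 1, 0), th[2]) %*%
    rot_axis(c(1, 0, 0), th[3])
  sweep(coords %*% t(R), 2, stats::runif(3, -30, 30), `+`)
}

# ---- independent oracles ------------------------------------------------

# literal restatement of the GROMOS greedy rule, written separately from the
# package implementation
oracle_gromos <- function(m, cutoff) {
  n <- nrow(m)
  unassigned <- seq_len(n)
  clusters <- list(); reps <- integer(0)
  while (length(unassigned) > 0) {
    best <- NA; best_n <- -1
    for (i in unassigned) {
      cnt <- 0
      for (j in unassigned) if (m[i, j] <= cutoff) cnt <- cnt + 1
      if (cnt > best_n) { best_n <- cnt; best <- i }  # first max = lowest label
    }
    memb <- unassigned[vapply(unassigned, function(j) m[best, j] <= cutoff,
                              logical(1))]
    clusters[[length(clusters) + 1]] <- memb
    reps <- c(reps, best)
    unassigned <- setdiff(unassigned, memb)
  }
  list(clusters = clusters, reps = reps)
}

# exhaustive PAM optimum over all medoid subsets
oracle_pam_cost <- function(m, k) {
  n <- nrow(m)
  combos <- utils::combn(n, k)
  best <- Inf
  for (c_ in seq_len(ncol(combos))) {
    med <- combos[, c_]
    cost <- sum(apply(m[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# grid-search rigid superposition oracle: Euler-angle scan with refinement,
# centroids matched exactly
oracle_grid_rmsd <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  rot <- function(a, b, c) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cc <- cos(c); sc <- sin(c)
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cc, -sc, 0, sc, cc, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  rmsd_at <- function(a, b, c) {
    sqrt(mean(rowSums((A %*% t(rot(a, b, c)) - B)^2)))
  }
  scan <- function(ctr, half, step) {
    best <- c(Inf, ctr)
    for (a in seq(ctr[1] - half, ctr[1] + half, by = step))
      for (b in seq(max(0, ctr[2] - half), min(pi, ctr[2] + half), by = step))
        for (c_ in seq(ctr[3] - half, ctr[3] + half, by = step)) {
          r <- rmsd_at(a, b, c_)
          if (r < best[1]) best <- c(r, a, b, c_)
        }
    best
  }
  b1 <- scan(c(pi, pi / 2, pi), pi, 8 * pi / 180)
  b2 <- scan(b1[2:4], 8 * pi / 180, pi / 180)
  b3 <- scan(b2[2:4], pi / 180, 0.1 * pi / 180)
  b3[1]
}

# plain-R mean silhouette, written independently of the package's
oracle_silhouette <- function(m, assignment) {
  n <- nrow(m)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(assignment == assignment[i]), i)
    if (length(same) == 0) { vals[i] <- 0; next }
    a <- mean(m[i, same])
    b <- Inf
    for (k in setdiff(unique(assignment), assignment[i]))
      b <- min(b, mean(m[i, assignment == k]))
    vals[i] <- (b - a) / max(a, b)
  }
  mean(vals)
}

# planted-cluster point set: k_true blobs (sd 0.4) with well-separated
# centers, the kind of data the consensus pipeline feeds PAM
clustered_points <- function(k_true, n_per, min_sep = 10, box = 40) {
  repeat {
    centers <- matrix(stats::runif(k_true * 3, 0, box), k_true, 3)
    if (k_true == 1 || min(dist(centers)) >= min_sep) break
  }
  do.call(rbind, lapply(seq_len(k_true), function(i)
    sweep(matrix(stats::rnorm(n_per[i] * 3, sd = 0.4), n_per[i], 3), 2,
          centers[i, ], `+`)))
}

# random symmetric distance matrix with zero diagonal
random_dmat <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
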