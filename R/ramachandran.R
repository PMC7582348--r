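# Backbone dihedrals and Ramachandran-region summaries.

# signed dihedral (degrees) of four points, IUPAC convention, in (-180, 180]
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitize(b2))
  wrap_angle(rad2deg(atan2(sum(m1 * n2), sum(n1 * n2))))
}

#' Backbone phi/psi dihedrals
#'
#' Residues missing any of N, CA, C are skipped with a warning; chain termini
#' without the needed neighbour are omitted.
#'
#' @param structure a `Structure` (or `Trajectory`; first frame used)
#' @param chain optional chain id restriction
#' @return data.frame(chain, resid, phi, psi); zero rows (with a warning) when
#'   no complete backbone exists
#' @export
phi_psi <- function(structure, chain = NULL) {
  s <- if (inherits(structure, "Trajectory")) get_frame(structure, 1) else structure
  a <- s$atoms
  keep <- if (is.null(chain)) rep(TRUE, nrow(a)) else a$chain %in% chain
  a <- a[keep, ]; xyz <- s$coords[keep, , drop = FALSE]
  out <- list()
  for (ch in unique(a$chain)) {
    in_ch <- a$chain == ch
    resids <- sort(unique(a$resid[in_ch]))
    bb <- function(resid, name) {
      i <- which(in_ch & a$resid == resid & a$name == name)
      if (length(i) != 1) return(NULL)
      xyz[i, ]
    }
    skipped <- FALSE
    for (k in seq_along(resids)) {
      r <- resids[k]
      N <- bb(r, "N"); CA <- bb(r, "CA"); C <- bb(r, "C")
      if (is.null(N) || is.null(CA) || is.null(C)) { skipped <- TRUE; next }
      phi <- psi <- NA_real_
      if (k > 1 && resids[k - 1] == r - 1) {
        Cprev <- bb(r - 1, "C")
        if (!is.null(Cprev)) phi <- dihedral_angle(Cprev, N, CA, C)
      }
      if (k < length(resids) && resids[k + 1] == r + 1) {
        Nnext <- bb(r + 1, "N")
        if (!is.null(Nnext)) psi <- dihedral_angle(N, CA, C, Nnext)
      }
      if (!is.na(phi) && !is.na(psi))
        out[[length(out) + 1]] <- data.frame(chain = ch, resid = r,
                                             phi = phi, psi = psi)
    }
    if (skipped)
      warnf("chain %s: residues missing backbone atoms were skipped", ch)
  }
  if (length(out) == 0) {
    warnf("no residues with a complete (phi, psi) pair")
    return(data.frame(chain = character(0), resid = integer(0),
                      phi = numeric(0), psi = numeric(0)))
  }
  do.call(rbind, out)
}

#' Default Ramachandran region map
#'
#' A coarse polygon map (favored alpha / beta / left-handed alpha cores with
#' allowed margins) shipped as JSON under `extdata`. It is comparable to, not
#' identical with, contour-based maps: absolute percentages from different
#' maps differ.
#'
#' @param path optional path to a user JSON region file with entries
#'   `{name, class, phi: [...], psi: [...]}`
#' @return list of regions (class `RamachandranRegionMap`)
#' @export
rama_region_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rama_regions.json", package = "gpcrtraj")
  regs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (r in regs) {
    stopifnot(all(c("name", "class", "phi", "psi") %in% names(r)))
    if (!r$class %in% c("favored", "allowed"))
      stopf("region class must be favored or allowed (outlier is the default)")
    if (length(r$phi) != length(r$psi) || length(r$phi) < 3)
      stopf("region '%s': polygon needs >=3 vertices", r$name)
  }
  structure(regs, class = "RamachandranRegionMap")
}

# point-in-polygon (even-odd rule), vertices as numeric vectors
.point_in_poly <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside <- !inside
    j <- i
  }
  inside
}

# classify one (phi, psi); wrap-around aware (checks +-360 images)
.rama_class <- function(phi, psi, map) {
  cls <- "outlier"
  for (r in map) {
    vx <- unlist(r$phi); vy <- unlist(r$psi)
    hit <- FALSE
    for (dx in c(-360, 0, 360)) for (dy in c(-360, 0, 360)) {
      if (.point_in_poly(phi + dx, psi + dy, vx, vy)) { hit <- TRUE; break }
    }
    if (hit) {
      if (r$class == "favored") return("favored")
      cls <- "allowed"
    }
  }
  cls
}

#' Ramachandran summary
#'
#' @param pp data.frame from [phi_psi()]
#' @param map region map from [rama_region_map()]
#' @return list(fractions = named percentages favored/allowed/outlier summing
#'   to 100, table = per-residue class table)
#' @export
ramachandran_summary <- function(pp, map = rama_region_map()) {
  if (nrow(pp) == 0) stopf("no residues with phi/psi to classify")
  cls <- vapply(seq_len(nrow(pp)),
                function(i) .rama_class(pp$phi[i], pp$psi[i], map),
                character(1))
  tab <- cbind(pp, class = cls)
  n <- nrow(pp)
  fr <- c(favored = 100 * sum(cls == "favored") / n,
          allowed = 100 * sum(cls == "allowed") / n,
          outlier = 100 * sum(cls == "outlier") / n)
  list(fractions = fr, table = tab)
}
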