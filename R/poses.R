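# Ligand poses: container and SDF (V2000) input-output.
#
# A pose is list(atoms = data.frame(element, x, y, z, charge, aromatic),
# bonds = data.frame(from, to, order)). A ligand groups poses sharing one
# atom ordering under an id (SDF name line) and carries an optional pKi.
# Aromatic bonds are stored with order 4 in SDF (common toolkit convention);
# on read they set the aromatic flag and count 1.5 toward valence.

#' Construct a ligand pose
#' @param atoms data.frame with element, x, y, z and optional charge, aromatic
#' @param bonds data.frame with from, to, order (may have zero rows)
#' @return list of class `LigandPose`
#' @export
new_pose <- function(atoms, bonds = data.frame(from = integer(0),
                                               to = integer(0),
                                               order = integer(0))) {
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  atoms$element <- toupper(atoms$element)
  n <- nrow(atoms)
  if (nrow(bonds) && (any(bonds$from < 1 | bonds$from > n |
                          bonds$to < 1 | bonds$to > n)))
    stopf("malformed molecule: dangling bond")
  if (nrow(bonds)) {
    arom <- bonds$order == 4
    atoms$aromatic[unique(c(bonds$from[arom], bonds$to[arom]))] <- TRUE
  }
  structure(list(atoms = atoms, bonds = bonds), class = "LigandPose")
}

#' Construct a pose set
#' @param ligands list of list(id, pKi, poses = list of `LigandPose`)
#' @return list of class `PoseSet`
#' @export
new_pose_set <- function(ligands) {
  for (lig in ligands) {
    stopifnot(!is.null(lig$id), length(lig$poses) >= 1)
    n0 <- nrow(lig$poses[[1]]$atoms)
    for (p in lig$poses)
      if (nrow(p$atoms) != n0)
        stopf("ligand %s: poses disagree on atom count", lig$id)
  }
  names(ligands) <- vapply(ligands, function(l) l$id, character(1))
  structure(list(ligands = ligands), class = "PoseSet")
}

#' Filter a pose set by pKi range
#' @param poses a `PoseSet`
#' @param min,max inclusive pKi bounds (defaults 5 and 9.7, the published
#'   antagonist range)
#' @return filtered `PoseSet`
#' @export
filter_pki <- function(poses, min = 5, max = 9.7) {
  keep <- vapply(poses$ligands, function(l)
    is.null(l$pKi) || is.na(l$pKi) || (l$pKi >= min && l$pKi <= max),
    logical(1))
  new_pose_set(poses$ligands[keep])
}

#' Write a PoseSet as a multi-record SDF
#'
#' One record per pose; records of one ligand share the name line. pKi and
#' pose_id are written as data fields.
#'
#' @param poses a `PoseSet`
#' @param path output path
#' @return invisibly, the path
#' @export
write_sdf <- function(poses, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (lig in poses$ligands) {
    for (pi in seq_along(lig$poses)) {
      p <- lig$poses[[pi]]
      a <- p$atoms; b <- p$bonds
      writeLines(c(lig$id, "  gpcrtraj", ""), con)
      writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         nrow(a), nrow(b)), con)
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         a$x, a$y, a$z, substr(a$element, 1, 1)), con)
      if (nrow(b))
        writeLines(sprintf("%3d%3d%3d  0", b$from, b$to, b$order), con)
      chg <- which(a$charge != 0)
      if (length(chg))
        writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                          paste0(sprintf("%4d%4d", chg, a$charge[chg]),
                                 collapse = "")), con)
      writeLines("M  END", con)
      writeLines(c("> <pose_id>", as.character(pi), ""), con)
      if (!is.null(lig$pKi) && !is.na(lig$pKi))
        writeLines(c("> <pKi>", format(lig$pKi), ""), con)
      writeLines("$$$$", con)
    }
  }
  invisible(path)
}

#' Read a multi-record SDF into a PoseSet
#'
#' Records sharing a name line are poses of one ligand.
#'
#' @param path SDF path
#' @return a `PoseSet`
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0) stopf("no SDF records in %s", path)
  start <- 1L
  ligs <- list()
  for (e in ends) {
    block <- lines[start:(e - 1)]
    start <- e + 1L
    if (length(block) < 4) next
    nm <- trimws(block[1])
    counts <- block[4]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    al <- block[5:(4 + na)]
    atoms <- data.frame(
      element = toupper(trimws(substr(al, 32, 34))),
      x = as.numeric(substr(al, 1, 10)),
      y = as.numeric(substr(al, 11, 20)),
      z = as.numeric(substr(al, 21, 30)),
      charge = 0L, aromatic = FALSE, stringsAsFactors = FALSE)
    bonds <- if (nb > 0) {
      bl <- block[(5 + na):(4 + na + nb)]
      data.frame(from = as.integer(substr(bl, 1, 3)),
                 to = as.integer(substr(bl, 4, 6)),
                 order = as.integer(substr(bl, 7, 9)))
    } else data.frame(from = integer(0), to = integer(0), order = integer(0))
    rest <- block[(5 + na + nb):length(block)]
    for (ln in rest[startsWith(rest, "M  CHG")]) {
      k <- as.integer(substr(ln, 7, 9))
      for (q in seq_len(k)) {
        off <- 10 + (q - 1) * 8
        ai <- as.integer(substr(ln, off, off + 3))
        atoms$charge[ai] <- as.integer(substr(ln, off + 4, off + 7))
      }
    }
    pki <- NA_real_
    tag <- grep("^>.*<pKi>", rest)
    if (length(tag)) pki <- as.numeric(trimws(rest[tag[1] + 1]))
    pose <- new_pose(atoms, bonds)
    if (is.null(ligs[[nm]]))
      ligs[[nm]] <- list(id = nm, pKi = pki, poses = list())
    ligs[[nm]]$poses <- c(ligs[[nm]]$poses, list(pose))
  }
  new_pose_set(unname(ligs))
}
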