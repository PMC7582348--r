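# Structure / Trajectory containers and PDB input-output.
#
# A Structure is a list(atoms = data.frame, coords = n x 3 matrix, title).
# The atom table carries: serial, name, altloc, resname, chain, resid,
# occupancy, bfactor, element, het (logical).
# A Trajectory shares one atom table (topology) across an ordered list of
# coordinate matrices; times (ns) are optional.

#' Construct a Structure
#'
#' @param atoms data.frame with columns serial, name, resname, chain, resid,
#'   element (plus optional altloc, occupancy, bfactor, het)
#' @param coords numeric matrix n_atoms x 3 (Angstroms)
#' @param title optional title string
#' @return object of class `Structure`
#' @export
new_structure <- function(atoms, coords, title = "") {
  coords <- as.matrix(coords)
  if (nrow(atoms) != nrow(coords) || ncol(coords) != 3)
    stopf("coords must be an n_atoms x 3 matrix matching the atom table")
  if (any(!is.finite(coords))) stopf("coordinates must be finite")
  defaults <- list(altloc = "", occupancy = 1, bfactor = 0, het = FALSE)
  for (nm in names(defaults)) if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  atoms$element <- toupper(trimws(as.character(atoms$element)))
  if (any(atoms$element == "")) stopf("every atom needs a non-empty element")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key))
    stopf("duplicate (chain, resid, name) atom: %s", key[anyDuplicated(key)])
  structure(list(atoms = atoms, coords = coords, title = title),
            class = "Structure")
}

#' Construct a Trajectory
#'
#' @param topology a `Structure` providing the shared atom table
#' @param frames list of n_atoms x 3 coordinate matrices
#' @param times optional numeric vector of frame times (ns), strictly increasing
#' @return object of class `Trajectory`
#' @export
new_trajectory <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "Structure"))
  n <- nrow(topology$atoms)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != n || ncol(f) != 3) stopf("inconsistent frame topology")
    f
  })
  if (length(frames) == 0) stopf("a Trajectory needs at least one frame")
  if (!is.null(times)) {
    if (length(times) != length(frames)) stopf("times length != n_frames")
    if (any(diff(times) <= 0)) stopf("frame times must be strictly increasing")
  }
  structure(list(atoms = topology$atoms, frames = frames, times = times,
                 title = topology$title), class = "Trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`
#' @return integer
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame of a trajectory as a Structure
#' @param traj a `Trajectory`
#' @param i frame index (1-based)
#' @return a `Structure`
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stopf("frame index %d out of range", i)
  structure(list(atoms = traj$atoms, coords = traj$frames[[i]],
                 title = traj$title), class = "Structure")
}

#' Promote a Structure to a 1-frame Trajectory
#' @param s a `Structure`
#' @return a `Trajectory`
#' @export
as_trajectory <- function(s) {
  if (inherits(s, "Trajectory")) return(s)
  new_trajectory(s, list(s$coords))
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<Structure> %d atoms, %d chains%s\n", nrow(x$atoms),
              length(unique(x$atoms$chain)),
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d frames x %d atoms%s\n", length(x$frames),
              nrow(x$atoms),
              if (is.null(x$times)) "" else
                sprintf(" (%.4g-%.4g ns)", x$times[1], x$times[length(x$times)])))
  invisible(x)
}

# element inference from the PDB atom-name field when columns 77-78 are blank
infer_element <- function(name) {
  nm <- toupper(trimws(name))
  # strip leading digits (e.g. "1HB", "2HG1")
  nm <- sub("^[0-9']+", "", nm)
  if (nm == "") return("X")
  two <- substr(nm, 1, 2)
  if (two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "CU", "SE"))
    return(two)
  substr(nm, 1, 1)
}

#' Read a PDB file into a Trajectory
#'
#' ATOM and HETATM records are kept; altloc other than blank or 'A' is
#' dropped. `MODEL`/`ENDMDL` delimit frames; a file without MODEL records is a
#' 1-frame trajectory. The element is taken from columns 77-78 when present,
#' otherwise inferred from the atom name. Every MODEL must repeat the atom
#' count of the first; a mismatch is an error, never silent truncation.
#' Insertion codes are unsupported and raise an error.
#'
#' @param path path to a PDB file
#' @return a `Trajectory`
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(lines, "MODEL")
  title <- ""
  tl <- lines[startsWith(lines, "TITLE")]
  if (length(tl)) title <- trimws(substr(tl[1], 11, nchar(tl[1])))

  # frame id per line: 0 before any MODEL (implicit single frame)
  frame_id <- cumsum(is_model)
  atom_lines <- lines[is_atom]
  atom_frames <- frame_id[is_atom]
  if (length(atom_lines) == 0) stopf("no ATOM/HETATM records in %s", path)
  if (all(atom_frames == 0)) atom_frames <- rep(1L, length(atom_lines))
  if (any(atom_frames == 0)) stopf("ATOM records found outside MODEL blocks")

  parse_block <- function(ls) {
    altloc <- substr(ls, 17, 17)
    keep <- altloc == " " | altloc == "A"
    ls <- ls[keep]
    icode <- trimws(substr(ls, 27, 27))
    if (any(nzchar(icode))) stopf("insertion codes are unsupported")
    elem <- toupper(trimws(substr(ls, 77, 78)))
    name <- trimws(substr(ls, 13, 16))
    missing_el <- elem == "" | is.na(elem)
    if (any(missing_el))
      elem[missing_el] <- vapply(name[missing_el], infer_element, character(1))
    data.frame(
      serial = as.integer(trimws(substr(ls, 7, 11))),
      name = name,
      altloc = "",
      resname = trimws(substr(ls, 18, 20)),
      chain = substr(ls, 22, 22),
      resid = as.integer(trimws(substr(ls, 23, 26))),
      occupancy = suppressWarnings(as.numeric(substr(ls, 55, 60))),
      bfactor = suppressWarnings(as.numeric(substr(ls, 61, 66))),
      element = elem,
      het = substr(ls, 1, 6) == "HETATM",
      stringsAsFactors = FALSE
    )
  }
  coords_of <- function(ls, keep) {
    ls <- ls[keep]
    cbind(as.numeric(substr(ls, 31, 38)),
          as.numeric(substr(ls, 39, 46)),
          as.numeric(substr(ls, 47, 54)))
  }

  ids <- sort(unique(atom_frames))
  first_lines <- atom_lines[atom_frames == ids[1]]
  first_keep <- substr(first_lines, 17, 17) %in% c(" ", "A")
  atoms <- parse_block(first_lines)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  frames <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    ls <- atom_lines[atom_frames == ids[k]]
    keep <- substr(ls, 17, 17) %in% c(" ", "A")
    if (sum(keep) != nrow(atoms)) stopf("inconsistent frame topology in MODEL %d", ids[k])
    frames[[k]] <- coords_of(ls, keep)
  }
  topo <- new_structure(atoms, frames[[1]], title = title)
  new_trajectory(topo, frames)
}

#' Write a Trajectory (or Structure) to a PDB file
#'
#' Multi-frame trajectories are written as MODEL/ENDMDL blocks. Round-trip
#' safe with [read_pdb()]: chains, residue numbers, atom names and
#' coordinates (3 decimals, PDB fixed width) are preserved.
#'
#' @param traj a `Trajectory` or `Structure`
#' @param path output path
#' @return invisibly, the path
#' @export
write_pdb <- function(traj, path) {
  traj <- as_trajectory(traj)
  if (nrow(traj$atoms) == 0) stopf("refusing to write an empty Trajectory")
  a <- traj$atoms
  rectype <- ifelse(a$het, "HETATM", "ATOM  ")
  # atom name column: names of length < 4 start in column 14
  name_fmt <- ifelse(nchar(a$name) >= 4, sprintf("%-4s", a$name),
                     sprintf(" %-3s", a$name))
  el <- sprintf("%2s", substr(a$element, 1, 2))
  multi <- n_frames(traj) > 1
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nzchar(traj$title)) writeLines(sprintf("TITLE     %s", traj$title), con)
  for (f in seq_len(n_frames(traj))) {
    if (multi) writeLines(sprintf("MODEL     %d", f), con)
    xyz <- traj$frames[[f]]
    writeLines(sprintf(
      "%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %s",
      rectype, a$serial %% 100000, name_fmt, a$resname, a$chain,
      a$resid %% 10000, xyz[, 1], xyz[, 2], xyz[, 3],
      a$occupancy, a$bfactor, el), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
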