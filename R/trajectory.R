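# Trajectory frames and dihedral specifications.
#
# Trajectories arrive as multi-frame XYZ (required) or single-model PDB
# (accepted, via bio3d). Coordinates are in Angstrom; atom indices are 0-based
# in all user-facing specifications, matching the convention of the record
# format.

#' Create a trajectory frame
#'
#' @param frame_index Integer frame number.
#' @param coordinates N x 3 numeric matrix of Cartesian coordinates, Angstrom.
#' @param atom_names Character vector of N atom labels.
#' @return An object of class `trajectory_frame`.
#' @export
trajectory_frame <- function(frame_index, coordinates, atom_names) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L)
    stop("coordinates must be an N x 3 matrix")
  if (nrow(coordinates) != length(atom_names))
    stop("coordinates and atom_names disagree on atom count")
  structure(list(frame_index = as.integer(frame_index),
                 coordinates = coordinates,
                 atom_names = as.character(atom_names)),
            class = "trajectory_frame")
}

#' Define a dihedral of interest
#'
#' @param name Label for the dihedral (e.g. `"azo"`, `"phenyl_1"`).
#' @param atom_indices Four distinct 0-based atom indices, in chain order.
#' @param role One of `"azo_EZ"` (the C-N=N-C torsion that defines the E/Z
#'   configuration), `"phenyl_inclination"` (ring torsion relative to the azo
#'   plane) or `"other"`.
#' @return An object of class `dihedral_spec`.
#' @export
dihedral_spec <- function(name, atom_indices,
                          role = c("other", "azo_EZ", "phenyl_inclination")) {
  role <- match.arg(role)
  atom_indices <- as.integer(atom_indices)
  if (length(atom_indices) != 4L || anyDuplicated(atom_indices) ||
      any(atom_indices < 0L))
    stop("atom_indices must be 4 distinct non-negative (0-based) indices")
  structure(list(name = as.character(name), atom_indices = atom_indices,
                 role = role),
            class = "dihedral_spec")
}

#' Read dihedral specifications from a YAML file
#'
#' The file holds a list of entries with fields `name`, `atoms` (four 0-based
#' indices) and optional `role`.
#'
#' @param path YAML file path.
#' @return List of `dihedral_spec` objects.
#' @export
read_dihedral_specs <- function(path) {
  entries <- yaml::read_yaml(path)
  lapply(entries, function(e)
    dihedral_spec(e$name, unlist(e$atoms),
                  role = if (is.null(e$role)) "other" else e$role))
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `name x y z` line per atom, repeated per frame. All frames must carry the
#' same atom count as declared on their own count line; a truncated or
#' malformed frame raises an error citing the frame index.
#'
#' @param path XYZ file path.
#' @return List of `trajectory_frame` objects in file order.
#' @export
read_xyz_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such trajectory file: ", path)
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  frames <- list()
  pos <- 1L
  fi <- 0L
  while (pos <= length(lines)) {
    fi <- fi + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n <= 0L)
      stop(sprintf("frame %d: expected an atom count at line %d", fi, pos))
    if (pos + 1L + n > length(lines))
      stop(sprintf("frame %d: truncated (need %d atom lines)", fi, n))
    body <- lines[(pos + 2L):(pos + 1L + n)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad))
      stop(sprintf("frame %d: malformed atom line %d", fi, bad[1]))
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop(sprintf("frame %d: non-numeric coordinates", fi))
    frames[[fi]] <- trajectory_frame(fi, xyz,
                                     vapply(toks, `[[`, character(1), 1L))
    pos <- pos + 2L + n
  }
  frames
}

#' Write a multi-frame XYZ trajectory
#'
#' @param frames List of `trajectory_frame` objects.
#' @param path Output path.
#' @param comment Comment-line text (recycled over frames).
#' @return The number of frames written, invisibly.
#' @export
write_xyz_trajectory <- function(frames, path, comment = "frame %d") {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(nrow(fr$coordinates)), con)
    writeLines(sprintf(comment, fr$frame_index), con)
    writeLines(sprintf("%-4s %14.8f %14.8f %14.8f", fr$atom_names,
                       fr$coordinates[, 1], fr$coordinates[, 2],
                       fr$coordinates[, 3]), con)
  }
  invisible(length(frames))
}

#' Read a single-model PDB file as one trajectory frame
#'
#' @param path PDB file path.
#' @return A one-element list holding a `trajectory_frame`.
#' @export
read_pdb_frame <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  list(trajectory_frame(1L, xyz, pdb$atom$elety))
}
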