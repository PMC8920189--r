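# Atom table columns shared by structures and trajectory topologies.
.atom_cols <- c("eleno", "elety", "resid", "chain", "resno", "insert",
                "occupancy", "bfactor", "element")

.check_atoms <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  missing <- setdiff(c("elety", "resid", "chain", "resno"), names(atoms))
  if (length(missing) > 0L)
    stop("atom table lacks required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(atoms) == 0L) stop("atom table is empty", call. = FALSE)
  if (any(!nzchar(atoms$elety))) stop("atom names must be non-empty", call. = FALSE)
  atoms$elety <- as.character(atoms$elety)
  atoms$resid <- as.character(atoms$resid)
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$bfactor)) atoms$bfactor <- 0
  if (is.null(atoms$element)) atoms$element <- .element_from_name(atoms$elety)
  atoms[, .atom_cols]
}

# Infer the element symbol from a PDB atom name (first alphabetic character,
# honouring two-letter names that start with a digit, e.g. "1HB").
.element_from_name <- function(elety) {
  nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety))
  toupper(substr(nm, 1L, 1L))
}

#' Construct a single-conformation structure
#'
#' A structure is an atom table plus one set of 3-D coordinates, the basic
#' unit every per-frame analysis (residue graphs, radius of gyration, pocket
#' volume) consumes.
#'
#' @param atoms data.frame with at least \code{elety} (PDB atom name),
#'   \code{resid} (3-letter residue code), \code{chain}, \code{resno}
#'   (integer residue number). Optional: \code{eleno}, \code{insert},
#'   \code{occupancy}, \code{bfactor}, \code{element}.
#' @param coords numeric matrix, \code{nrow(atoms)} x 3, coordinates in
#'   Angstrom. All values must be finite.
#' @param label free-text description.
#' @return An object of class \code{md_structure}.
#' @export
md_structure <- function(atoms, coords, label = "") {
  atoms <- .check_atoms(atoms)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != nrow(atoms))
    stop("coords must be an n_atoms x 3 matrix", call. = FALSE)
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords, label = label),
            class = "md_structure")
}

#' Construct a trajectory
#'
#' A trajectory is an ordered set of frames sharing one topology (atom
#' table), with a strictly increasing time index in nanoseconds. Frame
#' coordinates are stored in the flat \code{(x1, y1, z1, x2, ...)} layout,
#' one row per frame.
#'
#' @param atoms topology atom table (see [md_structure()]).
#' @param xyz numeric matrix, \code{n_frames} x \code{3 * n_atoms}.
#' @param times numeric vector of frame times in ns, strictly increasing.
#'   Defaults to \code{(0, 1, 2, ...) * dt} with \code{dt = 0.01} ns
#'   (a 10 ps stride).
#' @param label free-text description.
#' @return An object of class \code{md_trajectory}.
#' @export
md_trajectory <- function(atoms, xyz, times = NULL, label = "") {
  atoms <- .check_atoms(atoms)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz must have 3 * n_atoms columns", call. = FALSE)
  if (nrow(xyz) < 1L) stop("trajectory needs at least one frame", call. = FALSE)
  if (!all(is.finite(xyz))) stop("coordinates must be finite", call. = FALSE)
  if (is.null(times)) times <- (seq_len(nrow(xyz)) - 1L) * 0.01
  if (length(times) != nrow(xyz))
    stop("times must have one entry per frame", call. = FALSE)
  if (nrow(xyz) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz, times = as.numeric(times),
                 label = label),
            class = "md_trajectory")
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("md_structure: %d atoms, %d residues%s\n",
              nrow(x$atoms), n_residues(x),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms, %.4g-%.4g ns%s\n",
              n_frames(x), n_atoms(x), min(x$times), max(x$times),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an \code{md_trajectory}.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Number of atoms in a structure or trajectory
#' @param x an \code{md_structure} or \code{md_trajectory}.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Number of distinct residues
#' @param x an \code{md_structure} or \code{md_trajectory}.
#' @export
n_residues <- function(x) nrow(unique(x$atoms[, c("chain", "resno")]))

#' Extract one frame of a trajectory as a structure
#' @param traj an \code{md_trajectory}.
#' @param i frame index (1-based).
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range", call. = FALSE)
  md_structure(traj$atoms, frame_coords(traj, i),
               label = sprintf("%s frame %d", traj$label, i))
}

#' Coordinates of one frame as an n_atoms x 3 matrix
#' @inheritParams get_frame
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

# Flatten an n x 3 coordinate matrix into the row layout used by xyz.
.flatten_coords <- function(coords) as.numeric(t(coords))

#' Select atoms by chain, residue number and atom name
#'
#' Returns the indices (topology row numbers) of atoms matching all the
#' given filters. Resolution is deterministic: atoms are returned in
#' topology order.
#'
#' @param x an \code{md_structure} or \code{md_trajectory}.
#' @param chain,resno,elety optional filters; \code{NULL} means "any".
#' @param string alternatively, a selection string
#'   \code{"chain:resno"} or \code{"chain:resno:atom"} (chain may be empty).
#' @return integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(x, chain = NULL, resno = NULL, elety = NULL,
                         string = NULL) {
  at <- x$atoms
  if (!is.null(string)) {
    parts <- strsplit(string, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("selection string must be chain:resno[:atom]",
                                 call. = FALSE)
    chain <- if (nzchar(parts[1])) parts[1] else NULL
    resno <- as.integer(parts[2])
    if (length(parts) >= 3L) elety <- parts[3]
  }
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(elety)) keep <- keep & at$elety %in% elety
  which(keep)
}

#' Backbone heavy-atom indices
#'
#' Backbone heavy atoms are N, CA, C and O, the conventional set for
#' backbone RMSD and trajectory alignment.
#'
#' @inheritParams select_atoms
#' @export
backbone_indices <- function(x) {
  which(x$atoms$elety %in% c("N", "CA", "C", "O"))
}

#' Heavy-atom (non-hydrogen) indices
#' @inheritParams select_atoms
#' @export
heavy_indices <- function(x) {
  which(x$atoms$element != "H")
}

# Residue grouping: a factor over atoms, ordered by (chain, resno, insert)
# first appearance, plus a per-residue id table.
.residue_split <- function(atoms, indices = seq_len(nrow(atoms))) {
  at <- atoms[indices, , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  ukey <- unique(key)
  f <- factor(key, levels = ukey)
  first <- match(ukey, key)
  list(groups = split(indices, f),
       ids = data.frame(chain = at$chain[first], resno = at$resno[first],
                        resid = at$resid[first], stringsAsFactors = FALSE))
}
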