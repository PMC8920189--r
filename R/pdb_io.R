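# Multi-model PDB input/output. Parsing and writing are delegated to bio3d;
# the wrappers add the model-block validation and the error contract the
# rest of the package relies on (distinct, named conditions), plus the
# altloc policy: keep blank or 'A', drop the rest.

.hxk_error <- function(class, msg) {
  stop(structure(class = c(class, "hxkdyn_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Count ATOM/HETATM records inside each MODEL block (or in the whole file
# when no MODEL records are present). Used to diagnose inconsistent
# topologies before handing the file to the parser.
.scan_model_atom_counts <- function(lines) {
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0L) return(sum(is_atom))
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) < length(model_starts))
    model_ends <- c(model_ends, length(lines))
  vapply(seq_along(model_starts), function(k) {
    sum(is_atom[model_starts[k]:model_ends[k]])
  }, integer(1))
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' Each \code{MODEL}/\code{ENDMDL} block becomes one frame; a
#' single-conformation PDB yields a one-frame trajectory. Alternate
#' locations other than blank or \code{A} are dropped; insertion codes are
#' kept verbatim. Frame times default to \code{frame index * stride_ps}
#' because the PDB format carries no time metadata.
#'
#' @param path path to a PDB file.
#' @param stride_ps assumed time spacing between models, in picoseconds
#'   (default 10 ps, the analysis stride used throughout the package).
#' @param label free-text label; defaults to the file name.
#' @return An \code{md_trajectory}.
#' @section Errors: \code{hxkdyn_missing_file} if the file does not exist;
#'   \code{hxkdyn_inconsistent_models} if models differ in atom count;
#'   \code{hxkdyn_parse_error} if coordinate fields cannot be parsed.
#' @export
read_multimodel_pdb <- function(path, stride_ps = 10, label = basename(path)) {
  if (!file.exists(path))
    .hxk_error("hxkdyn_missing_file", paste("PDB file not found:", path))
  lines <- readLines(path, warn = FALSE)
  counts <- .scan_model_atom_counts(lines)
  if (length(unique(counts)) > 1L)
    .hxk_error("hxkdyn_inconsistent_models",
               sprintf("models differ in atom count: %s",
                       paste(unique(counts), collapse = ", ")))
  if (all(counts == 0L))
    .hxk_error("hxkdyn_parse_error", "file contains no ATOM/HETATM records")
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) .hxk_error("hxkdyn_parse_error",
                                   paste("PDB parse failure:", conditionMessage(e))))
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (!all(keep)) {
    cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                            3 * which(keep)))
    xyz <- xyz[, cols, drop = FALSE]
    at <- at[keep, , drop = FALSE]
  }
  if (!all(is.finite(xyz)))
    .hxk_error("hxkdyn_parse_error", "unparseable or missing coordinate fields")
  atoms <- data.frame(eleno = at$eleno, elety = at$elety, resid = at$resid,
                      chain = ifelse(is.na(at$chain), "", at$chain),
                      resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      occupancy = ifelse(is.na(at$o), 1, at$o),
                      bfactor = ifelse(is.na(at$b), 0, at$b),
                      element = .element_from_name(at$elety),
                      stringsAsFactors = FALSE)
  md_trajectory(atoms, xyz,
                times = (seq_len(nrow(xyz)) - 1L) * stride_ps / 1000,
                label = label)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Writes one \code{MODEL}/\code{ENDMDL} block per frame in fixed-column
#' PDB format (coordinates to 3 decimals). A round trip through
#' [read_multimodel_pdb()] preserves atom names, residue numbering and
#' coordinates to that precision.
#'
#' @param traj an \code{md_trajectory} (an \code{md_structure} is written
#'   as a single model).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  if (inherits(traj, "md_structure"))
    traj <- md_trajectory(traj$atoms, matrix(.flatten_coords(traj$coords),
                                             nrow = 1L),
                          label = traj$label)
  stopifnot(inherits(traj, "md_trajectory"))
  at <- traj$atoms
  # Atom-name field (cols 13-16): names shorter than 4 chars start in col 14.
  name4 <- ifelse(nchar(at$elety) >= 4L,
                  substr(at$elety, 1L, 4L),
                  formatC(paste0(" ", at$elety), width = -4L))
  chain1 <- substr(paste0(at$chain, " "), 1L, 1L)
  icode1 <- substr(paste0(at$insert, " "), 1L, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    lines <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$eleno %% 100000L, name4, at$resid, chain1, at$resno %% 10000L,
      icode1, xyz[, 1], xyz[, 2], xyz[, 3], at$occupancy, at$bfactor,
      at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
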