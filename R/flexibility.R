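# Per-residue flexibility: RMSF of residue centers of geometry, conversion
# to crystallographic-style B-factors, and the WT-vs-mutant difference map
# with its flexibility classification.

#' Per-residue RMSF of residue centers of geometry
#'
#' For each residue, the center of geometry of its heavy atoms is tracked
#' over the (already aligned) trajectory and the RMSF is the root mean
#' squared distance of that center from its time-average position.
#'
#' @param traj an aligned \code{md_trajectory} with at least 2 frames (see
#'   [align_trajectory()]).
#' @param selection atom indices restricting the analysis; defaults to all
#'   heavy atoms. Residues with no selected atom are omitted.
#' @return data.frame of class \code{rmsf_profile} with columns
#'   \code{chain}, \code{resno}, \code{resid}, \code{rmsf} (Angstrom).
#' @export
residue_rmsf <- function(traj, selection = heavy_indices(traj)) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames", call. = FALSE)
  if (length(selection) == 0L) stop("selection resolves to zero atoms",
                                    call. = FALSE)
  rs <- .residue_split(traj$atoms, selection)
  nf <- n_frames(traj)
  nr <- length(rs$groups)
  # cog[frame, residue, axis]
  cog <- array(NA_real_, c(nf, nr, 3L))
  for (f in seq_len(nf)) {
    crd <- frame_coords(traj, f)
    for (r in seq_len(nr)) {
      cog[f, r, ] <- colMeans(crd[rs$groups[[r]], , drop = FALSE])
    }
  }
  rmsf <- vapply(seq_len(nr), function(r) {
    dev <- sweep(cog[, r, , drop = FALSE], c(2L, 3L),
                 colMeans(cog[, r, , drop = FALSE], dims = 1L))
    sqrt(mean(rowSums(matrix(dev, nrow = nf)^2)))
  }, numeric(1))
  out <- cbind(rs$ids, rmsf = rmsf)
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Convert RMSF to a B-factor
#'
#' Uses the isotropic Debye-Waller relation B = (8 pi^2 / 3) RMSF^2,
#' reported in Angstrom^2.
#'
#' @param rmsf numeric vector of RMSF values (Angstrom), or an
#'   \code{rmsf_profile} whose \code{rmsf} column is used.
#' @return numeric vector of B-factors, or the profile with a
#'   \code{bfactor} column added.
#' @export
rmsf_to_bfactor <- function(rmsf) {
  if (inherits(rmsf, "rmsf_profile")) {
    rmsf$bfactor <- rmsf_to_bfactor(rmsf$rmsf)
    return(rmsf)
  }
  if (any(rmsf < 0)) stop("RMSF must be non-negative", call. = FALSE)
  (8 * pi^2 / 3) * rmsf^2
}

#' Per-residue RMSF difference between two systems
#'
#' Computes the signed difference delta = RMSF_ref - RMSF_other per residue
#' (reference first, e.g. WT minus mutant) and classifies each residue by
#' which system is more flexible: \code{"other-more-flexible"} when
#' RMSF_other - RMSF_ref >= threshold, \code{"ref-more-flexible"} when
#' RMSF_ref - RMSF_other >= threshold, else \code{"neutral"}.
#'
#' @param ref,other \code{rmsf_profile}s over identical residue lists
#'   (e.g. WT and mutant).
#' @param threshold classification threshold in Angstrom (default 0.85).
#' @return data.frame of class \code{delta_rmsf_profile} with columns
#'   \code{chain}, \code{resno}, \code{resid}, \code{delta}, \code{class}.
#' @export
delta_rmsf <- function(ref, other, threshold = 0.85) {
  if (!identical(ref[, c("chain", "resno")], other[, c("chain", "resno")]))
    stop("residue lists differ between profiles", call. = FALSE)
  delta <- ref$rmsf - other$rmsf
  cls <- ifelse(delta >= threshold, "ref-more-flexible",
                ifelse(-delta >= threshold, "other-more-flexible", "neutral"))
  out <- data.frame(chain = ref$chain, resno = ref$resno, resid = ref$resid,
                    delta = delta, class = cls, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("delta_rmsf_profile", "data.frame")
  out
}
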