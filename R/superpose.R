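# Rigid-body superposition (Kabsch), backbone RMSD time series and the
# equilibration trim/stride step that precedes every trajectory analysis.

#' Kabsch superposition of two coordinate sets
#'
#' Computes the proper rotation and translation that minimise the
#' least-squares deviation of \code{mobile} onto \code{reference}
#' (reflections are excluded by a sign correction on the smallest singular
#' value), together with the minimised RMSD.
#'
#' @param mobile,reference numeric n x 3 matrices with the same n >= 3.
#' @return list with \code{rotation} (3 x 3, determinant +1),
#'   \code{translation} (length-3), \code{rmsd} (Angstrom) and
#'   \code{fitted}, the transformed mobile coordinates
#'   (\code{fitted = (mobile - centroid) \%*\% rotation + translation'}).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be n x 3 matrices of equal size",
         call. = FALSE)
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 points", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2L, cm); B <- sweep(reference, 2L, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  fitted <- A %*% R
  rmsd <- sqrt(sum((fitted - B)^2) / n)
  fitted <- sweep(fitted, 2L, cr, "+")
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd,
       fitted = fitted)
}

#' Backbone RMSD time series against the first frame
#'
#' Each frame is superposed (on the selected atoms) to the reference frame
#' before the RMSD is measured, mirroring the per-simulation alignment used
#' for equilibration checks. The series is therefore 0 at the reference
#' frame and non-negative everywhere.
#'
#' @param traj an \code{md_trajectory}.
#' @param selection integer atom indices used both for fitting and RMSD;
#'   defaults to the backbone heavy atoms (N, CA, C, O).
#' @param reference_frame index of the reference frame (default 1).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_timeseries <- function(traj, selection = backbone_indices(traj),
                            reference_frame = 1L) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (length(selection) == 0L) stop("empty selection", call. = FALSE)
  ref <- frame_coords(traj, reference_frame)[selection, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(f) {
    kabsch_superpose(frame_coords(traj, f)[selection, , drop = FALSE],
                     ref)$rmsd
  }, numeric(1))
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' The rigid transform is fitted on \code{selection} (default backbone
#' heavy atoms) and applied to all atoms, yielding the aligned trajectory
#' that fluctuation and correlation analyses require.
#'
#' @inheritParams rmsd_timeseries
#' @return a new, aligned \code{md_trajectory}.
#' @export
align_trajectory <- function(traj, selection = backbone_indices(traj),
                             reference_frame = 1L) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (length(selection) == 0L) stop("empty selection", call. = FALSE)
  ref <- frame_coords(traj, reference_frame)[selection, , drop = FALSE]
  xyz <- traj$xyz
  for (f in seq_len(n_frames(traj))) {
    crd <- frame_coords(traj, f)
    fit <- kabsch_superpose(crd[selection, , drop = FALSE], ref)
    moved <- sweep(crd, 2L, colMeans(crd[selection, , drop = FALSE])) %*%
      fit$rotation
    moved <- sweep(moved, 2L, colMeans(ref), "+")
    xyz[f, ] <- .flatten_coords(moved)
  }
  md_trajectory(traj$atoms, xyz, traj$times, traj$label)
}

#' Discard the pre-equilibration segment and subsample frames
#'
#' Removes every frame with time strictly below \code{discard_ns}, then
#' keeps frames at (multiples of) the requested stride. The input
#' trajectory is untouched.
#'
#' @param traj an \code{md_trajectory}.
#' @param discard_ns initial segment to drop, in ns (default 5, the
#'   pre-equilibrated portion discarded before analysis).
#' @param stride_ps target frame spacing in ps (default 10). Must be a
#'   multiple of the trajectory's native spacing; frames are subsampled by
#'   the corresponding integer factor. \code{NULL} keeps the native spacing.
#' @return a new \code{md_trajectory}.
#' @export
trim_and_stride <- function(traj, discard_ns = 5, stride_ps = 10) {
  stopifnot(inherits(traj, "md_trajectory"))
  duration <- max(traj$times)
  if (discard_ns >= duration && discard_ns > 0)
    stop("discard_ns (", discard_ns, ") >= trajectory duration (", duration,
         " ns)", call. = FALSE)
  keep <- which(traj$times >= discard_ns)
  if (!is.null(stride_ps) && length(keep) > 1L) {
    dt_ps <- (traj$times[keep[2]] - traj$times[keep[1]]) * 1000
    k <- max(1L, as.integer(round(stride_ps / dt_ps)))
    keep <- keep[seq(1L, length(keep), by = k)]
  }
  md_trajectory(traj$atoms, traj$xyz[keep, , drop = FALSE],
                traj$times[keep], traj$label)
}
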