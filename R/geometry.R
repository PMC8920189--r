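# Geometric descriptors: radius of gyration (domain open/closed proxy),
# chi1 side-chain dihedrals with rotamer classification, residue-ligand
# minimum distances, and a grid-based cleft-volume estimate.

# Atomic masses (Da) for the elements found in protein heavy atoms plus
# hydrogen; unknown elements fall back to carbon.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974)

.masses_for <- function(element) {
  m <- .atomic_masses[element]
  m[is.na(m)] <- .atomic_masses[["C"]]
  unname(m)
}

#' Radius of gyration of one conformation
#'
#' RoG = sqrt( sum w_k |r_k - rbar|^2 / sum w_k ), with rbar the weighted
#' centroid. Weights are atomic masses by default (the convention of
#' standard trajectory-analysis libraries); pass
#' \code{mass_weighted = FALSE} for the geometric variant.
#'
#' @param frame an \code{md_structure}.
#' @param selection atom indices (default: all atoms).
#' @param mass_weighted logical (default \code{TRUE}).
#' @return RoG in Angstrom.
#' @export
radius_of_gyration <- function(frame, selection = seq_len(n_atoms(frame)),
                               mass_weighted = TRUE) {
  stopifnot(inherits(frame, "md_structure"))
  if (length(selection) == 0L) stop("empty selection", call. = FALSE)
  crd <- frame$coords[selection, , drop = FALSE]
  w <- if (mass_weighted) .masses_for(frame$atoms$element[selection])
       else rep(1, length(selection))
  ctr <- colSums(crd * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(crd, 2L, ctr)^2)) / sum(w))
}

#' Radius-of-gyration time series
#'
#' @param traj an \code{md_trajectory} (trim/stride beforehand as wanted).
#' @inheritParams radius_of_gyration
#' @return numeric vector, one RoG (Angstrom) per frame.
#' @export
rog_series <- function(traj, selection = seq_len(n_atoms(traj)),
                       mass_weighted = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (length(selection) == 0L) stop("empty selection", call. = FALSE)
  w <- if (mass_weighted) .masses_for(traj$atoms$element[selection])
       else rep(1, length(selection))
  vapply(seq_len(n_frames(traj)), function(f) {
    crd <- frame_coords(traj, f)[selection, , drop = FALSE]
    ctr <- colSums(crd * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(crd, 2L, ctr)^2)) / sum(w))
  }, numeric(1))
}

#' Signed dihedral angle of four points
#'
#' Standard torsion about the p2-p3 axis, in degrees in (-180, 180].
#' Invariant under rigid transforms; negates under mirror reflection.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Classify a chi1 angle into a rotamer bin
#'
#' Bins centered on the canonical rotamers: gauche- = [-120, 0),
#' gauche+ = [0, 120), anti = the remainder (|angle| >= 120).
#'
#' @param angle angle(s) in degrees, in (-180, 180].
#' @return character vector: \code{"gauche-"}, \code{"gauche+"} or
#'   \code{"anti"}.
#' @export
classify_rotamer <- function(angle) {
  ifelse(angle >= -120 & angle < 0, "gauche-",
         ifelse(angle >= 0 & angle < 120, "gauche+", "anti"))
}

#' Chi1 dihedral series of one residue
#'
#' The side-chain torsion tracked over a trajectory using a configurable
#' atom quartet. The default quartet is CG2-CB-CA-C (the convention used
#' for the valine open/closed rotamer analysis); the IUPAC chi1 quartet
#' N-CA-CB-CG1 is available via \code{quartet}.
#'
#' @param traj an \code{md_trajectory}.
#' @param resno residue number.
#' @param chain chain id (\code{NULL} = any unique match).
#' @param quartet four atom names defining the torsion, in order.
#' @return data.frame of class \code{dihedral_series}: \code{time_ns},
#'   \code{angle} (degrees, (-180, 180]), \code{rotamer}.
#' @export
chi1_series <- function(traj, resno, chain = NULL,
                        quartet = c("CG2", "CB", "CA", "C")) {
  stopifnot(inherits(traj, "md_trajectory"), length(quartet) == 4L)
  idx <- vapply(quartet, function(a) {
    hit <- select_atoms(traj, chain = chain, resno = resno, elety = a)
    if (length(hit) != 1L)
      stop("atom ", a, " not uniquely present in residue ", resno,
           call. = FALSE)
    hit
  }, integer(1))
  ang <- vapply(seq_len(n_frames(traj)), function(f) {
    crd <- frame_coords(traj, f)
    dihedral_angle(crd[idx[1], ], crd[idx[2], ], crd[idx[3], ], crd[idx[4], ])
  }, numeric(1))
  out <- data.frame(time_ns = traj$times, angle = ang,
                    rotamer = classify_rotamer(ang), stringsAsFactors = FALSE)
  class(out) <- c("dihedral_series", "data.frame")
  out
}

#' Minimum heavy-atom distance between a residue and a ligand
#'
#' @param structure an \code{md_structure}.
#' @param resno residue number (with optional \code{chain}).
#' @param ligand_coords numeric m x 3 matrix of ligand heavy-atom
#'   coordinates (e.g. a crystallographic sugar superposed into the frame).
#' @param chain chain id of the residue.
#' @return minimum distance in Angstrom.
#' @export
residue_ligand_distance <- function(structure, resno, ligand_coords,
                                    chain = NULL) {
  stopifnot(inherits(structure, "md_structure"))
  ligand_coords <- as.matrix(ligand_coords)
  if (nrow(ligand_coords) == 0L) stop("empty ligand atom set", call. = FALSE)
  idx <- select_atoms(structure, chain = chain, resno = resno)
  idx <- idx[structure$atoms$element[idx] != "H"]
  if (length(idx) == 0L) stop("residue ", resno, " not found", call. = FALSE)
  res <- structure$coords[idx, , drop = FALSE]
  d2 <- outer(rowSums(res^2), rowSums(ligand_coords^2), "+") -
    2 * res %*% t(ligand_coords)
  sqrt(max(0, min(d2)))
}

#' Pocket region specification
#'
#' A union of inclusion spheres plus the measurement grid spacing, the
#' minimal region description for grid-based cleft-volume estimates.
#'
#' @param centers numeric k x 3 matrix of sphere centers (Angstrom).
#' @param radii numeric vector of k sphere radii (> 0).
#' @param spacing grid spacing in Angstrom (> 0, default 0.5).
#' @return list of class \code{pocket_region}.
#' @export
pocket_region <- function(centers, radii, spacing = 0.5) {
  centers <- matrix(as.numeric(centers), ncol = 3L)
  if (length(radii) == 1L) radii <- rep(radii, nrow(centers))
  stopifnot(nrow(centers) == length(radii), all(radii > 0), spacing > 0)
  structure(list(centers = centers, radii = radii, spacing = spacing),
            class = "pocket_region")
}

#' Grid-based pocket (cleft) volume
#'
#' Counts regular grid points that fall inside at least one inclusion
#' sphere and farther than the exclusion radius from every protein heavy
#' atom; the volume is that count times spacing^3. This is a deliberately
#' simple grid estimate of an enclosed-cleft volume (no ligand-defined
#' regions or probe sweeps).
#'
#' @param frame an \code{md_structure} (its heavy atoms exclude grid
#'   points); pass \code{NULL} for a protein-free region.
#' @param region a \code{pocket_region}.
#' @param exclusion_radius uniform heavy-atom exclusion radius in Angstrom
#'   (default 1.09).
#' @return volume in Angstrom^3.
#' @export
pocket_volume <- function(frame, region, exclusion_radius = 1.09) {
  stopifnot(inherits(region, "pocket_region"))
  sp <- region$spacing
  lo <- apply(region$centers - region$radii, 2L, min)
  hi <- apply(region$centers + region$radii, 2L, max)
  axes <- lapply(1:3, function(k) seq(lo[k], hi[k], by = sp))
  grid <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  inside <- rep(FALSE, nrow(grid))
  for (k in seq_len(nrow(region$centers))) {
    d2 <- rowSums(sweep(grid, 2L, region$centers[k, ])^2)
    inside <- inside | d2 <= region$radii[k]^2
  }
  pts <- grid[inside, , drop = FALSE]
  if (!is.null(frame)) {
    stopifnot(inherits(frame, "md_structure"))
    atoms <- frame$coords[heavy_indices(frame), , drop = FALSE]
    if (nrow(atoms) > 0L && nrow(pts) > 0L) {
      free <- rep(TRUE, nrow(pts))
      r2 <- exclusion_radius^2
      # chunk the distance evaluation to bound memory
      chunk <- 20000L
      for (start in seq(1L, nrow(pts), by = chunk)) {
        sel <- start:min(start + chunk - 1L, nrow(pts))
        d2 <- outer(rowSums(pts[sel, , drop = FALSE]^2), rowSums(atoms^2), "+") -
          2 * pts[sel, , drop = FALSE] %*% t(atoms)
        free[sel] <- apply(d2, 1L, min) > r2
      }
      pts <- pts[free, , drop = FALSE]
    }
  }
  nrow(pts) * sp^3
}
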