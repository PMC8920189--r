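# Synthetic test-data generators. These produce inputs with exactly the
# statistical structure the analyses assume: equilibrium fluctuation
# ensembles with prescribed per-residue amplitudes and cross-residue
# correlations, two-domain hinge open/close trajectories with a controlled
# closure schedule, and tabular kinetics/growth data. All generators are
# pure functions of their arguments plus a seed.

#' Build a toy polypeptide structure
#'
#' An extended poly-alanine chain with explicit N, CA, C, O and CB atoms;
#' selected positions can be glycine (no CB, exercising the CA-node rule
#' of residue graphs) or valine (CB, CG1, CG2, exercising chi1 analyses).
#' Consecutive CB atoms are ~3.8 A apart, so the default residue graph at
#' a 6.7 A cutoff is a simple chain.
#'
#' @param n_res number of residues.
#' @param resno_start first residue number (default 1).
#' @param chain chain id (default "A").
#' @param glycine_at,valine_at residue numbers to build as GLY / VAL.
#' @param origin length-3 offset applied to all coordinates.
#' @param direction unit-ish length-3 vector for the chain axis (default
#'   +x); successive residues advance 3.8 A along it.
#' @return an \code{md_structure}.
#' @export
make_test_protein <- function(n_res = 10, resno_start = 1L, chain = "A",
                              glycine_at = integer(0), valine_at = integer(0),
                              origin = c(0, 0, 0), direction = c(1, 0, 0)) {
  stopifnot(n_res >= 1)
  direction <- direction / sqrt(sum(direction^2))
  # local atom offsets within one residue (non-degenerate side chain)
  offs <- list(N = c(0.00, 0.00, 0.0), CA = c(1.46, 1.00, 0.0),
               C = c(2.55, 0.00, 0.0), O = c(2.55, -1.23, 0.0),
               CB = c(1.46, 1.80, 1.2), CG1 = c(0.70, 2.90, 1.6),
               CG2 = c(2.30, 2.60, 2.0))
  # orthonormal frame with e1 = direction
  e1 <- direction
  ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  basis <- rbind(e1, e3, e2)  # local x along chain, y/z lateral
  rows <- list(); crds <- list()
  for (i in seq_len(n_res)) {
    resno <- resno_start + i - 1L
    resid <- if (resno %in% glycine_at) "GLY"
             else if (resno %in% valine_at) "VAL" else "ALA"
    names_i <- switch(resid,
                      GLY = c("N", "CA", "C", "O"),
                      VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
                      c("N", "CA", "C", "O", "CB"))
    for (a in names_i) {
      local <- offs[[a]] + c((i - 1L) * 3.8, 0, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        elety = a, resid = resid, chain = chain, resno = resno,
        stringsAsFactors = FALSE)
      crds[[length(crds) + 1L]] <- origin + as.numeric(local %*% basis)
    }
  }
  md_structure(do.call(rbind, rows), do.call(rbind, crds),
               label = sprintf("toy %d-residue chain", n_res))
}

# Symmetric PSD square root via eigendecomposition with an eigenvalue
# floor; errors if the matrix is materially non-PSD.
.psd_sqrt <- function(C, tol = 1e-8) {
  if (!isSymmetric(unname(C), tol = 1e-8))
    stop("correlation matrix must be symmetric", call. = FALSE)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -tol)
    stop("correlation matrix is not positive semi-definite (min eigenvalue ",
         signif(min(e$values), 3), ")", call. = FALSE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Generate a correlated-fluctuation trajectory
#'
#' Each residue moves as a rigid unit about its reference position with an
#' isotropic Gaussian displacement of per-axis standard deviation
#' \code{sigma[i]}; cross-residue correlations follow \code{corr} (applied
#' through its symmetric matrix square root, with independent drivers per
#' axis). Consequently the residue RMSF converges to \code{sigma * sqrt(3)}
#' and the empirical dynamic cross-correlation converges to \code{corr}
#' as frames grow. Identical seeds give bit-identical output.
#'
#' @param reference an \code{md_structure} supplying topology and mean
#'   positions.
#' @param sigma per-residue displacement SD per axis, Angstrom (scalar or
#'   one per residue; >= 0).
#' @param corr target residue-residue correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite); default identity.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param dt_ps frame spacing in ps (default 10).
#' @return an \code{md_trajectory} (frame 1 is not special; the ensemble
#'   is already aligned by construction).
#' @export
gen_fluctuation_trajectory <- function(reference, sigma, corr = NULL,
                                       n_frames = 1000L, seed = 1L,
                                       dt_ps = 10) {
  stopifnot(inherits(reference, "md_structure"), n_frames >= 1)
  rs <- .residue_split(reference$atoms)
  nr <- length(rs$groups)
  if (length(sigma) == 1L) sigma <- rep(sigma, nr)
  stopifnot(length(sigma) == nr, all(sigma >= 0))
  if (is.null(corr)) corr <- diag(nr)
  stopifnot(all(dim(corr) == nr))
  if (any(abs(diag(corr) - 1) > 1e-8))
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  L <- .psd_sqrt(corr)
  disp <- withr::with_seed(seed, {
    lapply(1:3, function(axis) {
      Z <- matrix(stats::rnorm(nr * n_frames), nr, n_frames)
      sigma * (L %*% Z)  # residues x frames, row-scaled by sigma
    })
  })
  na <- n_atoms(reference)
  res_of_atom <- integer(na)
  for (r in seq_len(nr)) res_of_atom[rs$groups[[r]]] <- r
  xyz <- matrix(0, n_frames, 3L * na)
  for (axis in 1:3) {
    # frames x atoms: reference coordinate plus the residue displacement
    xyz[, seq(axis, 3L * na, by = 3L)] <-
      t(disp[[axis]][res_of_atom, , drop = FALSE]) +
      matrix(reference$coords[, axis], n_frames, na, byrow = TRUE)
  }
  md_trajectory(reference$atoms, xyz,
                times = (seq_len(n_frames) - 1L) * dt_ps / 1000,
                label = "synthetic fluctuation ensemble")
}

# Rodrigues rotation of points (n x 3) about a unit axis by angle (deg).
.rotate_about_axis <- function(points, point_on_axis, axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(points, 2L, point_on_axis) %*% t(R), 2L, point_on_axis, "+")
}

#' Build a two-armed hinge test protein
#'
#' Two rigid poly-alanine arms joined at the origin: arm 1 along +x, arm 2
#' along +y, hinge axis +z. Rotating arm 2 by a positive closure angle
#' (with [gen_hinge_trajectory()]) swings it toward arm 1, so the radius
#' of gyration strictly decreases as the closure angle grows.
#'
#' @param arm_res residues per arm.
#' @return list with \code{structure} (an \code{md_structure}),
#'   \code{block1}, \code{block2} (residue numbers), \code{hinge_point},
#'   \code{hinge_axis}.
#' @export
make_hinge_protein <- function(arm_res = 8L) {
  s1 <- make_test_protein(arm_res, resno_start = 1L, origin = c(3.8, 0, 0),
                          direction = c(1, 0, 0))
  s2 <- make_test_protein(arm_res, resno_start = arm_res + 1L,
                          origin = c(0, 3.8, 0), direction = c(0, 1, 0))
  atoms <- rbind(s1$atoms, s2$atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  st <- md_structure(atoms, rbind(s1$coords, s2$coords),
                     label = "toy hinge protein")
  list(structure = st, block1 = 1:arm_res,
       block2 = (arm_res + 1L):(2L * arm_res),
       hinge_point = c(0, 0, 0), hinge_axis = c(0, 0, 1))
}

#' Generate a hinge open/close trajectory
#'
#' Block 2 is rotated rigidly about the hinge axis by the scheduled
#' closure angle in every frame (positive angles rotate block 2 toward
#' block 1 for the [make_hinge_protein()] geometry); optional isotropic
#' Gaussian jitter is added to every atom. With zero jitter, a strictly
#' increasing closure schedule gives a strictly decreasing
#' radius-of-gyration series; a bimodal schedule gives a bimodal RoG
#' distribution, emulating open/closed conformational ensembles.
#'
#' @param reference an \code{md_structure}.
#' @param block2 residue numbers of the mobile block.
#' @param hinge_point,hinge_axis point and direction of the hinge axis.
#' @param schedule_deg closure angle per frame, degrees.
#' @param block1 residue numbers of the fixed block (must be disjoint from
#'   \code{block2}; defaults to all other residues).
#' @param jitter_sd isotropic per-atom jitter SD, Angstrom (default 0).
#' @param seed RNG seed (used only when \code{jitter_sd > 0}).
#' @param dt_ps frame spacing in ps (default 10).
#' @return an \code{md_trajectory}.
#' @export
gen_hinge_trajectory <- function(reference, block2, hinge_point, hinge_axis,
                                 schedule_deg, block1 = NULL, jitter_sd = 0,
                                 seed = 1L, dt_ps = 10) {
  stopifnot(inherits(reference, "md_structure"), length(schedule_deg) >= 1)
  all_res <- unique(reference$atoms$resno)
  if (is.null(block1)) block1 <- setdiff(all_res, block2)
  if (length(intersect(block1, block2)) > 0L)
    stop("hinge blocks overlap", call. = FALSE)
  idx2 <- which(reference$atoms$resno %in% block2)
  if (length(idx2) == 0L) stop("block2 matches no atoms", call. = FALSE)
  nf <- length(schedule_deg)
  na <- n_atoms(reference)
  jit <- if (jitter_sd > 0) {
    withr::with_seed(seed, array(stats::rnorm(nf * na * 3, sd = jitter_sd),
                                 c(nf, na, 3L)))
  } else NULL
  xyz <- matrix(0, nf, 3L * na)
  for (f in seq_len(nf)) {
    crd <- reference$coords
    # negative angle about +z swings the +y arm toward the +x arm
    crd[idx2, ] <- .rotate_about_axis(crd[idx2, , drop = FALSE],
                                      hinge_point, hinge_axis,
                                      -schedule_deg[f])
    if (!is.null(jit)) crd <- crd + jit[f, , ]
    xyz[f, ] <- .flatten_coords(crd)
  }
  md_trajectory(reference$atoms, xyz,
                times = (seq_len(nf) - 1L) * dt_ps / 1000,
                label = "synthetic hinge trajectory")
}

#' Generate a synthetic (substrate, rate) kinetics table
#'
#' Rates follow the Michaelis-Menten curve with optional additive Gaussian
#' noise, clipped at zero.
#'
#' @param Km,Vmax generating parameters (> 0).
#' @param S substrate concentration grid, mM.
#' @param noise_sd additive rate noise SD (default 0).
#' @param seed RNG seed.
#' @param enzyme_au enzyme amount recorded with the table (default 1).
#' @return data.frame with \code{substrate_mM}, \code{rate}; the enzyme
#'   amount is carried in attribute \code{enzyme_au}.
#' @export
gen_kinetics_table <- function(Km, Vmax, S, noise_sd = 0, seed = 1L,
                               enzyme_au = 1) {
  v <- michaelis_menten_rate(S, Km, Vmax)
  if (noise_sd > 0)
    v <- withr::with_seed(seed, pmax(0, v + stats::rnorm(length(v),
                                                         sd = noise_sd)))
  out <- data.frame(substrate_mM = S, rate = v)
  attr(out, "enzyme_au") <- enzyme_au
  out
}

#' Generate a synthetic growth curve
#'
#' OD(t) = od0 * 2^(t / td) with optional multiplicative log-normal noise.
#'
#' @param od0 initial optical density (> 0).
#' @param doubling_time_h generating doubling time, hours (> 0).
#' @param duration_h total duration, hours.
#' @param interval_h sampling interval, hours (default 0.5, a 30-minute
#'   plate-reader cadence).
#' @param noise_sd SD of the log-normal noise on log-OD (default 0).
#' @param seed RNG seed.
#' @return data.frame with \code{time_h}, \code{od}.
#' @export
gen_growth_curve <- function(od0, doubling_time_h, duration_h,
                             interval_h = 0.5, noise_sd = 0, seed = 1L) {
  stopifnot(od0 > 0, doubling_time_h > 0, duration_h > 0, interval_h > 0)
  t <- seq(0, duration_h, by = interval_h)
  od <- od0 * 2^(t / doubling_time_h)
  if (noise_sd > 0)
    od <- withr::with_seed(seed, od * exp(stats::rnorm(length(od),
                                                       sd = noise_sd)))
  data.frame(time_h = t, od = od)
}
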