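# Radius of gyration, dihedrals/rotamers, ligand distances, pocket volume.

struct_from_points <- function(pts, elety = "CA", element = NULL) {
  n <- nrow(pts)
  atoms <- data.frame(elety = rep_len(elety, n), resid = "ALA", chain = "A",
                      resno = seq_len(n), stringsAsFactors = FALSE)
  if (!is.null(element)) atoms$element <- rep_len(element, n)
  md_structure(atoms, pts)
}

test_that("radius of gyration matches closed-form toy values", {
  one <- struct_from_points(matrix(c(1, 2, 3), 1))
  expect_equal(radius_of_gyration(one), 0)

  two <- struct_from_points(rbind(c(0, 0, 0), c(2, 0, 0)), element = "C")
  expect_equal(radius_of_gyration(two), 1.0, tolerance = 1e-12)
  expect_equal(radius_of_gyration(two, mass_weighted = FALSE), 1.0)

  sq <- struct_from_points(rbind(c(0, 0, 0), c(2, 0, 0),
                                 c(2, 2, 0), c(0, 2, 0)), element = "C")
  expect_equal(radius_of_gyration(sq), sqrt(2), tolerance = 1e-12)

  # unequal masses shift the weighting (C vs O two-atom dumbbell)
  co <- struct_from_points(rbind(c(0, 0, 0), c(2, 0, 0)),
                           elety = c("C", "O"), element = c("C", "O"))
  m <- c(12.011, 15.999)
  ctr <- 2 * m[2] / sum(m)
  expect_equal(radius_of_gyration(co),
               sqrt((m[1] * ctr^2 + m[2] * (2 - ctr)^2) / sum(m)),
               tolerance = 1e-12)
  expect_error(radius_of_gyration(co, selection = integer(0)), "empty")
})

test_that("RoG is rigid-transform invariant, scales linearly, and matches bio3d", {
  st <- make_test_protein(8)
  r0 <- radius_of_gyration(st, mass_weighted = FALSE)
  set.seed(3)
  R <- random_rotation()
  moved <- md_structure(st$atoms, st$coords %*% t(R) +
                          matrix(c(4, -7, 2), n_atoms(st), 3, byrow = TRUE))
  expect_equal(radius_of_gyration(moved, mass_weighted = FALSE), r0,
               tolerance = 1e-10)
  scaled <- md_structure(st$atoms, st$coords * 2.5)
  expect_equal(radius_of_gyration(scaled, mass_weighted = FALSE), 2.5 * r0,
               tolerance = 1e-10)

  # mass-weighted variant against the bio3d reference
  expect_equal(radius_of_gyration(st),
               bio3d::rgyr(xyz = as.numeric(t(st$coords)),
                           mass = c(H = 1.008, C = 12.011, N = 14.007,
                                    O = 15.999, S = 32.06)[st$atoms$element]),
               tolerance = 1e-6)
})

test_that("rog_series tracks hinge closure monotonically", {
  hp <- make_hinge_protein(arm_res = 6)
  sched <- seq(0, 30, by = 5)
  tr <- gen_hinge_trajectory(hp$structure, hp$block2, hp$hinge_point,
                             hp$hinge_axis, schedule_deg = sched)
  rog <- rog_series(tr)
  expect_true(all(diff(rog) < 0))

  static <- gen_hinge_trajectory(hp$structure, hp$block2, hp$hinge_point,
                                 hp$hinge_axis, schedule_deg = c(0, 0, 0))
  expect_equal(var(rog_series(static)), 0, tolerance = 1e-20)
})

test_that("dihedral angles follow the signed torsion convention", {
  p1 <- c(1, 1, 0); p2 <- c(0, 1, 0); p3 <- c(0, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(1, 0, 0)), 0, tolerance = 1e-10)
  expect_equal(dihedral_angle(p1, p2, p3, c(-1, 0, 0)), 180,
               tolerance = 1e-10)

  # rigid-transform invariance; mirror reflection negates
  set.seed(8)
  for (k in 1:10) {
    pts <- matrix(rnorm(12, sd = 2), 4)
    a0 <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    R <- random_rotation(); sh <- rnorm(3)
    tp <- pts %*% t(R) + matrix(sh, 4, 3, byrow = TRUE)
    expect_equal(dihedral_angle(tp[1, ], tp[2, ], tp[3, ], tp[4, ]), a0,
                 tolerance = 1e-8)
    mp <- pts; mp[, 3] <- -mp[, 3]
    am <- dihedral_angle(mp[1, ], mp[2, ], mp[3, ], mp[4, ])
    expect_equal(abs(am + a0) %% 360, 0, tolerance = 1e-8)
    # cross-check against the bio3d torsion reference
    expect_equal(a0, bio3d::torsion.xyz(as.numeric(t(pts))),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("rotamer bins cover gauche-, gauche+ and anti", {
  expect_equal(classify_rotamer(c(-51, 60, 160, -160, 180, -120, 0, 119.9)),
               c("gauche-", "gauche+", "anti", "anti", "anti", "gauche-",
                 "gauche+", "gauche+"))
})

test_that("chi1 series extracts the quartet torsion per frame", {
  st <- make_test_protein(5, valine_at = 3)
  tr <- gen_fluctuation_trajectory(st, sigma = 0, n_frames = 2, seed = 1)
  ser <- chi1_series(tr, 3)
  expect_equal(nrow(ser), 2)
  expect_equal(ser$angle[1], ser$angle[2])
  idx <- vapply(c("CG2", "CB", "CA", "C"), function(a)
    select_atoms(st, resno = 3, elety = a), integer(1))
  want <- dihedral_angle(st$coords[idx[1], ], st$coords[idx[2], ],
                         st$coords[idx[3], ], st$coords[idx[4], ])
  expect_equal(ser$angle[1], want, tolerance = 1e-10)
  expect_equal(ser$rotamer[1], classify_rotamer(want))
  # IUPAC quartet option resolves different atoms
  ser2 <- chi1_series(tr, 3, quartet = c("N", "CA", "CB", "CG1"))
  expect_false(isTRUE(all.equal(ser$angle[1], ser2$angle[1])))
  expect_error(chi1_series(tr, 2), "not uniquely")  # ALA has no CG2
})

test_that("residue-ligand distances take the heavy-atom minimum", {
  st <- struct_from_points(matrix(c(0, 0, 0), 1), element = "C")
  expect_equal(residue_ligand_distance(st, 1, matrix(c(0, 0, 0), 1)), 0)
  lig <- rbind(c(3, 0, 0), c(7, 0, 0))
  expect_equal(residue_ligand_distance(st, 1, lig), 3.0)
  expect_error(residue_ligand_distance(st, 1, matrix(0, 0, 3)), "empty")
  expect_error(residue_ligand_distance(st, 9, lig), "not found")
})

test_that("grid pocket volume approximates the enclosed free space", {
  reg <- pocket_region(matrix(c(0, 0, 0), 1), radii = 5, spacing = 0.5)
  v <- pocket_volume(NULL, reg)
  expect_lt(abs(v / (4 / 3 * pi * 125) - 1), 0.03)

  # halving the spacing tightens the estimate
  reg_f <- pocket_region(matrix(c(0, 0, 0), 1), radii = 5, spacing = 0.25)
  v_f <- pocket_volume(NULL, reg_f)
  expect_lt(abs(v_f - 4 / 3 * pi * 125), abs(v - 4 / 3 * pi * 125) + 1)

  # densely packed atoms leave no free volume
  grid <- as.matrix(expand.grid(seq(-5, 5, 1), seq(-5, 5, 1),
                                seq(-5, 5, 1)))
  packed <- struct_from_points(grid, element = "C")
  expect_equal(pocket_volume(packed, reg), 0)

  # volume is non-increasing as atoms are added inside the region
  some <- struct_from_points(grid[1:80, , drop = FALSE], element = "C")
  more <- struct_from_points(grid[1:200, , drop = FALSE], element = "C")
  v1 <- pocket_volume(some, reg); v2 <- pocket_volume(more, reg)
  expect_lte(v2, v1)
  expect_lte(v1, v)
})
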