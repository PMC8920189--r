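# Trajectory data model, multi-model PDB I/O, superposition and trimming.

test_that("multi-model PDB reading handles models, single structures and bad files", {
  st <- make_test_protein(3)
  tr <- gen_fluctuation_trajectory(st, sigma = 0.2, n_frames = 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(tr, f)
  got <- read_multimodel_pdb(f)
  expect_equal(n_frames(got), 2)
  expect_equal(n_atoms(got), n_atoms(tr))

  # single-conformation file -> 1-frame trajectory
  f1 <- withr::local_tempfile(fileext = ".pdb")
  lines <- readLines(f)
  body <- lines[startsWith(lines, "ATOM")]
  writeLines(c(body[seq_len(n_atoms(tr))], "END"), f1)
  one <- read_multimodel_pdb(f1)
  expect_equal(n_frames(one), 1)
  expect_equal(n_atoms(one), n_atoms(tr))

  # model 2 missing an atom -> named inconsistent-topology error
  f2 <- withr::local_tempfile(fileext = ".pdb")
  bad <- lines[-(which(startsWith(lines, "ATOM"))[n_atoms(tr) + 1L])]
  writeLines(bad, f2)
  expect_error(read_multimodel_pdb(f2), class = "hxkdyn_inconsistent_models")

  expect_error(read_multimodel_pdb(tempfile()), class = "hxkdyn_missing_file")
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", "ENDMDL"), f3)
  expect_error(read_multimodel_pdb(f3), class = "hxkdyn_parse_error")
})

test_that("PDB round trip preserves topology and coordinates to 3 decimals", {
  st <- make_test_protein(6, glycine_at = 3, valine_at = 5)
  tr <- gen_fluctuation_trajectory(st, sigma = 1.0, n_frames = 3, seed = 7)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(tr, f)
  got <- read_multimodel_pdb(f)
  expect_identical(got$atoms$elety, tr$atoms$elety)
  expect_identical(got$atoms$resno, tr$atoms$resno)
  expect_identical(got$atoms$resid, tr$atoms$resid)
  expect_lt(max(abs(got$xyz - tr$xyz)), 5.1e-4)

  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(got, f2)
  expect_identical(read_multimodel_pdb(f2)$xyz, got$xyz)
})

test_that("Kabsch superposition is exact on rigid motions and matches the quaternion oracle", {
  set.seed(11)
  A <- matrix(rnorm(12), 4)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)

  # proper rigid transform of either input leaves the RMSD unchanged
  for (k in 1:5) {
    R <- random_rotation()
    shift <- rnorm(3, sd = 5)
    B <- A + matrix(rnorm(12, sd = 0.3), 4)
    r0 <- kabsch_superpose(B, A)$rmsd
    Bt <- B %*% t(R) + matrix(shift, 4, 3, byrow = TRUE)
    expect_equal(kabsch_superpose(Bt, A)$rmsd, r0, tolerance = 1e-8)
    expect_equal(kabsch_superpose(B, A %*% t(R))$rmsd, r0, tolerance = 1e-8)
  }

  # rotation is always proper (no reflections), even for near-planar sets
  flat <- cbind(matrix(rnorm(8), 4), 0)
  fit <- kabsch_superpose(flat, flat[, c(2, 1, 3)])
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # unit square with one displaced corner vs quaternion-method oracle
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  sq2 <- sq; sq2[2, ] <- sq2[2, ] + c(0, 0, 1)
  expect_equal(kabsch_superpose(sq2, sq)$rmsd, oracle_rmsd(sq2, sq),
               tolerance = 1e-10)
  for (k in 1:10) {
    P <- matrix(rnorm(15), 5); Q <- matrix(rnorm(15), 5)
    expect_equal(kabsch_superpose(P, Q)$rmsd, oracle_rmsd(P, Q),
                 tolerance = 1e-8)
  }

  expect_error(kabsch_superpose(A, A[1:3, ]), "equal size")
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
})

test_that("superposition agrees with the bio3d reference fit", {
  set.seed(4)
  P <- matrix(rnorm(30), 10); Q <- P + matrix(rnorm(30, sd = 0.5), 10)
  ref <- bio3d::fit.xyz(as.numeric(t(P)), as.numeric(t(Q)),
                        fixed.inds = 1:30, mobile.inds = 1:30)
  expect_equal(kabsch_superpose(Q, P)$rmsd,
               bio3d::rmsd(as.numeric(t(P)), ref), tolerance = 1e-3)
})

test_that("RMSD time series is zero for static/translated frames and matches a closed form", {
  st <- make_test_protein(4)
  static <- gen_fluctuation_trajectory(st, sigma = 0, n_frames = 3, seed = 1)
  expect_equal(rmsd_timeseries(static), rep(0, 3), tolerance = 1e-12)

  shifted <- static
  shifted$xyz[2, ] <- shifted$xyz[2, ] + rep(c(3, -2, 7), n_atoms(st))
  expect_equal(rmsd_timeseries(shifted), rep(0, 3), tolerance = 1e-10)

  # one atom displaced by 2 A among 4 CA atoms: oracle via quaternion fit
  atoms <- ca_atoms(4)
  base <- cbind(seq(0, 9, 3), 0, 0)
  moved <- base; moved[2, 2] <- 2
  tr <- toy_trajectory(atoms, list(base, moved))
  expect_equal(rmsd_timeseries(tr, selection = 1:4)[2],
               oracle_rmsd(moved, base), tolerance = 1e-10)
  expect_true(all(rmsd_timeseries(tr, selection = 1:4) >= 0))
  expect_error(rmsd_timeseries(tr, selection = integer(0)), "empty")
})

test_that("trim_and_stride removes the pre-equilibration segment and subsamples", {
  atoms <- ca_atoms(3)
  frames <- replicate(10, matrix(rnorm(9), 3), simplify = FALSE)
  tr <- toy_trajectory(atoms, frames, times = 0:9)  # 1 ns spacing

  trimmed <- trim_and_stride(tr, discard_ns = 5, stride_ps = 1000)
  expect_equal(n_frames(trimmed), 5)
  expect_equal(trimmed$times, 5:9)

  strided <- trim_and_stride(tr, discard_ns = 0, stride_ps = 2000)
  expect_equal(n_frames(strided), 5)
  expect_equal(strided$times, c(0, 2, 4, 6, 8))

  expect_error(trim_and_stride(tr, discard_ns = 9, stride_ps = 1000),
               "duration")
  # original untouched
  expect_equal(n_frames(tr), 10)
})

test_that("atom selection is deterministic and supports selection strings", {
  st <- make_test_protein(5, glycine_at = 2)
  idx <- select_atoms(st, resno = 3, elety = "CA")
  expect_length(idx, 1)
  expect_equal(st$atoms$resno[idx], 3)
  expect_identical(select_atoms(st, string = "A:3:CA"), idx)
  expect_identical(select_atoms(st, string = "A:3"),
                   select_atoms(st, resno = 3))
  expect_length(select_atoms(st, resno = 99), 0)
  expect_setequal(st$atoms$elety[backbone_indices(st)],
                  c("N", "CA", "C", "O"))
})
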