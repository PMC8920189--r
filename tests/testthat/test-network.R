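# Residue interaction graphs, betweenness centrality and path-participation
# fractions.

line_graph <- function(xs, cutoff = 6.7) {
  # residues with CB node atoms at the given x positions
  atoms <- data.frame(elety = rep(c("CA", "CB"), length(xs)),
                      resid = "ALA", chain = "A",
                      resno = rep(seq_along(xs), each = 2),
                      stringsAsFactors = FALSE)
  coords <- matrix(0, 2 * length(xs), 3)
  coords[seq(2, nrow(coords), 2), 1] <- xs
  coords[seq(1, nrow(coords), 2), ] <- cbind(xs, 50, 0)  # CA out of range
  build_residue_graph(md_structure(atoms, coords), cutoff = cutoff)
}

test_that("graph construction thresholds node-atom distances inclusively", {
  g <- line_graph(c(0, 5, 10))
  expect_equal(nrow(g$nodes), 3)
  expect_equal(g$edges[, c("i", "j")], data.frame(i = 1:2, j = 2:3),
               ignore_attr = TRUE)

  # exactly at the cutoff -> edge present
  g2 <- line_graph(c(0, 6.7))
  expect_equal(nrow(g2$edges), 1)
  g3 <- line_graph(c(0, 6.701))
  expect_equal(nrow(g3$edges), 0)

  # glycine contributes its CA as the node atom
  st <- make_test_protein(3, glycine_at = 2)
  gg <- build_residue_graph(st)
  gly_ca <- st$coords[select_atoms(st, resno = 2, elety = "CA"), ]
  expect_equal(unlist(gg$nodes[2, c("x", "y", "z")]), gly_ca,
               ignore_attr = TRUE)
})

test_that("betweenness follows the fractional shortest-path definition", {
  # path graph A-B-C: only the middle node is interior to a pair
  expect_equal(betweenness_profile(line_graph(c(0, 5, 10))),
               c("1" = 0, "2" = 1, "3" = 0))

  # 4-cycle: each antipodal pair has two tied shortest paths
  atoms <- data.frame(elety = "CB", resid = "ALA", chain = "A", resno = 1:4,
                      stringsAsFactors = FALSE)
  sq <- md_structure(atoms, rbind(c(0, 0, 0), c(5, 0, 0),
                                  c(5, 5, 0), c(0, 5, 0)))
  bc <- betweenness_profile(build_residue_graph(sq, cutoff = 6))
  expect_equal(unname(bc), rep(0.5, 4))
})

test_that("betweenness matches exhaustive path enumeration on random geometric graphs", {
  set.seed(2024)
  for (k in 1:60) {
    n <- sample(3:8, 1)
    g <- random_geometric_graph(n, cutoff = runif(1, 0.8, 1.6))
    got <- betweenness_profile(g)
    want <- oracle_betweenness(g$edges, n)
    expect_equal(unname(got), want, tolerance = 1e-10)
    # conservation: total BC equals total interior traversals of all paths
    expect_equal(sum(got), sum(want), tolerance = 1e-10)
  }
})

test_that("ensemble BC averages per-frame profiles", {
  st <- make_test_protein(5)
  static <- gen_fluctuation_trajectory(st, sigma = 0, n_frames = 3, seed = 1)
  es <- ensemble_bc(static)
  expect_equal(nrow(es$bc), 3)
  expect_equal(apply(es$bc, 2, var), rep(0, 5), ignore_attr = TRUE)
  expect_equal(es$mean, es$bc[1, ], tolerance = 1e-12)

  one <- ensemble_bc(trim_and_stride(static, 0, NULL)) # same frames
  expect_equal(one$mean,
               betweenness_profile(build_residue_graph(get_frame(static, 1))))

  # two-frame toy alternating path and star topologies
  xs_path <- c(0, 5, 10, 15)
  xs_star <- c(0, 5, 5.5, 6)          # node 1 peripheral; 2,3,4 clustered
  atoms <- data.frame(elety = "CB", resid = "ALA", chain = "A", resno = 1:4,
                      stringsAsFactors = FALSE)
  tr <- toy_trajectory(atoms, list(cbind(xs_path, 0, 0),
                                   cbind(xs_star, 0, 0)))
  es2 <- ensemble_bc(tr, cutoff = 6.7)
  p1 <- betweenness_profile(build_residue_graph(get_frame(tr, 1)))
  p2 <- betweenness_profile(build_residue_graph(get_frame(tr, 2)))
  expect_equal(es2$mean, (p1 + p2) / 2, tolerance = 1e-12)
})

test_that("group path fractions count path-level membership", {
  g5 <- line_graph(c(0, 5, 10, 15, 20))
  # middle node of a 5-path is interior to 4 of the 10 pairs
  expect_equal(group_path_fraction(g5, 3), 0.4, tolerance = 1e-12)
  # leaves are never interior
  expect_equal(group_path_fraction(g5, 1), 0)
  # whole-graph group: fraction counts only pairs at distance >= 2
  expect_equal(group_path_fraction(g5, 1:5), 6 / 10, tolerance = 1e-12)

  # monotone non-decreasing under group enlargement
  set.seed(7)
  for (k in 1:10) {
    g <- random_geometric_graph(7, cutoff = 1.2)
    f1 <- group_path_fraction(g, 3)
    f2 <- group_path_fraction(g, c(3, 5))
    f3 <- group_path_fraction(g, c(3, 5, 6))
    expect_true(f1 <= f2 + 1e-12 && f2 <= f3 + 1e-12)
    expect_true(f3 <= 1 + 1e-12)
  }
  expect_error(group_path_fraction(g5, 99), "absent")

  # fractional ties: on a 4-cycle, half of each antipodal pair's paths
  # pass through a given off-pair node
  atoms <- data.frame(elety = "CB", resid = "ALA", chain = "A", resno = 1:4,
                      stringsAsFactors = FALSE)
  sq <- build_residue_graph(md_structure(atoms,
                                         rbind(c(0, 0, 0), c(5, 0, 0),
                                               c(5, 5, 0), c(0, 5, 0))),
                            cutoff = 6)
  expect_equal(group_path_fraction(sq, 2), 0.5 / 6, tolerance = 1e-12)
})

test_that("residue-count fractions match the printed protein-wide percentages", {
  expect_identical(residue_fraction(c(231, 236), 469), 1.28)
  expect_identical(residue_fraction(1, 469), 0.21)
  expect_identical(residue_fraction(c(417, 425), 469), 1.92)
  expect_error(residue_fraction(0, 469), "empty span")
  expect_error(residue_fraction(5, 0), "positive")
})

test_that("per-residue BC effect sizes follow the pooled-SD convention", {
  ids <- data.frame(chain = "A", resno = 1:2, resid = "ALA",
                    stringsAsFactors = FALSE)
  mk <- function(col1, col2) {
    structure(list(residues = ids, bc = cbind(col1, col2),
                   mean = c(mean(col1), mean(col2))),
              class = "centrality_series")
  }
  a <- mk(c(1, 2, 3), c(0, 0, 0))
  b <- mk(c(3, 4, 5), c(1, 1, 1))
  d <- bc_effect_size(a, b)
  expect_equal(unname(d[1]), -2)
  expect_true(is.na(d[2]))  # zero pooled SD with unequal means: flagged
  expect_equal(unname(d[1]), -unname(bc_effect_size(b, a)[1]))
  expect_equal(unname(bc_effect_size(a, a)[1]), 0)
})

test_that("hinge closure adds interface edges between the arms", {
  hp <- make_hinge_protein(arm_res = 6)
  tr <- gen_hinge_trajectory(hp$structure, hp$block2, hp$hinge_point,
                             hp$hinge_axis, schedule_deg = c(0, 30, 60, 80))
  cross_edges <- vapply(seq_len(n_frames(tr)), function(f) {
    g <- build_residue_graph(get_frame(tr, f))
    in1 <- g$nodes$resno[g$edges$i] %in% hp$block1
    in2 <- g$nodes$resno[g$edges$j] %in% hp$block2
    sum((in1 & in2) |
          (g$nodes$resno[g$edges$i] %in% hp$block2 &
             g$nodes$resno[g$edges$j] %in% hp$block1))
  }, numeric(1))
  expect_true(all(diff(cross_edges) >= 0))
  expect_gt(cross_edges[4], cross_edges[1])
})
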