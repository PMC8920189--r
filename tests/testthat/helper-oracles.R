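# Independent oracles used across the suite. Each is a deliberately
# brute-force or closed-form implementation, kept separate from the
# package's computational path.

# Exhaustive shortest-path enumeration: betweenness by listing every
# simple path between every node pair and keeping the shortest ones.
# Only viable for tiny graphs (<= ~8 nodes).
oracle_betweenness <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer(0)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- edges$i[k]; j <- edges$j[k]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1L]] <<- path; return(invisible()) }
      for (w in adj[[v]]) if (!(w %in% path)) walk(c(path, w))
    }
    walk(s)
    out
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in seq.int(s + 1L, n)) {
    paths <- all_paths(s, t)
    if (length(paths) == 0L) next
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    k <- length(shortest)
    for (p in shortest) {
      interior <- p[-c(1L, length(p))]
      bc[interior] <- bc[interior] + 1 / k
    }
  }
  bc
}

# Random geometric graph on n points in a box, as a residue_graph whose
# node atoms are CB atoms of a synthetic chain placed at the points.
random_geometric_graph <- function(n, cutoff = 1.0, box = 2.0) {
  pts <- matrix(stats::runif(3 * n, 0, box), ncol = 3)
  atoms <- data.frame(elety = rep(c("CA", "CB"), n),
                      resid = "ALA", chain = "A",
                      resno = rep(seq_len(n), each = 2),
                      stringsAsFactors = FALSE)
  coords <- matrix(0, 2 * n, 3)
  coords[seq(2, 2 * n, 2), ] <- pts                 # CB at the point
  coords[seq(1, 2 * n, 2), ] <- pts + 100           # CA far away, unused
  build_residue_graph(md_structure(atoms, coords), cutoff = cutoff)
}

# Double-loop DCC oracle: explicit covariance/normalization per the
# definition, no matrix algebra shared with the implementation.
oracle_dcc <- function(traj, node_atom = "CA") {
  idx <- which(traj$atoms$elety == node_atom)
  nf <- n_frames(traj)
  pos <- lapply(seq_along(idx), function(k) {
    t(vapply(seq_len(nf),
             function(f) frame_coords(traj, f)[idx[k], ], numeric(3)))
  })
  nr <- length(idx)
  C <- matrix(NA_real_, nr, nr)
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    di <- sweep(pos[[i]], 2, colMeans(pos[[i]]))
    dj <- sweep(pos[[j]], 2, colMeans(pos[[j]]))
    num <- mean(rowSums(di * dj))
    den <- sqrt(mean(rowSums(di^2)) * mean(rowSums(dj^2)))
    if (den > 0) C[i, j] <- num / den
  }
  C
}

# Quaternion-method superposition RMSD oracle (Kearsley): the minimal
# RMSD is derived from the smallest eigenvalue of the 4x4 residual
# matrix, an entirely different route from the SVD-based Kabsch fit.
oracle_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  xm <- B[, 1] - A[, 1]; ym <- B[, 2] - A[, 2]; zm <- B[, 3] - A[, 3]
  xp <- B[, 1] + A[, 1]; yp <- B[, 2] + A[, 2]; zp <- B[, 3] + A[, 3]
  Q <- matrix(0, 4, 4)
  Q[1, 1] <- sum(xm^2 + ym^2 + zm^2)
  Q[2, 2] <- sum(xm^2 + yp^2 + zp^2)
  Q[3, 3] <- sum(xp^2 + ym^2 + zp^2)
  Q[4, 4] <- sum(xp^2 + yp^2 + zm^2)
  Q[1, 2] <- Q[2, 1] <- sum(yp * zm - ym * zp)
  Q[1, 3] <- Q[3, 1] <- sum(xm * zp - xp * zm)
  Q[1, 4] <- Q[4, 1] <- sum(xp * ym - xm * yp)
  Q[2, 3] <- Q[3, 2] <- sum(xm * ym - xp * yp)
  Q[2, 4] <- Q[4, 2] <- sum(xm * zm - xp * zp)
  Q[3, 4] <- Q[4, 3] <- sum(ym * zm - yp * zp)
  sqrt(max(0, min(eigen(Q, symmetric = TRUE)$values)) / nrow(mobile))
}

# Tiny trajectory built directly from a list of per-frame coordinate
# matrices over an explicit atom table.
toy_trajectory <- function(atoms, frames, times = NULL) {
  xyz <- t(vapply(frames, function(m) as.numeric(t(m)),
                  numeric(3 * nrow(atoms))))
  md_trajectory(atoms, xyz, times = times)
}

ca_atoms <- function(n) {
  data.frame(elety = "CA", resid = "ALA", chain = "A", resno = seq_len(n),
             stringsAsFactors = FALSE)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}
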