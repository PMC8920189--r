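# Dynamic cross-correlation: C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>),
# where dr_i is the displacement of residue i's node atom from its
# time-average position and <.> averages over the retained frames.

#' Dynamic cross-correlation matrix
#'
#' One node atom per residue (C-alpha by default); residues lacking the
#' node atom are omitted. Residues that never move (\code{<dr^2> = 0})
#' yield \code{NA} rows/columns: an undefined correlation is flagged, not
#' imputed.
#'
#' @param traj an aligned \code{md_trajectory} with at least 2 frames.
#' @param node_atom atom name used as each residue's node (default
#'   \code{"CA"}).
#' @return numeric symmetric matrix in [-1, 1] with unit diagonal (where
#'   defined), class \code{dcc_matrix}; residue numbers as dimnames and a
#'   \code{residues} attribute carrying the id table.
#' @export
dcc_matrix <- function(traj, node_atom = "CA") {
  stopifnot(inherits(traj, "md_trajectory"))
  if (n_frames(traj) < 2L) stop("DCC needs at least 2 frames", call. = FALSE)
  idx <- select_atoms(traj, elety = node_atom)
  if (length(idx) == 0L) stop("no '", node_atom, "' atoms found", call. = FALSE)
  nf <- n_frames(traj)
  nr <- length(idx)
  # Displacements about the time mean, per axis: (frames x residues).
  xs <- traj$xyz[, 3L * idx - 2L, drop = FALSE]
  ys <- traj$xyz[, 3L * idx - 1L, drop = FALSE]
  zs <- traj$xyz[, 3L * idx, drop = FALSE]
  xs <- sweep(xs, 2L, colMeans(xs)); ys <- sweep(ys, 2L, colMeans(ys))
  zs <- sweep(zs, 2L, colMeans(zs))
  # <dr_i . dr_j> accumulated axis-wise.
  cov <- (crossprod(xs) + crossprod(ys) + crossprod(zs)) / nf
  msd <- diag(cov)
  mobile <- msd > 0
  norm <- sqrt(outer(msd, msd))
  C <- matrix(NA_real_, nr, nr)
  C[mobile, mobile] <- cov[mobile, mobile] / norm[mobile, mobile]
  diag(C)[mobile] <- 1
  C <- pmin(pmax(C, -1), 1)
  ids <- traj$atoms[idx, c("chain", "resno", "resid")]
  rownames(ids) <- NULL
  dimnames(C) <- list(ids$resno, ids$resno)
  attr(C, "residues") <- ids
  class(C) <- c("dcc_matrix", class(C))
  C
}

#' Element-wise difference of two correlation matrices
#'
#' Returns ref - other (e.g. WT minus mutant). Entries lie in [-2, 2] and
#' the diagonal is 0; \code{NA} entries propagate.
#'
#' @param ref,other \code{dcc_matrix} objects over identical residue lists.
#' @return matrix of class \code{delta_dcc_matrix}.
#' @export
delta_dcc <- function(ref, other) {
  ri <- attr(ref, "residues"); oi <- attr(other, "residues")
  if (is.null(ri) || is.null(oi) ||
      !identical(ri[, c("chain", "resno")], oi[, c("chain", "resno")]))
    stop("residue lists differ between matrices", call. = FALSE)
  D <- unclass(ref) - unclass(other)
  attr(D, "residues") <- ri
  class(D) <- c("delta_dcc_matrix", class(D))
  D
}

#' Correlation profile of a single residue
#'
#' Extracts the matrix row for one residue as a per-residue track, e.g. the
#' correlation of the mutation-site residue with every other residue, or
#' its row of a difference matrix.
#'
#' @param mat a \code{dcc_matrix} or \code{delta_dcc_matrix}.
#' @param resno residue number (with optional \code{chain}).
#' @param chain chain identifier; \code{NULL} matches any single hit.
#' @return data.frame with \code{chain}, \code{resno}, \code{resid},
#'   \code{value}.
#' @export
residue_correlation_profile <- function(mat, resno, chain = NULL) {
  ids <- attr(mat, "residues")
  hit <- which(ids$resno == resno &
                 (if (is.null(chain)) TRUE else ids$chain == chain))
  if (length(hit) != 1L)
    stop("residue ", resno, " not uniquely present in matrix", call. = FALSE)
  data.frame(chain = ids$chain, resno = ids$resno, resid = ids$resid,
             value = unclass(mat)[hit, ], row.names = NULL,
             stringsAsFactors = FALSE)
}
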