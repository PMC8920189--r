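# Residue interaction networks and betweenness centrality. Nodes are the
# C-beta atoms (C-alpha for glycine); edges connect node atoms within a
# distance cutoff (6.7 A by default). Betweenness uses the standard
# unweighted shortest-path definition with fractional handling of tied
# paths and endpoints excluded.

#' Build a residue interaction graph from one conformation
#'
#' @param frame an \code{md_structure}.
#' @param cutoff edge distance cutoff in Angstrom (default 6.7); the
#'   threshold is inclusive.
#' @return list of class \code{residue_graph} with \code{nodes}
#'   (data.frame: chain, resno, resid, x, y, z), \code{edges} (data.frame:
#'   i, j, distance; node indices i < j) and \code{cutoff}. Nodes are
#'   ordered by (chain, residue number).
#' @export
build_residue_graph <- function(frame, cutoff = 6.7) {
  stopifnot(inherits(frame, "md_structure"))
  rs <- .residue_split(frame$atoms)
  node_idx <- vapply(seq_along(rs$groups), function(r) {
    g <- rs$groups[[r]]
    names <- frame$atoms$elety[g]
    cb <- g[names == "CB"]
    if (length(cb) >= 1L) return(cb[1])
    ca <- g[names == "CA"]
    if (rs$ids$resid[r] == "GLY" && length(ca) >= 1L) return(ca[1])
    if (length(ca) >= 1L) return(ca[1])  # tolerate CB-less non-glycine
    stop("residue ", rs$ids$resno[r], " lacks both CB and CA", call. = FALSE)
  }, integer(1))
  ord <- order(rs$ids$chain, rs$ids$resno)
  ids <- rs$ids[ord, , drop = FALSE]
  xyz <- frame$coords[node_idx[ord], , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  n <- nrow(xyz)
  pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  edges <- data.frame(i = pairs[, 1], j = pairs[, 2],
                      distance = d[pairs])
  nodes <- data.frame(chain = ids$chain, resno = ids$resno, resid = ids$resid,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff),
            class = "residue_graph")
}

# igraph view of a residue_graph (undirected, simple).
.as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("i", "j")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(graph$nodes))))
}

#' Betweenness centrality of every residue node
#'
#' Unweighted shortest-path betweenness: each connected node pair
#' contributes 1 split fractionally over its tied shortest paths; endpoints
#' do not count as "passing through"; unreachable pairs contribute nothing.
#' Counts are unnormalized by default.
#'
#' @param graph a \code{residue_graph}.
#' @param normalized if \code{TRUE}, divide by \code{(n-1)(n-2)/2}.
#' @return numeric vector of BC values, one per node, named by residue
#'   number.
#' @export
betweenness_profile <- function(graph, normalized = FALSE) {
  stopifnot(inherits(graph, "residue_graph"))
  g <- .as_igraph(graph)
  bc <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  bc <- bc[order(as.integer(names(bc)))]
  names(bc) <- graph$nodes$resno
  bc
}

#' Ensemble (time-averaged) betweenness centrality over a trajectory
#'
#' Rebuilds the residue graph for every retained frame, computes the
#' per-frame betweenness profile, and averages.
#'
#' @param traj an \code{md_trajectory} (already trimmed/strided as wanted).
#' @param cutoff edge cutoff in Angstrom (default 6.7).
#' @return list of class \code{centrality_series}: \code{residues} (id
#'   table), \code{bc} (frames x residues matrix), \code{mean} (per-residue
#'   ensemble average).
#' @export
ensemble_bc <- function(traj, cutoff = 6.7) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (n_frames(traj) < 1L) stop("empty trajectory", call. = FALSE)
  profiles <- lapply(seq_len(n_frames(traj)), function(f) {
    betweenness_profile(build_residue_graph(get_frame(traj, f), cutoff))
  })
  bc <- do.call(rbind, profiles)
  g1 <- build_residue_graph(get_frame(traj, 1L), cutoff)
  structure(list(residues = g1$nodes[, c("chain", "resno", "resid")],
                 bc = bc, mean = colMeans(bc)),
            class = "centrality_series")
}

# BFS geodesic counting from one source over an adjacency list:
# returns integer distances (-1 = unreachable) and shortest-path counts.
.geodesic_counts <- function(adj, source) {
  n <- length(adj)
  dist <- rep(-1L, n); sigma <- numeric(n)
  dist[source] <- 0L; sigma[source] <- 1
  frontier <- source
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

.adjacency_list <- function(graph, drop = integer(0)) {
  n <- nrow(graph$nodes)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer(0)
  e <- graph$edges
  keep <- !(e$i %in% drop) & !(e$j %in% drop)
  for (k in which(keep)) {
    adj[[e$i[k]]] <- c(adj[[e$i[k]]], e$j[k])
    adj[[e$j[k]]] <- c(adj[[e$j[k]]], e$i[k])
  }
  adj
}

#' Fraction of shortest paths passing through a residue group
#'
#' For every connected node pair (s, t), the fraction of its tied shortest
#' paths that traverse at least one group member as an interior node is
#' computed (a path counts once even if it crosses several members); the
#' result is the mean of these fractions over all connected pairs, in
#' [0, 1]. Multiply by 100 for the percent-of-paths figure.
#'
#' @param graph a \code{residue_graph}.
#' @param resnos residue numbers forming the group (all must be nodes).
#' @param per_member if \code{TRUE}, count a path once per traversed
#'   member instead of once per path (alternative bookkeeping; default
#'   \code{FALSE}).
#' @return fraction in [0, 1] (can exceed 1 when \code{per_member}).
#' @export
group_path_fraction <- function(graph, resnos, per_member = FALSE) {
  stopifnot(inherits(graph, "residue_graph"))
  group <- which(graph$nodes$resno %in% resnos)
  if (length(group) == 0L || length(group) < length(unique(resnos)))
    stop("group contains residues absent from the graph", call. = FALSE)
  if (per_member) {
    bc <- betweenness_profile(graph)
    tot <- .connected_pair_count(graph)
    if (tot == 0) return(0)
    return(sum(bc[group]) / tot)
  }
  adj_full <- .adjacency_list(graph)
  n <- length(adj_full)
  total_pairs <- 0
  through <- 0
  for (s in seq_len(n - 1L)) {
    full <- .geodesic_counts(adj_full, s)
    # paths avoiding group members other than the endpoints themselves
    adj_avoid <- .adjacency_list(graph, drop = setdiff(group, s))
    avoid <- .geodesic_counts(adj_avoid, s)
    for (t in seq.int(s + 1L, n)) {
      if (full$dist[t] < 0L) next
      total_pairs <- total_pairs + 1
      av <- if (t %in% group) {
        # t is an endpoint: re-run with t kept in the graph
        .geodesic_counts(.adjacency_list(graph, drop = setdiff(group, c(s, t))), s)
      } else avoid
      frac_avoid <- if (av$dist[t] == full$dist[t]) av$sigma[t] / full$sigma[t] else 0
      through <- through + (1 - frac_avoid)
    }
  }
  if (total_pairs == 0) return(0)
  through / total_pairs
}

.connected_pair_count <- function(graph) {
  adj <- .adjacency_list(graph)
  n <- length(adj)
  tot <- 0
  for (s in seq_len(n - 1L)) {
    d <- .geodesic_counts(adj, s)$dist
    tot <- tot + sum(d[seq.int(s + 1L, n)] > 0L)
  }
  tot
}

#' Residue-count fraction of a sequence span
#'
#' The percentage of the simulated residues that a contiguous span (or a
#' residue count) represents, reported to 2 decimals, e.g. a 6-residue
#' hairpin of a 469-residue protein is 1.28\%.
#'
#' @param span either a single count, or a length-2 vector
#'   \code{c(first, last)} of an inclusive residue-number range.
#' @param total total residue count (> 0).
#' @return percentage, rounded to 2 decimals.
#' @export
residue_fraction <- function(span, total) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  n <- if (length(span) == 2L) abs(span[2] - span[1]) + 1 else span[1]
  if (n <= 0) stop("empty span", call. = FALSE)
  round(100 * n / total, 2)
}

#' Per-residue Cohen's d between two centrality series
#'
#' Standardized mean difference of the per-frame BC values, residue by
#' residue: d = (mean_A - mean_B) / pooled SD. Residues with zero pooled
#' SD are flagged \code{NA}.
#'
#' @param a,b \code{centrality_series} over identical residue lists, each
#'   with >= 2 frames.
#' @return numeric vector of d values named by residue number.
#' @export
bc_effect_size <- function(a, b) {
  if (!identical(a$residues[, c("chain", "resno")],
                 b$residues[, c("chain", "resno")]))
    stop("residue lists differ between series", call. = FALSE)
  if (nrow(a$bc) < 2L || nrow(b$bc) < 2L)
    stop("each series needs >= 2 frames", call. = FALSE)
  d <- vapply(seq_len(ncol(a$bc)), function(r) {
    tryCatch(cohens_d(a$bc[, r], b$bc[, r]), error = function(e) NA_real_)
  }, numeric(1))
  names(d) <- a$residues$resno
  d
}
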