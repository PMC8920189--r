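# End-to-end comparison of a reference system (e.g. wild type) against a
# perturbed one (e.g. a point mutant), each supplied as one or more
# replicate trajectories: trim -> align -> concatenate -> RMSF / DCC /
# betweenness / RoG (+ optional chi1 and pocket volume) -> distribution
# statistics, with every stage delegated to the standalone module
# functions so pipeline output equals standalone output on the same input.

#' Build a comparison configuration
#'
#' Captures the fixed analysis constants in one place. Defaults: 5 ns
#' equilibration discard, 10 ps frame stride, 6.7 A residue-graph cutoff,
#' 0.85 A RMSF-difference classification threshold.
#'
#' @param systems named list of systems; each system is a list of one or
#'   more \code{md_trajectory} replicates (or file paths readable by
#'   [read_multimodel_pdb()]) sharing a topology.
#' @param discard_ns,stride_ps equilibration trim and stride (see
#'   [trim_and_stride()]). Use \code{discard_ns = 0} for synthetic
#'   ensembles that need no equilibration.
#' @param cutoff residue-graph edge cutoff, Angstrom.
#' @param delta_rmsf_threshold flexibility classification threshold,
#'   Angstrom.
#' @param groups named list of residue-number vectors whose path
#'   participation is reported (e.g.
#'   \code{list(hairpin = 231:236, catalytic = 211, helix = 417:425)}).
#' @param contrast length-2 character vector naming the (reference,
#'   other) systems for the difference maps; defaults to the first two
#'   systems.
#' @param chi1_resno optional residue number for a chi1 rotamer analysis.
#' @param chi1_quartet atom quartet for the chi1 torsion.
#' @param pocket optional \code{pocket_region} for cleft-volume series.
#' @param node_atom DCC node atom name (default \code{"CA"}).
#' @return list of class \code{comparison_config}.
#' @export
comparison_config <- function(systems, discard_ns = 5, stride_ps = 10,
                              cutoff = 6.7, delta_rmsf_threshold = 0.85,
                              groups = list(), contrast = NULL,
                              chi1_resno = NULL,
                              chi1_quartet = c("CG2", "CB", "CA", "C"),
                              pocket = NULL, node_atom = "CA") {
  stopifnot(is.list(systems), length(systems) >= 2L,
            !is.null(names(systems)), all(nzchar(names(systems))),
            discard_ns >= 0, stride_ps > 0, cutoff > 0,
            delta_rmsf_threshold > 0)
  if (is.null(contrast)) contrast <- names(systems)[1:2]
  stopifnot(length(contrast) == 2L, all(contrast %in% names(systems)))
  structure(list(systems = systems, discard_ns = discard_ns,
                 stride_ps = stride_ps, cutoff = cutoff,
                 delta_rmsf_threshold = delta_rmsf_threshold,
                 groups = groups, contrast = contrast,
                 chi1_resno = chi1_resno, chi1_quartet = chi1_quartet,
                 pocket = pocket, node_atom = node_atom),
            class = "comparison_config")
}

# Load (if paths), trim/stride, align each replicate to its own first
# frame, then concatenate retained frames into one trajectory.
.prepare_system <- function(replicates, discard_ns, stride_ps, label) {
  trajs <- lapply(replicates, function(tr) {
    if (is.character(tr)) tr <- read_multimodel_pdb(tr, stride_ps = stride_ps)
    stopifnot(inherits(tr, "md_trajectory"))
    tr <- trim_and_stride(tr, discard_ns = discard_ns, stride_ps = stride_ps)
    align_trajectory(tr)
  })
  topo <- trajs[[1]]$atoms
  for (tr in trajs[-1]) {
    if (!identical(tr$atoms[, c("elety", "resid", "chain", "resno")],
                   topo[, c("elety", "resid", "chain", "resno")]))
      stop("replicate topologies differ within system '", label, "'",
           call. = FALSE)
  }
  xyz <- do.call(rbind, lapply(trajs, function(tr) tr$xyz))
  dt <- if (n_frames(trajs[[1]]) > 1L)
    diff(trajs[[1]]$times[1:2]) else stride_ps / 1000
  md_trajectory(topo, xyz, times = (seq_len(nrow(xyz)) - 1L) * dt,
                label = label)
}

#' Run the full comparative-dynamics analysis
#'
#' Executes, in fixed order and per system: equilibration trim + stride,
#' backbone alignment, replicate concatenation, residue RMSF, dynamic
#' cross-correlation, ensemble betweenness centrality, group path
#' fractions, radius-of-gyration series, and (optionally) chi1 rotamer
#' occupancies and pocket-volume series. Systems named by
#' \code{config$contrast} are then differenced (RMSF, DCC, per-residue BC
#' effect sizes) and the RoG distributions of all systems are compared
#' with the Kruskal-Wallis omnibus, Conover post hoc and Cohen's d.
#'
#' @param config a \code{comparison_config}.
#' @return list of class \code{comparison_report}; see the fields
#'   \code{per_system}, \code{delta_rmsf}, \code{delta_dcc},
#'   \code{site_profile}, \code{bc_cohens_d}, \code{rog_stats}.
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "comparison_config"))
  sys_names <- names(config$systems)
  per_system <- list()
  for (nm in sys_names) {
    traj <- .prepare_system(config$systems[[nm]], config$discard_ns,
                            config$stride_ps, nm)
    res <- list(trajectory = traj,
                rmsf = rmsf_to_bfactor(residue_rmsf(traj)),
                dcc = dcc_matrix(traj, node_atom = config$node_atom),
                bc = ensemble_bc(traj, cutoff = config$cutoff),
                rog = rog_series(traj))
    if (length(config$groups) > 0L) {
      res$group_fractions <- vapply(config$groups, function(grp) {
        mean(vapply(seq_len(n_frames(traj)), function(f) {
          group_path_fraction(build_residue_graph(get_frame(traj, f),
                                                  config$cutoff), grp)
        }, numeric(1)))
      }, numeric(1))
    }
    if (!is.null(config$chi1_resno)) {
      ser <- chi1_series(traj, config$chi1_resno,
                         quartet = config$chi1_quartet)
      res$chi1 <- ser
      res$rotamer_occupancy <- prop.table(table(factor(
        ser$rotamer, levels = c("gauche-", "gauche+", "anti"))))
    }
    if (!is.null(config$pocket)) {
      res$pocket_volume <- vapply(seq_len(n_frames(traj)), function(f) {
        pocket_volume(get_frame(traj, f), config$pocket)
      }, numeric(1))
    }
    per_system[[nm]] <- res
  }
  ref <- per_system[[config$contrast[1]]]
  oth <- per_system[[config$contrast[2]]]
  ddcc <- delta_dcc(ref$dcc, oth$dcc)
  report <- list(
    config = config,
    per_system = per_system,
    delta_rmsf = delta_rmsf(ref$rmsf, oth$rmsf,
                            threshold = config$delta_rmsf_threshold),
    delta_dcc = ddcc,
    bc_cohens_d = bc_effect_size(ref$bc, oth$bc),
    rog_stats = compare_distributions(lapply(per_system, `[[`, "rog")))
  if (!is.null(config$chi1_resno)) {
    site <- config$chi1_resno
    if (site %in% attr(ddcc, "residues")$resno)
      report$site_profile <- residue_correlation_profile(ddcc, site)
  }
  class(report) <- "comparison_report"
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Comparative dynamics report\n")
  cat("  systems:", paste(names(x$per_system), collapse = ", "), "\n")
  cat(sprintf("  contrast: %s - %s\n", x$config$contrast[1],
              x$config$contrast[2]))
  n_flex <- table(x$delta_rmsf$class)
  cat("  delta-RMSF classes:",
      paste(sprintf("%s=%d", names(n_flex), n_flex), collapse = ", "), "\n")
  cat(sprintf("  RoG Kruskal-Wallis: H = %.4g (df %d), p = %.3g\n",
              x$rog_stats$omnibus$H, x$rog_stats$omnibus$df,
              x$rog_stats$omnibus$p_value))
  invisible(x)
}

#' Write the tabular artifacts of a report to a directory
#'
#' Emits CSV files (per-system RMSF/B-factor profiles, the signed
#' RMSF-difference map with classifications, DCC and difference matrices,
#' per-residue mean betweenness with effect sizes, RoG series) plus a
#' \code{rog_stats.json}-style summary written as CSVs. Output is
#' deterministic given the same report.
#'
#' @param report a \code{comparison_report}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$per_system)) {
    sys <- report$per_system[[nm]]
    utils::write.csv(sys$rmsf, file.path(dir, paste0("rmsf_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(unclass(sys$dcc)),
                     file.path(dir, paste0("dcc_", nm, ".csv")))
    bc <- cbind(sys$bc$residues, mean_bc = sys$bc$mean,
                sd_bc = apply(sys$bc$bc, 2L, stats::sd))
    utils::write.csv(bc, file.path(dir, paste0("bc_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(frame = seq_along(sys$rog), rog_A = sys$rog),
                     file.path(dir, paste0("rog_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(report$delta_rmsf, file.path(dir, "delta_rmsf.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(report$delta_dcc)),
                   file.path(dir, "delta_dcc.csv"))
  utils::write.csv(data.frame(resno = names(report$bc_cohens_d),
                              cohens_d = report$bc_cohens_d),
                   file.path(dir, "bc_cohens_d.csv"), row.names = FALSE)
  utils::write.csv(report$rog_stats$effect_sizes,
                   file.path(dir, "rog_effect_sizes.csv"), row.names = FALSE)
  utils::write.csv(report$rog_stats$posthoc$pairs,
                   file.path(dir, "rog_posthoc.csv"), row.names = FALSE)
  invisible(dir)
}
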