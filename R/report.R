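# One-shot analysis driver chaining every stage for a two-chain
# trajectory, with diff-able tab-separated outputs.

write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full dimer analysis report
#'
#' Chains all stages on one trajectory: RMSD/RMSF of the alpha carbons,
#' dPCA with cumulative variance and per-chain contribution profiles of
#' PC1, the free-energy surface over (V1, V2) with grid clustering,
#' the interface snapshot table with consensus hot spots, and (when glycan
#' residues are present) the typed glycan contact tables.  All outputs are
#' plain tab-separated files under `out_prefix`, plus a machine-readable
#' JSON summary.
#'
#' @param traj a [trajectory] (e.g. from [read_multimodel_pdb()] or
#'   [simulate_dimer()]).
#' @param out_prefix output path prefix (directories are created).
#' @param chain_a,chain_b chain ids.
#' @param times interface snapshot times in ns (clipped to the trajectory
#'   span).
#' @param bins free-energy grid bins per axis.
#' @param cutoff interface distance cutoff (Angstrom).
#' @param temperature kelvin (only used for absolute free-energy units).
#' @param glycan_residues optional data.frame (`chain`, `res_seq`).
#' @return (invisibly) a list with every stage's results and the summary.
#' @export
run_report <- function(traj, out_prefix, chain_a = "A", chain_b = "B",
                       times = c(0, 20, 60, 100, 120, 160, 170),
                       bins = 64L, cutoff = 5.0, temperature = 310,
                       glycan_residues = NULL) {
  if (dirname(out_prefix) != ".")
    dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  pfx <- function(s) paste0(out_prefix, s)

  ca <- select_atoms(traj, atom_names = "CA")
  rmsd_v <- rmsd_series(traj, 1L, ca)
  write_tsv(data.frame(time = traj$times, rmsd = rmsd_v), pfx("_rmsd.tsv"),
            "RMSD (A) of CA atoms to frame 1 after superposition")
  rmsf_v <- rmsf(traj, ca)
  write_tsv(data.frame(atom = names(rmsf_v), rmsf = as.numeric(rmsf_v)),
            pfx("_rmsf.tsv"), "RMSF (A) of CA atoms about the mean structure")

  dih <- compute_dihedrals(traj, chains = c(chain_a, chain_b))
  model <- dpca_fit(dih)
  write_tsv(data.frame(time = traj$times, V1 = model$projections[, 1],
                       V2 = model$projections[, 2]),
            pfx("_projections.tsv"), "dPCA projections onto PC1/PC2")
  contrib <- dpca_contributions(model, 1L)
  write_tsv(contrib, pfx("_contrib_pc1.tsv"),
            "per-angle contribution profile Delta_n(1)")

  surf <- free_energy(fes_density(model$projections[, 1],
                                  model$projections[, 2], bins = bins))
  cmap <- find_clusters(surf)
  frame_labels <- assign_frames(cmap, model$projections[, 1],
                                model$projections[, 2])
  write_tsv(data.frame(time = traj$times, cluster = frame_labels),
            pfx("_clusters.tsv"), "per-frame density-grid cluster labels")

  times_use <- times[times >= min(traj$times) & times <= max(traj$times)]
  if (!length(times_use)) times_use <- traj$times[1]
  iface <- snapshot_report(traj, times_use, chain_a, chain_b, cutoff)
  write_tsv(iface$summary, pfx("_interface.tsv"),
            "per-snapshot interface summary")

  glycans <- NULL
  if (is.null(glycan_residues)) {
    nag <- traj$atoms[traj$atoms$res_name == "NAG", ]
    if (nrow(nag))
      glycan_residues <- unique(data.frame(chain = nag$chain_id,
                                           res_seq = nag$res_seq))
  }
  if (!is.null(glycan_residues) && nrow(glycan_residues)) {
    glycans <- glycan_interactions(traj, which.min(abs(traj$times - times_use[1])),
                                   glycan_residues)
    if (!is.null(glycans))
      write_tsv(glycans, pfx("_glycans.tsv"), "typed glycan-protein contacts")
  }

  summary <- list(
    n_frames = n_frames(traj), n_atoms = n_atoms(traj),
    rmsd_mean = mean(rmsd_v), rmsf_max = max(rmsf_v),
    cumulative_variance_2pc = cumulative_variance(model, 2L),
    contribution_sum_pc1 = sum(contrib$contribution),
    delta_g_at_max_density = {
      am <- which(surf$density == surf$rho_max, arr.ind = TRUE)[1, ]
      surf$delta_g[am[1], am[2]]
    },
    n_clusters = cmap$n_clusters,
    cluster1_population = sum(frame_labels == 1L),
    hotspots_a = iface$hotspots$residues_a,
    hotspots_b = iface$hotspots$residues_b,
    interface_area_mean = mean(iface$summary$interface_area))
  jsonlite::write_json(summary, pfx("_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(rmsd = rmsd_v, rmsf = rmsf_v, dpca = model, surface = surf,
                 clusters = cmap, frame_labels = frame_labels,
                 interface = iface, glycans = glycans, summary = summary))
}
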