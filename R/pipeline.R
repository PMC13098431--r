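# End-to-end orchestration: simulate (or read) -> census -> torsion ->
# pucker -> landscape -> report.  All numeric outputs are plain TSV with a
# commented header echoing the effective configuration, so repeated runs with
# the same config and seed agree byte-for-byte.

write_tsv_report <- function(df, path, header_lines) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full ensemble-analysis pipeline
#'
#' Generates a synthetic ensemble (or reads a supplied trajectory), runs the
#' plausibility census, the contact censuses under both denominators, the
#' pyrophosphate-torsion statistics, the puckering analysis and the
#' two-dimensional free-energy landscape (torsion x catalytic-base distance),
#' and writes per-stage TSV outputs plus a human-readable summary into
#' `out_dir`.  The pipeline is a pure function of (inputs, config, seed):
#' reruns with the same arguments produce byte-identical numeric outputs.
#'
#' @param config a [synthetic_config()] / [synthetic_preset()], or a list
#'   with elements `topology` (path), `trajectory` (path) and `format` plus
#'   `bindings` (role map for [default_sdr_criteria()]) to analyse external
#'   data.
#' @param out_dir output directory (created if missing).
#' @param seed optional integer overriding the config seed.
#' @param temperature kelvin, for the free-energy surface (default 333).
#' @param binwidth_dihedral degrees (default 5).
#' @param binwidth_distance Angstrom (default 0.25).
#' @param max_basin_F report basins up to this free energy (kcal/mol).
#' @return Invisibly, a list with the stage results (`census`, `contacts`,
#'   `dihedral`, `pucker`, `surface`, `basins`, `hydride`, `config`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, temperature = 333,
                         binwidth_dihedral = 5, binwidth_distance = 0.25,
                         max_basin_F = 5) {
  if (inherits(config, "synthetic_config")) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    ens <- generate_ensemble(config)
    traj <- ens$trajectory
    truth <- ens$truth
    bindings <- synthetic_bindings()
    contact_list <- list(
      contact_spec("asn_cg", atom_select(resname = "ASN", name = "CG"),
                   atom_select(resname = "HEX", name = c("O3", "O4")),
                   cutoff = config$contacts$asn_cg$cutoff,
                   denominator = "plausible-frames"),
      contact_spec("gln_cd", atom_select(resname = "GLN", name = "CD"),
                   atom_select(resname = "HEX", name = c("O3", "O4")),
                   cutoff = config$contacts$gln_cd$cutoff),
      contact_spec("val_o", atom_select(resname = "VAL", name = "O"),
                   atom_select(resname = "HEX", name = c("O3", "O4")),
                   cutoff = config$contacts$val_o$cutoff),
      contact_spec("met_o", atom_select(resname = "MET", name = "O"),
                   atom_select(resname = "HEX", name = c("O3", "O4")),
                   cutoff = config$contacts$met_o$cutoff))
    dihedral_sel <- lapply(c("O1", "P1", "O12", "P2"), function(nm)
      atom_select(resname = "CDP", name = nm))
    ring_sel <- atom_select(resname = "PYR")
    hydride_roles <- list(c2 = atom_select(resname = "HEX", name = "C2"),
                          h2 = atom_select(resname = "HEX", name = "H2"),
                          nad_c4 = atom_select(resname = "NAD", name = "C4"))
  } else if (is.list(config) && !is.null(config$trajectory)) {
    for (p in c(config$topology, config$trajectory))
      if (!is.null(p) && !file.exists(p))
        stop("configuration error: input path does not exist: ", p,
             call. = FALSE)
    if (is.null(config$bindings))
      stop("configuration error: external input needs a `bindings` role map",
           call. = FALSE)
    base <- read_structure(config$topology, format = "pdb")
    traj <- read_trajectory(base$topology, config$trajectory,
                            format = config$format %||% "xyz")
    truth <- NULL
    bindings <- config$bindings
    contact_list <- config$contacts %||% list()
    dihedral_sel <- config$dihedral_selection
    ring_sel <- config$ring_selection
    hydride_roles <- config$hydride_roles
  } else {
    stop("configuration error: `config` must be a synthetic_config or a ",
         "list with input paths", call. = FALSE)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_echo <- utils::capture.output(utils::str(config, give.attr = FALSE))

  cs <- default_sdr_criteria(bindings)
  cen <- census(traj, cs)

  contacts <- lapply(contact_list, function(sp)
    contact_census(traj, sp, verdicts = cen$verdicts$plausible))

  results <- list(census = cen, contacts = contacts, config = config)

  write_tsv_report(cen$verdicts, file.path(out_dir, "verdicts.tsv"), cfg_echo)

  if (!is.null(dihedral_sel)) {
    idx <- vapply(dihedral_sel, function(s)
      resolve_selection(traj$topology, s)[1L], integer(1))
    series <- traj_dihedral(traj, idx[1L], idx[2L], idx[3L], idx[4L])
    mode <- circular_mode(series, binwidth = binwidth_dihedral)
    cstats <- circular_stats(series)
    results$dihedral <- list(series = series, mode = mode, stats = cstats)
    write_tsv_report(data.frame(frame = seq_along(series),
                                dihedral = series),
                     file.path(out_dir, "dihedral.tsv"), cfg_echo)
    # 2D landscape: torsion x catalytic-base distance (criterion 1)
    surface <- pmf(cv_histogram(series, cen$verdicts[[cs$labels[1L]]],
                                binwidth_x = binwidth_dihedral,
                                binwidth_y = binwidth_distance,
                                circular_x = TRUE),
                   temperature = temperature)
    basins <- find_basins(surface, max_F = max_basin_F)
    results$surface <- surface
    results$basins <- basins
    grid <- expand.grid(x = surface$centers_x, y = surface$centers_y)
    grid$count <- as.vector(surface$counts)
    grid$F <- as.vector(surface$F)
    grid$masked <- as.vector(surface$mask)
    write_tsv_report(grid, file.path(out_dir, "landscape.tsv"), cfg_echo)
    write_tsv_report(basins, file.path(out_dir, "basins.tsv"), cfg_echo)
  }

  if (!is.null(ring_sel)) {
    ps <- pucker_series(traj, ring_sel)
    results$pucker <- ps
    write_tsv_report(ps$frames, file.path(out_dir, "pucker.tsv"), cfg_echo)
  }

  if (!is.null(hydride_roles)) {
    results$hydride <- hydride_angle_stats(
      traj, hydride_roles$c2, hydride_roles$h2, hydride_roles$nad_c4)
  }

  summary_lines <- c(
    "ensemble analysis summary",
    "=========================",
    sprintf("frames: %d", cen$n_frames),
    sprintf("plausible: %d (%.4f%%), Wilson 95%% CI [%.4f%%, %.4f%%]",
            cen$n_plausible, 100 * cen$fraction, 100 * cen$ci["lower"],
            100 * cen$ci["upper"]),
    "per-criterion marginal pass fractions:",
    sprintf("  %-22s %.4f%%", names(cen$marginals), 100 * cen$marginals),
    "contact censuses (both denominators):",
    unlist(lapply(contacts, function(ct) sprintf(
      "  %-8s cutoff %.1f A: %.4f%% of all frames; %.4f%% of plausible",
      ct$label, ct$cutoff, 100 * ct$fraction_all,
      100 * (ct$fraction_plausible %||% NA_real_)))),
    if (!is.null(results$dihedral)) sprintf(
      "torsion mode: %.1f deg (+/- %.1f); circular mean %.1f, R = %.3f",
      results$dihedral$mode$mode, results$dihedral$mode$half_width,
      results$dihedral$stats$mean, results$dihedral$stats$resultant_length),
    if (!is.null(results$pucker)) c(
      "conformer populations:",
      sprintf("  %-5s %.3f%%", names(results$pucker$populations),
              100 * results$pucker$populations)),
    if (!is.null(results$hydride)) sprintf(
      "hydride angle: mean %.1f deg, sd %.1f, max %.1f",
      results$hydride$mean, results$hydride$sd, results$hydride$max),
    if (!is.null(results$basins)) sprintf(
      "basins (F <= %.1f kcal/mol): %d", max_basin_F, nrow(results$basins)),
    "", "effective configuration:", cfg_echo)
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(results)
}
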