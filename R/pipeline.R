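#' Write per-cell CDP tables as TSV with a bin-scheme sidecar
#'
#' Columns `cell_id`, `chrom`, `allele`, `n_contacts`, `bin_0..bin_142` (or
#' `bin_0..bin_13` for rebinned profiles); a sidecar JSON (`<path>.json`)
#' records the bin scheme so profiles are self-describing.
#'
#' @param x a `cdp_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cdp_table <- function(x, path) {
  stopifnot(inherits(x, "cdp_set"))
  m <- as.data.frame(x$counts)
  names(m) <- paste0("bin_", seq_len(ncol(m)) - 1)
  df <- cbind(x$info[, c("cell_id", "chrom", "allele", "n_contacts")], m)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sch <- x$scheme
  side <- if (!is.null(sch$rebinned) && isTRUE(sch$rebinned)) {
    list(rebinned = TRUE, group_size = sch$group_size, n_bins = sch$n_bins,
         parent = list(x0 = sch$parent$x0, step = sch$parent$step,
                       n_bins = sch$parent$n_bins))
  } else {
    list(x0 = sch$x0, step = sch$step, n_bins = sch$n_bins,
         normalized = x$normalized)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All numeric defaults mirror the analysis parameters: QC at 1000 pairs,
#' cis:trans >= 1, 95% purity; per-allele coverage 50 contacts; 10% FPR
#' thresholds from chr1; cell-cycle k-means with k = 4; contact score at
#' 500 kb resolution with 20 Mb arms. Every parameter the method leaves open
#' (quantile rule aside, which is fixed as nearest-rank) is a named key.
#'
#' @param ... overrides of the defaults, as `section = list(key = value)`
#'   or top-level keys (`seed`). Unknown keys are rejected.
#' @return a validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    simulate = list(n_cells = 120, bipartite_fraction = c(0.1, 0.6, 0.85),
                    time_points = NULL,
                    silencing_fraction = c(0.2, 0.8, 0.95),
                    n_min = 200, n_max = 2000, mid_depletion = 0.5,
                    long_boost = 4, mitotic_fraction = 0.03,
                    xi_skew = 0.75),
    qc = list(min_pairs = 1000, min_cis_trans = 1.0, min_purity = 0.95),
    structure = list(fpr = 0.10, mode = "lmd", null_chrom = "chr1",
                     target_chrom = "chrX", min_contacts = 50),
    cellcycle = list(k = 4, seed = 1L),
    score = list(resolution = 500e3, arm = 20e6, edge_exclusion = 10e6,
                 window = 5, polyorder = 2, pseudocount = 1),
    skew = list(fpr = 0.10, pseudocount = 1, min_cells_per_feature = 10,
                min_umis = 10, atac_min_total_umis = 500),
    modalities = list(hic = TRUE, rna = TRUE, atac = TRUE))
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    abort("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(overrides)) {
    if (is.list(defaults[[k]])) {
      bad <- setdiff(names(overrides[[k]]), names(defaults[[k]]))
      if (length(bad))
        abort("unknown config key(s) in '", k, "': ",
              paste(bad, collapse = ", "))
      defaults[[k]][names(overrides[[k]])] <- overrides[[k]]
    } else defaults[[k]] <- overrides[[k]]
  }
  structure(defaults, class = "pipeline_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates simulate -> qc -> cdp -> cell-cycle -> bipartite calling ->
#' contact score -> allelic skew -> report under one config, returning all
#' stage outputs and a reproducibility manifest (config hash, seed,
#' per-stage output checksums, timestamps). Identical config and seed give
#' identical checksums for every stage.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; if given, stage tables are written as
#'   TSV (contacts, CDPs, calls, report).
#' @return list of class `pipeline_run` with elements `truth`, `qc`, `cdp`,
#'   `cellcycle`, `structure_fit`, `score_track`, `dip`, `skew_rna`,
#'   `skew_atac`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  if (!inherits(config, "pipeline_config"))
    abort("config must come from pipeline_config()")
  t0 <- Sys.time()
  manifest <- list(config_checksum = object_checksum(unclass(config)),
                   seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("xcistruct")),
                   stages = list(), started = format(t0, usetz = TRUE))
  sim_cfg <- config$simulate
  cspec <- contact_sim_spec(n_min = sim_cfg$n_min, n_max = sim_cfg$n_max,
                            mid_depletion = sim_cfg$mid_depletion,
                            long_boost = sim_cfg$long_boost,
                            mitotic_fraction = sim_cfg$mitotic_fraction,
                            xi_skew = sim_cfg$xi_skew)
  pop <- simulate_population(cspec, sim_cfg$n_cells,
                             sim_cfg$bipartite_fraction,
                             time_points = sim_cfg$time_points,
                             seed = config$seed)
  time_points <- unique(pop$truth$time_point)
  kspec <- count_sim_spec(xi_skew = sim_cfg$xi_skew)
  rna <- simulate_allelic_counts(kspec, sim_cfg$n_cells,
                                 sim_cfg$silencing_fraction,
                                 time_points = time_points,
                                 seed = config$seed + 1L)
  atac <- simulate_allelic_counts(kspec, sim_cfg$n_cells,
                                  sim_cfg$silencing_fraction,
                                  time_points = time_points,
                                  seed = config$seed + 2L)
  manifest$stages$simulate <- object_checksum(list(pop, rna, atac))
  message(sprintf("[simulate] %d cells, %d contacts, %d time points",
                  nrow(pop$truth), nrow(pop$contacts),
                  length(time_points)))

  # qc: per-cell pair counts from the simulated table (single species)
  cells <- unique(pop$contacts$cell_id)
  cis <- pop$contacts$chrom_a == pop$contacts$chrom_b
  qc <- data.frame(cell_id = cells,
                   n_valid_pairs = as.integer(table(factor(
                     pop$contacts$cell_id, levels = cells))),
                   cis_count = as.integer(table(factor(
                     pop$contacts$cell_id[cis], levels = cells))),
                   trans_count = as.integer(table(factor(
                     pop$contacts$cell_id[!cis], levels = cells))),
                   species_purity = 1, stringsAsFactors = FALSE)
  qc <- filter_cells_qc(qc, config$qc$min_pairs, config$qc$min_cis_trans,
                        config$qc$min_purity)
  keep_cells <- qc$cell_id[qc$pass]
  manifest$stages$qc <- object_checksum(qc)
  message(sprintf("[qc] %d / %d cells pass", length(keep_cells),
                  nrow(qc)))

  inf <- informative_contacts(pop$contacts)
  cdp <- cdp_profiles(inf, chroms = c(config$structure$null_chrom,
                                      config$structure$target_chrom),
                      cells = keep_cells)
  manifest$stages$cdp <- object_checksum(cdp)

  cc <- NULL
  if (isTRUE(config$modalities$hic)) {
    prof <- cellcycle_profile(inf, cells = keep_cells)
    bands <- band_fractions(inf, cells = keep_cells)
    cc <- cluster_cellcycle(prof, bands, k = config$cellcycle$k,
                            seed = config$cellcycle$seed)
    manifest$stages$cellcycle <- object_checksum(cc)
    message(sprintf("[cell-cycle] %d cells staged into %d clusters",
                    nrow(cc), config$cellcycle$k))
  }

  groups <- stats::setNames(pop$truth$time_point, pop$truth$cell_id)
  fit <- xci_classifier(cdp, mode = config$structure$mode,
                        fpr = config$structure$fpr,
                        null_chrom = config$structure$null_chrom,
                        target_chrom = config$structure$target_chrom,
                        min_contacts = config$structure$min_contacts,
                        groups = groups)
  manifest$stages$structure <- object_checksum(fit$calls)
  message(sprintf("[call-bipartite] threshold %.4g, %d / %d called",
                  fit$threshold$threshold,
                  sum(fit$calls$is_bipartite, na.rm = TRUE),
                  sum(!is.na(fit$calls$is_bipartite))))

  # pseudobulk Xi contact map of bipartite-called cells -> contact score
  score_track <- NULL; dip <- NULL
  called <- fit$calls[!is.na(fit$calls$is_bipartite) &
                        fit$calls$is_bipartite, ]
  if (nrow(called) >= 5) {
    xi_key <- paste(called$cell_id, called$xi_allele)
    sel <- paste(inf$cell_id, inf$allele) %in% xi_key &
      inf$chrom_a == config$structure$target_chrom &
      inf$chrom_b == config$structure$target_chrom
    xi_tab <- structure(as.data.frame(inf[sel, , drop = FALSE]),
                        genome = attr(inf, "genome"),
                        class = c("contact_table", "data.frame"))
    bm <- bin_contacts(xi_tab, config$structure$target_chrom,
                       config$score$resolution)
    score_track <- contact_score(bm, attr(inf, "genome"),
                                 arm = config$score$arm,
                                 pseudocount = config$score$pseudocount,
                                 edge_exclusion = config$score$edge_exclusion,
                                 window = config$score$window,
                                 polyorder = config$score$polyorder)
    hinge <- cspec$boundary_frac *
      chrom_length(cspec$genome, config$structure$target_chrom)
    dip <- locate_dip(score_track, hinge)
    manifest$stages$score <- object_checksum(score_track)
    message(sprintf("[contact-score] dip near hinge at bin %s (depth %.3f)",
                    dip$bin, dip$depth))
  }

  skew_rna <- skew_atac <- NULL
  if (isTRUE(config$modalities$rna)) {
    skew_rna <- skew_classifier(rna$counts, "rna", fpr = config$skew$fpr,
                                pseudocount = config$skew$pseudocount,
                                min_cells_per_feature =
                                  config$skew$min_cells_per_feature,
                                min_umis_per_allele_per_chrom =
                                  config$skew$min_umis,
                                groups = stats::setNames(
                                  rna$truth$time_point, rna$truth$cell_id))
    manifest$stages$skew_rna <- object_checksum(skew_rna$calls)
  }
  if (isTRUE(config$modalities$atac)) {
    skew_atac <- skew_classifier(atac$counts, "atac",
                                 fpr = config$skew$fpr,
                                 pseudocount = config$skew$pseudocount,
                                 min_cells_per_feature =
                                   config$skew$min_cells_per_feature,
                                 min_umis_per_allele_per_chrom =
                                   config$skew$min_umis,
                                 min_total_umis =
                                   config$skew$atac_min_total_umis,
                                 groups = stats::setNames(
                                   atac$truth$time_point,
                                   atac$truth$cell_id))
    manifest$stages$skew_atac <- object_checksum(skew_atac$calls)
  }

  mods <- list()
  if (!is.null(skew_rna)) mods$rna <- skew_rna
  if (!is.null(skew_atac)) mods$atac <- skew_atac
  mods$hic <- fit
  report <- list(timecourse = silencing_timecourse(mods),
                 bipartite_by_group = proportion_bipartite(fit$calls))
  manifest$stages$report <- object_checksum(report)
  manifest$finished <- format(Sys.time(), usetz = TRUE)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_contacts(pop$contacts, file.path(outdir, "contacts.pairs.tsv"))
    write_cdp_table(cdp, file.path(outdir, "cdp.tsv"))
    utils::write.table(fit$calls, file.path(outdir, "bipartite_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$timecourse,
                       file.path(outdir, "timecourse.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(score_track))
      write_contact_score(score_track,
                          file.path(outdir, "contact_score.bedgraph"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  structure(list(truth = pop$truth, qc = qc, cdp = cdp, cellcycle = cc,
                 structure_fit = fit, score_track = score_track, dip = dip,
                 skew_rna = skew_rna, skew_atac = skew_atac,
                 report = report, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run (seed", x$manifest$seed, ")\n")
  cat("\nJoint time course (% of callable cells per modality):\n")
  print(x$report$timecourse, row.names = FALSE, digits = 3)
  invisible(x)
}
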