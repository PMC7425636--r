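# Orchestration layer: each run_*() resolves a config against the standard
# defaults, runs one module, writes its outputs plus a JSON report and the
# resolved config, and returns the report invisibly.

#' Default run configuration
#'
#' Defaults are the analysis' standard parameters: 1 Mb bins, a 5 Mb
#' minimum separation for CCF, modularity gamma 1.0, 10 Mb correlation
#' windows, the human 15-state grouping, and seed 1.
#'
#' @param ... overrides for individual fields.
#' @return a named list.
#' @export
run_config <- function(...) {
  cfg <- list(bin_size = 1e6, min_separation = 5e6, gamma = 1.0,
              window_bp = 1e7, grouping = "human15", n_perm = 200,
              seed = 1, outdir = ".")
  utils::modifyList(cfg, list(...))
}

resolve_config <- function(config, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(run_config(), config)
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  cfg
}

write_run_artifacts <- function(cfg, report, name) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$outdir, paste0(name, "_config.yaml")))
  jsonlite::write_json(report,
                       file.path(cfg$outdir, paste0(name, "_report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

load_matrix_inputs <- function(cfg) {
  bins <- read_bin_table_bed(cfg$bins)
  cm <- read_dense_matrix(cfg$matrix, bins)
  mask_empty_bins(cm)
}

#' Simulate a synthetic study and write its inputs to disk
#'
#' Writes the bin table (BED3+gc), the dense contact matrix, the state
#' segmentation (BED4), the ground truth table and a JSON report.
#'
#' @param config list or YAML path; `...` overrides. Relevant fields: `seed`,
#'   `outdir`, plus any [sim_spec()] parameter under `sim` (a list).
#' @return the report, invisibly.
#' @export
run_simulate <- function(config = list(), ...) {
  cfg <- resolve_config(config, ...)
  spec <- do.call(sim_spec, c(cfg$sim, list(seed = cfg$seed)))
  g <- generate_genome(spec)
  hic <- generate_hic(g)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write_bin_table_bed(g$bins, file.path(cfg$outdir, "bins.bed"))
  write_dense_matrix(hic, file.path(cfg$outdir, "matrix.tsv"))
  utils::write.table(as.data.frame(g$states),
                     file.path(cfg$outdir, "states.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(g$bins[, c("chrom", "start", "end")], g$truth),
                     file.path(cfg$outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- list(n_bins = n_bins(g$bins), seed = cfg$seed,
                 n_chromosomes = length(spec$chrom_lengths),
                 total_counts = sum(hic$counts) / 2)
  write_run_artifacts(cfg, report, "simulate")
}

#' Compute CCF tracks from a contact matrix on disk
#'
#' @param config list or YAML path with `matrix`, `bins`, `min_separation`,
#'   `outdir`; `...` overrides.
#' @return the report, invisibly.
#' @export
run_ccf <- function(config = list(), ...) {
  cfg <- resolve_config(config, ...)
  cm <- load_matrix_inputs(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(n_bins = n_bins(cm$bins),
                 n_masked = sum(cm$bins$masked))
  for (scope in c("total", "inter_chromosomal")) {
    ccf <- compute_ccf(cm, scope, cfg$min_separation)
    write_bedgraph(ccf_track(ccf, "raw"),
                   file.path(cfg$outdir, paste0("ccf_", scope, "_raw.bedgraph")))
    write_bedgraph(ccf_track(ccf, "percent"),
                   file.path(cfg$outdir,
                             paste0("ccf_", scope, "_percent.bedgraph")))
    report[[paste0("max_raw_", scope)]] <- max(ccf$raw, na.rm = TRUE)
  }
  report$min_separation <- cfg$min_separation
  write_run_artifacts(cfg, report, "ccf")
}

#' Call A/B compartments from a contact matrix on disk
#'
#' @param config list or YAML path with `matrix`, `bins`, `outdir`; the GC
#'   column of the bin table orients PC1.
#' @return the report (including the PVE), invisibly.
#' @export
run_compartments <- function(config = list(), ...) {
  cfg <- resolve_config(config, ...)
  cm <- load_matrix_inputs(cfg)
  gc_track <- genomic_track(cm$bins, cm$bins$gc, "gc")
  comp <- compartment_pipeline(cm, gc_track)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write_compartments(comp,
                     file.path(cfg$outdir, "compartments_pc1.bedgraph"),
                     file.path(cfg$outdir, "compartments.bed"))
  report <- list(pve = comp$pve,
                 n_A = sum(comp$label == "A", na.rm = TRUE),
                 n_B = sum(comp$label == "B", na.rm = TRUE),
                 orientation_reference = comp$orientation_reference)
  write_run_artifacts(cfg, report, "compartments")
}

#' Call TADs from a contact matrix on disk
#'
#' @param config list or YAML path with `matrix`, `bins`, `gamma`, `outdir`.
#' @return the report, invisibly.
#' @export
run_tads <- function(config = list(), ...) {
  cfg <- resolve_config(config, ...)
  cm <- load_matrix_inputs(cfg)
  seg <- call_tads(cm, cfg$gamma)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write_tads_bed(seg, file.path(cfg$outdir, "tads.bed"))
  report <- list(gamma = cfg$gamma,
                 n_tads = sum(seg$label == "TAD"),
                 n_intertad_segments = sum(seg$label == "interTAD"),
                 mean_tad_bins = mean(seg$n_bins[seg$label == "TAD"]))
  write_run_artifacts(cfg, report, "tads")
}

#' Bin a chromatin-state segmentation and write grouped tracks
#'
#' @param config list or YAML path with `states` (BED4), `bins`, `grouping`,
#'   `outdir`.
#' @return the report, invisibly.
#' @export
run_states <- function(config = list(), ...) {
  cfg <- resolve_config(config, ...)
  bins <- read_bin_table_bed(cfg$bins)
  grouping <- state_grouping(cfg$grouping)
  seg <- read_state_bed(cfg$states, catalog = names(grouping))
  cov <- bin_state_coverage(seg, bins)
  grp <- group_fractions(cov, grouping)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write_state_coverage(cov, file.path(cfg$outdir, "state_coverage.tsv"))
  write_bedgraph(grp$active, file.path(cfg$outdir, "active.bedgraph"))
  write_bedgraph(grp$inactive, file.path(cfg$outdir, "inactive.bedgraph"))
  report <- list(n_states = ncol(cov$fractions),
                 n_annotated = sum(cov$annotated),
                 mean_active = mean(grp$active$value, na.rm = TRUE))
  write_run_artifacts(cfg, report, "states")
}

#' Correlate CCF with chromatin-state tracks
#'
#' Builds the standard correlation-heatmap report (states x states + total and
#' inter-chromosomal CCF) and the key CCF-activity coefficients, including
#' the confounder-controlled variants.
#'
#' @param config list or YAML path with `matrix`, `bins`, `states`,
#'   `grouping`, `min_separation`, `outdir`.
#' @return the report, invisibly.
#' @export
run_correlate <- function(config = list(), ...) {
  cfg <- resolve_config(config, ...)
  cm <- load_matrix_inputs(cfg)
  grouping <- state_grouping(cfg$grouping)
  seg <- read_state_bed(cfg$states, catalog = names(grouping))
  cov <- bin_state_coverage(seg, cm$bins)
  grp <- group_fractions(cov, grouping)
  ccf_tot <- compute_ccf(cm, "total", cfg$min_separation)
  ccf_int <- compute_ccf(cm, "inter_chromosomal", cfg$min_separation)
  tracks <- c(state_tracks(cov),
              list(ccf_total = ccf_track(ccf_tot, "percent"),
                   ccf_inter = ccf_track(ccf_int, "percent")))
  rep_genome <- correlation_report(tracks, "genome")
  gc_track <- genomic_track(cm$bins, cm$bins$gc, "gc")
  report <- list(
    ccf_active_r = pearson(ccf_track(ccf_tot, "percent"), grp$active),
    ccf_inactive_r = pearson(ccf_track(ccf_tot, "percent"), grp$inactive),
    ccf_active_r_gc_regressed =
      if (all(is.na(cm$bins$gc))) NA else
        pearson(regress_out_gc(ccf_tot, gc_track), grp$active),
    n_bins_used = sum(!cm$bins$masked & cov$annotated))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(round(rep_genome$r, 6),
                     file.path(cfg$outdir, "correlation_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  write_run_artifacts(cfg, report, "correlate")
}

#' Compare CCF across a synteny map between two genomes
#'
#' @param config list or YAML path with `matrix_a`, `bins_a`, `matrix_b`,
#'   `bins_b`, `map` (7-column TSV), `min_separation`, `outdir`. Chromosome
#'   classes follow the numeric large/small rule unless `classes_a` /
#'   `classes_b` (named lists) are given.
#' @return the report (per-class-pair correlations), invisibly.
#' @export
run_synteny <- function(config = list(), ...) {
  cfg <- resolve_config(config, ...)
  bins_a <- read_bin_table_bed(cfg$bins_a)
  bins_b <- read_bin_table_bed(cfg$bins_b)
  cm_a <- mask_empty_bins(read_dense_matrix(cfg$matrix_a, bins_a))
  cm_b <- mask_empty_bins(read_dense_matrix(cfg$matrix_b, bins_b))
  map <- read_synteny_map(cfg$map)
  ccf_a <- compute_ccf(cm_a, "total", cfg$min_separation)
  ccf_b <- compute_ccf(cm_b, "total", cfg$min_separation)
  mk_classes <- function(bins, override) {
    if (!is.null(override)) chrom_size_class(chrom_order_of(bins),
                                             mapping = unlist(override))
    else chrom_size_class(chrom_order_of(bins))
  }
  cls_a <- mk_classes(bins_a, cfg$classes_a)
  cls_b <- mk_classes(bins_b, cfg$classes_b)
  tab <- syntenic_ccf_table(ccf_a, ccf_b, map, cls_a, cls_b)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(tab, file.path(cfg$outdir, "syntenic_ccf.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pairs <- expand.grid(a = c("large", "small"), b = c("large", "small"),
                       stringsAsFactors = FALSE)
  report <- list()
  for (i in seq_len(nrow(pairs))) {
    sel <- tab[tab$class_a == pairs$a[i] & tab$class_b == pairs$b[i], ]
    key <- paste0("r_", substr(pairs$a[i], 1, 1), substr(pairs$b[i], 1, 1))
    report[[key]] <- if (nrow(sel) >= 3) stats::cor(sel$a, sel$b) else NA
    report[[paste0("n_", substr(pairs$a[i], 1, 1),
                   substr(pairs$b[i], 1, 1))]] <- nrow(sel)
  }
  write_run_artifacts(cfg, report, "synteny")
}
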