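#' Pipeline run configuration
#'
#' One flat configuration object drives the command-style entry points
#' (`cmd_*`): input/output paths, the population design, filtering and
#' region-calling thresholds, the selection-coefficient grid and the seed. It
#' serialises to YAML, and every `cmd_*` call writes the resolved
#' configuration and package version next to its outputs for provenance.
#'
#' @param genotypes,metadata,genes Input paths (genotype TSV/VCF, sample
#'   metadata TSV, GFF3 gene annotation).
#' @param outdir Output directory.
#' @param population Population label scanned/simulated.
#' @param Ne Effective population size.
#' @param years,n_diploid Sampling events (see [population_design()]); `years`
#'   may be a list with pooled-year events.
#' @param generation_time Years per generation.
#' @param maf,het,overall_min,sample_min,strict_min,n_strict,r2,window_snps,window_bp
#'   Filtering thresholds (see [run_filters()]).
#' @param p1,p2,merge_bp,gene_dist Region-calling and annotation thresholds.
#' @param s_grid Selection-coefficient grid.
#' @param sim_s,sim_n_snps,sim_prop_selected,sim_missing_rate,sim_ld_block,p0_law,alpha,n_reps
#'   Simulation / power-experiment settings.
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(genotypes = NULL, metadata = NULL, genes = NULL,
                       outdir = ".", population = "FN", Ne = 34,
                       years = list(1999, c(2012, 2013)),
                       n_diploid = c(29, 20), generation_time = 2,
                       maf = 0.01, het = 0.5, overall_min = 1 / 3,
                       sample_min = 1 / 3, strict_min = 1 / 2, n_strict = 2,
                       r2 = 0.99, window_snps = 20, window_bp = 50000,
                       p1 = 1e-4, p2 = 1e-2, merge_bp = 100000,
                       gene_dist = 100000, s_grid = s_grid_default(),
                       sim_s = 0.5, sim_n_snps = 100, sim_prop_selected = 0,
                       sim_missing_rate = 0, sim_ld_block = 1,
                       p0_law = c(0.1, 0.9), alpha = 0.01, n_reps = 1000,
                       seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file to read or write.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$years <- lapply(cfg$years, unlist)
  for (f in c("n_diploid", "s_grid", "p0_law")) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  }
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.cfg_design <- function(cfg) {
  population_design(cfg$population, cfg$Ne, cfg$years, cfg$n_diploid,
                    cfg$generation_time)
}

.stamp <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(cfg, file.path(outdir, "run_config.yaml"))
  writeLines(paste0("driftscan ", as.character(packageVersion("driftscan"))),
             file.path(outdir, "VERSION"))
}

.read_panel <- function(cfg) {
  if (is.null(cfg$genotypes) || is.null(cfg$metadata)) {
    abort("config must set `genotypes` and `metadata` paths.")
  }
  if (grepl("\\.vcf(\\.gz)?$", cfg$genotypes)) {
    read_geno_vcf(cfg$genotypes, cfg$metadata)
  } else {
    read_geno_tsv(cfg$genotypes, cfg$metadata)
  }
}

#' Command-style pipeline entry points
#'
#' Thin file-in/file-out wrappers binding the pipeline together; each maps to
#' one subcommand of the `inst/cli/driftscan.R` script and writes its outputs
#' plus the resolved configuration into `cfg$outdir`.
#'
#' * `cmd_simulate()`: synthetic panel -> `genotypes.tsv`, `samples.tsv`,
#'   `truth.tsv`.
#' * `cmd_filter()`: four-step SNP filtering -> `filtered_genotypes.tsv`,
#'   `filter_report.tsv`.
#' * `cmd_scan()`: per-SNP selection test -> `scan.tsv`.
#' * `cmd_regions()`: signature calling -> `signatures.bed`.
#' * `cmd_annotate()`: gene annotation of signatures -> `signatures_annotated.bed`.
#' * `cmd_power()`: power / false-positive experiment -> `power_report.tsv`.
#'
#' @param cfg A [run_config].
#' @return The main result object of the step, invisibly.
#' @name cmd
NULL

#' @rdname cmd
#' @export
cmd_simulate <- function(cfg) {
  design <- .cfg_design(cfg)
  sc <- sim_config(design, s = cfg$sim_s, p0_law = cfg$p0_law,
                   n_snps = cfg$sim_n_snps,
                   prop_selected = cfg$sim_prop_selected,
                   missing_rate = cfg$sim_missing_rate,
                   ld_block_size = cfg$sim_ld_block, seed = cfg$seed)
  sim <- simulate_panel(sc)
  .stamp(cfg, cfg$outdir)
  write_geno_tsv(sim$panel, file.path(cfg$outdir, "genotypes.tsv"),
                 file.path(cfg$outdir, "samples.tsv"))
  write_truth_tsv(sim$truth, file.path(cfg$outdir, "truth.tsv"))
  message("simulated ", n_snps(sim$panel), " SNPs x ",
          nrow(sim$panel$genotypes), " individuals -> ", cfg$outdir)
  invisible(sim)
}

#' @rdname cmd
#' @export
cmd_filter <- function(cfg) {
  panel <- .read_panel(cfg)
  out <- run_filters(panel, maf = cfg$maf, het = cfg$het,
                     overall_min = cfg$overall_min,
                     sample_min = cfg$sample_min,
                     strict_min = cfg$strict_min, n_strict = cfg$n_strict,
                     r2_threshold = cfg$r2, window_snps = cfg$window_snps,
                     window_bp = cfg$window_bp)
  .stamp(cfg, cfg$outdir)
  write_geno_tsv(out$panel, file.path(cfg$outdir, "filtered_genotypes.tsv"),
                 file.path(cfg$outdir, "filtered_samples.tsv"))
  readr::write_tsv(select(as_tibble(out$report), -"removed_snps"),
                   file.path(cfg$outdir, "filter_report.tsv"))
  message("filtering: ", out$report$n_in[1], " -> ",
          out$report$n_out[nrow(out$report)], " SNPs")
  invisible(out)
}

#' @rdname cmd
#' @export
cmd_scan <- function(cfg) {
  panel <- .read_panel(cfg)
  scan <- scan_population(panel, .cfg_design(cfg), grid = cfg$s_grid)
  .stamp(cfg, cfg$outdir)
  write_scan_tsv(scan, file.path(cfg$outdir, "scan.tsv"))
  message("scanned ", nrow(scan), " SNPs (",
          sum(scan$pvalue < cfg$p2), " at p < ", cfg$p2, ")")
  invisible(scan)
}

#' @rdname cmd
#' @export
cmd_regions <- function(cfg) {
  scan <- read_scan_tsv(file.path(cfg$outdir, "scan.tsv"))
  sig <- call_signatures(scan, p1 = cfg$p1, p2 = cfg$p2,
                         merge_bp = cfg$merge_bp)
  .stamp(cfg, cfg$outdir)
  write_signatures_bed(sig, file.path(cfg$outdir, "signatures.bed"))
  message(nrow(sig), " signature(s) of selection called")
  invisible(sig)
}

#' @rdname cmd
#' @export
cmd_annotate <- function(cfg) {
  if (is.null(cfg$genes)) abort("config must set the `genes` GFF3 path.")
  sig <- read_signatures_bed(file.path(cfg$outdir, "signatures.bed"))
  genes <- read_gff_genes(cfg$genes)
  known <- genes$scaffold %in% unique(sig$scaffold)
  if (nrow(sig) && !all(known) && any(known)) {
    message(sum(!known), " gene(s) on scaffolds without signatures ignored")
  }
  sig <- annotate_genes(sig, genes, max_dist = cfg$gene_dist)
  .stamp(cfg, cfg$outdir)
  write_signatures_bed(sig, file.path(cfg$outdir, "signatures_annotated.bed"))
  invisible(sig)
}

#' @rdname cmd
#' @export
cmd_power <- function(cfg) {
  pw <- power_experiment(design = .cfg_design(cfg), s = cfg$sim_s,
                         p0_law = cfg$p0_law, alpha = cfg$alpha,
                         n_reps = cfg$n_reps, grid = cfg$s_grid,
                         seed = cfg$seed)
  .stamp(cfg, cfg$outdir)
  readr::write_tsv(as_tibble(pw), file.path(cfg$outdir, "power_report.tsv"))
  g <- glance(pw)
  message(sprintf("power = %.3f, FPR = %.3f at alpha = %g (%d replicates/arm)",
                  g$power, g$fpr, g$alpha, g$n_reps))
  invisible(pw)
}
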