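#' Assemble a pipeline configuration
#'
#' Collects the parameters of every stage into one list: simulation settings
#' (see [sim_config()]), call filtering and CNVR compilation thresholds,
#' permutation test settings, association scan settings, and qPCR assay
#' selection. All stage randomness derives from the single root `seed`. A
#' YAML snapshot of the configuration is written alongside the outputs of
#' every run.
#'
#' @param outdir Output directory of the run.
#' @param seed Root seed.
#' @param sim,compile,overlap,assoc,qpcr Named lists overriding stage
#'   defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L, sim = list(),
                            compile = list(), overlap = list(),
                            assoc = list(), qpcr = list()) {
  merge_into <- function(defaults, over) {
    stopifnot(all(names(over) %in% names(defaults)))
    defaults[names(over)] <- over
    defaults
  }
  cfg <- list(
    outdir = outdir,
    seed = as.integer(seed),
    sim = sim,  # forwarded to sim_config(); validated there
    compile = merge_into(list(
      min_len_bp = 5000, max_calls_per_sample = 150, autosomes_only = TRUE,
      population_size = NULL, recurrence = 0.1,
      polymorphic_threshold = 0.01, fixed_freq_threshold = 0.75,
      fixed_state_fraction = 0.95), compile),
    overlap = merge_into(list(
      n_perm = 1000, measure = "region_count", max_len_bp = 1e6,
      n_genes = 500, n_qtls = 200, gene_placement = "avoid_loci",
      qtl_placement = "uniform"), overlap),
    assoc = merge_into(list(
      min_dev = 0.05, identity_frac = 0.95, window_bp = 450000), assoc),
    qpcr = merge_into(list(
      n_loci = 10, n_samples = 30, drop_outlier_replicate = FALSE), qpcr))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] arguments: top-level `outdir`
#' and `seed` plus optional `sim`, `compile`, `overlap`, `assoc`, `qpcr`
#' sections.
#'
#' @param path Path to the YAML file.
#' @param outdir,seed Optional overrides of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    outdir = outdir %||% y$outdir %||% ".",
    seed = seed %||% y$seed %||% 1L,
    sim = y$sim %||% list(), compile = y$compile %||% list(),
    overlap = y$overlap %||% list(), assoc = y$assoc %||% list(),
    qpcr = y$qpcr %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_line <- function(config, ..., verbose = TRUE) {
  msg <- paste0(...)
  if (verbose) message(msg)
  cat(msg, "\n", sep = "", file = file.path(config$outdir, "run_log.txt"),
      append = TRUE)
}

snapshot_config <- function(config) {
  plain <- unclass(config)
  yaml::write_yaml(plain, file.path(config$outdir, "config_snapshot.yaml"))
}

data_dir <- function(config) file.path(config$outdir, "data")

#' Pipeline stage: simulate a dataset
#'
#' Generates the synthetic population, phenotypes, annotation tracks (genes
#' placed away from the CNV loci, QTLs uniformly) and qPCR plates, and
#' writes them under `<outdir>/data/` in the plain-text formats the other
#' stages read.
#'
#' @param config A `pipeline_config`.
#' @param verbose Echo log lines to the console.
#' @return Invisibly, the dataset directory.
#' @export
cmd_simulate <- function(config, verbose = TRUE) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  snapshot_config(config)
  sc <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  sim <- simulate_population(sc)
  phen <- simulate_phenotype(sim$truth, sc)
  dd <- write_dataset(sim, data_dir(config), phenotypes = phen)
  genes <- simulate_annotation(sim$genome, sim$truth,
                               n_intervals = config$overlap$n_genes,
                               placement = config$overlap$gene_placement,
                               seed = config$seed, label = "gene")
  qtls <- simulate_annotation(sim$genome, sim$truth,
                              n_intervals = config$overlap$n_qtls,
                              placement = config$overlap$qtl_placement,
                              seed = config$seed + 1L, label = "qtl")
  write_bed_track(genes, file.path(dd, "genes.bed"))
  write_bed_track(qtls, file.path(dd, "qtls.bed"))
  n_loci <- min(config$qpcr$n_loci, nrow(sim$truth$loci))
  n_samp <- min(config$qpcr$n_samples, length(sim$truth$sample_ids))
  plate <- simulate_qpcr(sim$truth, loci = seq_len(n_loci),
                         samples = sim$truth$sample_ids[seq_len(n_samp)],
                         config = sc)
  write_qpcr_plate(plate, file.path(dd, "qpcr_plate.tsv"))
  log_line(config, "simulate: ", nrow(sim$calls), " calls, ",
           nrow(sim$truth$loci), " loci, ", sc$n_animals, " animals",
           verbose = verbose)
  invisible(dd)
}

read_dataset <- function(config) {
  dd <- data_dir(config)
  need <- c("calls.rawcnv", "chrom.sizes", "probes.tsv", "phenotypes.tsv")
  for (f in need) {
    if (!file.exists(file.path(dd, f))) {
      stop("missing input '", file.path(dd, f),
           "'; run cmd_simulate() first or point outdir at a dataset")
    }
  }
  genome <- read_chrom_sizes(file.path(dd, "chrom.sizes"))
  list(genome = genome,
       calls = read_penncnv_calls(file.path(dd, "calls.rawcnv")),
       probe_map = read_probe_map(file.path(dd, "probes.tsv"), genome),
       phenotypes = read_phenotypes(file.path(dd, "phenotypes.tsv")))
}

#' Pipeline stage: compile CNV regions
#'
#' Reads the dataset, applies call-level QC, compiles CNVRs, classifies
#' polymorphic regions, flags fixed-state high-frequency regions, and writes
#' `cnvr.bed`, `cnvr_summary.tsv`, `cnvr_length_hist.tsv`, `qc_report.tsv`
#' and the filtered calls (`calls_filtered.rawcnv`).
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the compiled `cnv_regions`.
#' @export
cmd_compile <- function(config, verbose = TRUE) {
  ds <- read_dataset(config)
  cc <- config$compile
  fr <- filter_calls(ds$calls, ds$genome, min_len_bp = cc$min_len_bp,
                     max_calls_per_sample = cc$max_calls_per_sample,
                     autosomes_only = cc$autosomes_only)
  pop <- cc$population_size %||% length(unique(ds$calls$sample_id))
  reg <- compile_cnvrs(fr$calls, ds$genome, population_size = pop,
                       recurrence = cc$recurrence)
  reg <- classify_polymorphic(reg, threshold = cc$polymorphic_threshold)
  reg <- flag_fixed_state(reg, fr$calls,
                          freq_threshold = cc$fixed_freq_threshold,
                          state_fraction = cc$fixed_state_fraction)
  out <- config$outdir
  write_qc_report(fr$qc, file.path(out, "qc_report.tsv"))
  write_penncnv_calls(fr$calls, file.path(out, "calls_filtered.rawcnv"))
  write_regions_bed(reg, file.path(out, "cnvr.bed"))
  write_region_summary(summarize_regions(reg, ds$genome),
                       file.path(out, "cnvr_summary.tsv"))
  write_length_histogram(length_histogram(reg),
                         file.path(out, "cnvr_length_hist.tsv"))
  log_line(config, "compile: ", fr$qc$n_output_calls, "/",
           fr$qc$n_input_calls, " calls kept, ", nrow(reg), " CNVRs (",
           sum(reg$polymorphic), " polymorphic)", verbose = verbose)
  invisible(reg)
}

read_compiled_regions <- function(config) {
  path <- file.path(config$outdir, "cnvr.bed")
  if (!file.exists(path)) {
    stop("missing '", path, "'; run cmd_compile() first")
  }
  read_bed_track(path, label = "cnvr")
}

#' Pipeline stage: permutation overlap tests
#'
#' Tests the compiled CNVRs against the gene and QTL tracks with the
#' permutation overlap test, one row per track and measure, and writes
#' `overlap_permutation.tsv`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the results data.frame.
#' @export
cmd_overlap <- function(config, verbose = TRUE) {
  reg <- read_compiled_regions(config)
  ds <- read_dataset(config)
  dd <- data_dir(config)
  tracks <- list(genes = read_bed_track(file.path(dd, "genes.bed"), "genes"),
                 qtls = read_bed_track(file.path(dd, "qtls.bed"), "qtls"))
  res <- do.call(rbind, lapply(c("region_count", "total_bp"), function(m) {
    permutation_overlap_batch(reg, tracks, ds$genome, seed = config$seed,
                              n_perm = config$overlap$n_perm, measure = m,
                              max_len_bp = config$overlap$max_len_bp)
  }))
  utils::write.table(res, file.path(config$outdir,
                                    "overlap_permutation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line(config, "overlap: ", nrow(res), " permutation tests (N=",
           config$overlap$n_perm, ")", verbose = verbose)
  invisible(res)
}

#' Pipeline stage: copy-number association scan
#'
#' Runs the six-step CN-state association of the filtered calls with the
#' phenotype and writes `assoc_segments.tsv`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the segment table.
#' @export
cmd_assoc <- function(config, verbose = TRUE) {
  ds <- read_dataset(config)
  fpath <- file.path(config$outdir, "calls_filtered.rawcnv")
  calls <- if (file.exists(fpath)) read_penncnv_calls(fpath) else ds$calls
  genes <- read_bed_track(file.path(data_dir(config), "genes.bed"), "genes")
  seg <- run_cnv_gwas(calls, ds$probe_map, ds$phenotypes, gene_track = genes,
                      min_dev = config$assoc$min_dev,
                      identity_frac = config$assoc$identity_frac,
                      window_bp = config$assoc$window_bp,
                      genome = ds$genome)
  write_assoc_table(seg, file.path(config$outdir, "assoc_segments.tsv"))
  log_line(config, "assoc: ", nrow(seg), " segments, ",
           sum(seg$fdr_q < 0.05), " with q < 0.05", verbose = verbose)
  invisible(seg)
}

#' Pipeline stage: qPCR validation
#'
#' Quantifies the simulated qPCR plates, derives copy number states, and
#' compares them with the array calls over the assayed regions, writing
#' `qpcr_records.tsv` and `qpcr_concordance.tsv`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the concordance table.
#' @export
cmd_qpcr <- function(config, verbose = TRUE) {
  ds <- read_dataset(config)
  dd <- data_dir(config)
  plate <- read_qpcr_plate(file.path(dd, "qpcr_plate.tsv"))
  loci <- utils::read.table(file.path(dd, "truth_loci.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  names(loci)[names(loci) == "locus_id"] <- "region_id"
  loci$chrom <- normalize_chrom(loci$chrom)
  fpath <- file.path(config$outdir, "calls_filtered.rawcnv")
  calls <- if (file.exists(fpath)) read_penncnv_calls(fpath) else ds$calls
  arr <- array_cn_from_calls(calls, loci, unique(plate$sample_id))
  rec <- analyze_qpcr(plate, arr,
                      drop_outlier_replicate =
                        config$qpcr$drop_outlier_replicate)
  conc <- qpcr_concordance(rec, calls, loci)
  num_cols <- c("dct", "ddct", "nr")
  rec[num_cols] <- lapply(rec[num_cols], function(x) sprintf("%.6g", x))
  utils::write.table(rec, file.path(config$outdir, "qpcr_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(conc, file.path(config$outdir, "qpcr_concordance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line(config, "qpcr: ", nrow(conc), " regions tested, ",
           sum(conc$validated), " validated, mean concordance ",
           sprintf("%.1f", mean(conc$concordance_pct)), "%",
           verbose = verbose)
  invisible(conc)
}

#' Run the full pipeline
#'
#' Simulation, CNVR compilation, overlap permutation tests, the association
#' scan, and qPCR validation, in order. Outputs are a pure function of the
#' configuration (including its seed): re-running with the same config
#' reproduces every output file byte for byte.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, a named list of the per-stage results.
#' @export
cmd_all <- function(config, verbose = TRUE) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$outdir, "run_log.txt")
  if (file.exists(logf)) file.remove(logf)
  res <- list()
  cmd_simulate(config, verbose = verbose)
  res$regions <- cmd_compile(config, verbose = verbose)
  res$overlap <- cmd_overlap(config, verbose = verbose)
  res$assoc <- cmd_assoc(config, verbose = verbose)
  res$qpcr <- cmd_qpcr(config, verbose = verbose)
  log_line(config, "all: 5 stages complete", verbose = verbose)
  invisible(res)
}
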