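#' Configuration for the synthetic CNV population generator
#'
#' Bundles every tunable of the simulator with desk-scale defaults chosen to
#' mirror the statistical structure of a SNP-array CNV study in a diploid
#' livestock population: a five-chromosome 50 Mb genome with a probe every
#' 3.2 kb (the density of a ~770k-probe high-density chip on a 2.5 Gb
#' genome), 40 non-overlapping CNV loci with lengths log-uniform between
#' 5 kb and 500 kb, population frequencies drawn uniformly per locus, a
#' minority of gain loci, boundary jitter of the emitted calls, sporadic
#' false positive calls, a phenotype with additive per-copy dosage effects at
#' a few causal loci, and triplicate qPCR plates. The seed fully determines
#' every output; sub-streams are decoupled so changing, say, the qPCR noise
#' does not perturb the locus layout.
#'
#' @param seed Root integer seed.
#' @param n_animals Number of diploid animals.
#' @param n_chromosomes,chrom_length_bp Genome shape (equal-length autosomes).
#' @param probe_spacing_bp Array probe spacing in bp.
#' @param n_cnv_loci Number of CNV loci.
#' @param locus_frequency_range Range (min, max) of per-locus population
#'   frequencies, drawn uniformly.
#' @param locus_length_range Range of locus lengths in bp, drawn log-uniform.
#' @param gain_fraction Fraction of loci that are copy gains.
#' @param loss_cn0_prob,gain_cn4_prob Probability that a carrier of a
#'   loss/gain locus is in the homozygous state (0n / 4n) rather than 1n/3n.
#' @param boundary_jitter_sd_bp SD of the Gaussian jitter applied to emitted
#'   call boundaries, rounded to the probe grid; 0 emits exact locus spans.
#' @param false_positive_rate Expected number of spurious calls per animal
#'   (Poisson), placed away from the animal's true calls.
#' @param causal_loci Integer indices of loci with a phenotype effect.
#' @param causal_beta Effect per copy deviation from 2n, in phenotype units
#'   (recycled over `causal_loci`).
#' @param phenotype_mu,phenotype_noise_sd Phenotype baseline and residual SD.
#' @param overlap_pair Plant one additional gain and loss locus pair with
#'   partial overlap (exercises "both"-type regions).
#' @param qpcr_base_ct,qpcr_efficiency,qpcr_ct_noise_sd,qpcr_n_replicates
#'   qPCR plate generator settings.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_animals = 100L,
                       n_chromosomes = 5L,
                       chrom_length_bp = 10e6,
                       probe_spacing_bp = 3200,
                       n_cnv_loci = 40L,
                       locus_frequency_range = c(0.02, 0.6),
                       locus_length_range = c(5e3, 5e5),
                       gain_fraction = 0.4,
                       loss_cn0_prob = 0.1,
                       gain_cn4_prob = 0.1,
                       boundary_jitter_sd_bp = 3200,
                       false_positive_rate = 0.2,
                       causal_loci = c(1L, 2L, 3L),
                       causal_beta = 0.8,
                       phenotype_mu = 0,
                       phenotype_noise_sd = 1,
                       overlap_pair = FALSE,
                       qpcr_base_ct = 25,
                       qpcr_efficiency = 2,
                       qpcr_ct_noise_sd = 0.1,
                       qpcr_n_replicates = 3L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_animals > 0, cfg$n_chromosomes > 0,
            cfg$chrom_length_bp > 0, cfg$probe_spacing_bp > 0,
            cfg$n_cnv_loci >= 0,
            all(cfg$locus_frequency_range > 0),
            all(cfg$locus_frequency_range < 1),
            cfg$gain_fraction >= 0, cfg$gain_fraction <= 1,
            cfg$boundary_jitter_sd_bp >= 0, cfg$false_positive_rate >= 0,
            cfg$phenotype_noise_sd >= 0,
            cfg$qpcr_efficiency > 1, cfg$qpcr_efficiency <= 2)
  if (length(cfg$causal_loci) > 0 &&
      any(cfg$causal_loci > cfg$n_cnv_loci + 2 * cfg$overlap_pair)) {
    stop("causal_loci index exceeds the number of loci")
  }
  cfg$causal_beta <- rep_len(cfg$causal_beta,
                             max(length(cfg$causal_loci), 1L))[
                               seq_along(cfg$causal_loci)]
  class(cfg) <- "sim_config"
  cfg
}

# Decoupled RNG sub-streams: each named component seeds its own stream from
# the root seed, so outputs are reproducible component-wise.
seed_stream <- function(seed, component) {
  offsets <- c(loci = 101L, carriers = 211L, jitter = 307L, fp = 401L,
               phenotype = 503L, annotation = 601L, qpcr = 701L)
  stopifnot(component %in% names(offsets))
  set.seed((as.integer(seed) %% 1000000L) * 1000L + offsets[[component]])
}

#' Simulate a CNV population with ground truth
#'
#' Places non-overlapping CNV loci on the genome, draws carrier status per
#' animal per locus with the locus frequency, assigns integer copy numbers
#' (1n or 0n at loss loci, 3n or 4n at gain loci), and emits per-animal CNV
#' calls: true spans perturbed by Gaussian boundary jitter rounded to the
#' probe grid, plus Poisson-distributed false positive calls placed away
#' from the animal's true calls. All randomness is governed by the config
#' seed; re-running with the same config reproduces every output.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (a `genome_build`), `probe_map`, `truth` (list
#'   with `loci` data.frame, integer `cn` matrix animals x loci, and
#'   `sample_ids`), and `calls` (a `cnv_calls` data.frame).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- genome_build(as.character(seq_len(config$n_chromosomes)),
                         rep(config$chrom_length_bp, config$n_chromosomes))
  probe_map <- data.frame(
    chrom = rep(genome$chrom, each = floor(config$chrom_length_bp /
                                             config$probe_spacing_bp)),
    pos = rep(seq(config$probe_spacing_bp, config$chrom_length_bp,
                  by = config$probe_spacing_bp), times = config$n_chromosomes),
    stringsAsFactors = FALSE)
  probe_map$probe_id <- sprintf("probe_%s_%07d", probe_map$chrom,
                                as.integer(probe_map$pos))
  probe_map <- sort_probe_map(probe_map[, c("probe_id", "chrom", "pos")],
                              genome)

  loci <- place_loci(genome, config)
  sample_ids <- sprintf("animal_%03d", seq_len(config$n_animals))

  seed_stream(config$seed, "carriers")
  n_loci <- nrow(loci)
  cn <- matrix(2L, nrow = config$n_animals, ncol = n_loci,
               dimnames = list(sample_ids, loci$locus_id))
  for (l in seq_len(n_loci)) {
    carrier <- stats::runif(config$n_animals) < loci$frequency[l]
    if (!any(carrier)) next
    if (loci$type[l] == "loss") {
      state <- ifelse(stats::runif(sum(carrier)) < config$loss_cn0_prob,
                      0L, 1L)
    } else {
      state <- ifelse(stats::runif(sum(carrier)) < config$gain_cn4_prob,
                      4L, 3L)
    }
    cn[carrier, l] <- state
  }

  calls <- emit_calls(loci, cn, genome, probe_map, config)
  truth <- list(loci = loci, cn = cn, sample_ids = sample_ids)
  list(genome = genome, probe_map = probe_map, truth = truth, calls = calls)
}

place_loci <- function(genome, config) {
  seed_stream(config$seed, "loci")
  n <- config$n_cnv_loci
  lr <- config$locus_length_range
  fr <- config$locus_frequency_range
  placed <- list()
  types <- ifelse(stats::runif(n) < config$gain_fraction, "gain", "loss")
  for (l in seq_len(n)) {
    len <- round(exp(stats::runif(1, log(lr[1]), log(lr[2]))))
    ok <- FALSE
    for (try in seq_len(1000L)) {
      chrom <- sample(genome$chrom, 1L)
      room <- chrom_length(genome, chrom) - len + 1
      if (room < 1) next
      start <- floor(stats::runif(1, 1, room + 1))
      prev <- placed[[chrom]]
      if (is.null(prev) ||
          !any(start <= prev$end & start + len - 1 >= prev$start)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place ", n, " non-overlapping loci; ",
           "use fewer or shorter loci")
    }
    row <- data.frame(chrom = chrom, start = start, end = start + len - 1,
                      type = types[l], stringsAsFactors = FALSE)
    placed[[chrom]] <- rbind(placed[[chrom]], row)
  }
  loci <- do.call(rbind, placed)
  if (isTRUE(config$overlap_pair)) {
    # one gain and one loss locus with 50% overlap, on the first chromosome
    # with room after all placed loci
    len <- 20000
    for (chrom in genome$chrom) {
      prev <- loci[loci$chrom == chrom, , drop = FALSE]
      start <- find_free_start(prev, chrom_length(genome, chrom), 2 * len)
      if (!is.na(start)) {
        loci <- rbind(loci,
          data.frame(chrom = chrom, start = start, end = start + len - 1,
                     type = "gain", stringsAsFactors = FALSE),
          data.frame(chrom = chrom, start = start + len / 2,
                     end = start + 3 * len / 2 - 1, type = "loss",
                     stringsAsFactors = FALSE))
        break
      }
    }
  }
  loci <- loci[order(match(loci$chrom, genome$chrom), loci$start), ,
               drop = FALSE]
  rownames(loci) <- NULL
  loci$locus_id <- sprintf("LOC_%d", seq_len(nrow(loci)))
  loci$frequency <- stats::runif(nrow(loci), fr[1], fr[2])
  loci[, c("locus_id", "chrom", "start", "end", "type", "frequency")]
}

find_free_start <- function(prev, chrom_len, len) {
  # first grid-free start for an interval of `len`, or NA
  for (start in seq(1, chrom_len - len + 1, by = len)) {
    if (nrow(prev) == 0L ||
        !any(start <= prev$end & start + len - 1 >= prev$start)) {
      return(start)
    }
  }
  NA_real_
}

emit_calls <- function(loci, cn, genome, probe_map, config) {
  seed_stream(config$seed, "jitter")
  grid <- config$probe_spacing_bp
  rows <- list()
  per_sample_iv <- list()  # for false-positive placement
  sample_ids <- rownames(cn)
  for (l in seq_len(nrow(loci))) {
    carriers <- which(cn[, l] != 2L)
    for (a in carriers) {
      if (config$boundary_jitter_sd_bp > 0) {
        js <- round(stats::rnorm(1, 0, config$boundary_jitter_sd_bp) /
                      grid) * grid
        je <- round(stats::rnorm(1, 0, config$boundary_jitter_sd_bp) /
                      grid) * grid
      } else {
        js <- je <- 0
      }
      s <- max(1, loci$start[l] + js)
      e <- min(chrom_length(genome, loci$chrom[l]), loci$end[l] + je)
      # jitter must not run a call into the same sample's previous call on
      # the chromosome (a caller emits disjoint per-sample calls)
      prev <- per_sample_iv[[sample_ids[a]]]
      if (!is.null(prev)) {
        on_chr <- prev[prev$chrom == loci$chrom[l], , drop = FALSE]
        if (nrow(on_chr) > 0L && any(s <= on_chr$end & e >= on_chr$start)) {
          s <- max(s, max(on_chr$end[on_chr$start <= e]) + 1)
        }
      }
      if (e - s + 1 < 1000) next  # jitter collapsed the call; drop it
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_ids[a], chrom = loci$chrom[l], start = s, end = e,
        cn = cn[a, l], stringsAsFactors = FALSE)
      per_sample_iv[[sample_ids[a]]] <-
        rbind(per_sample_iv[[sample_ids[a]]],
              data.frame(chrom = loci$chrom[l], start = s, end = e))
    }
  }
  seed_stream(config$seed, "fp")
  if (config$false_positive_rate > 0) {
    for (a in seq_along(sample_ids)) {
      n_fp <- stats::rpois(1, config$false_positive_rate)
      for (k in seq_len(n_fp)) {
        len <- round(stats::runif(1, 5e3, 5e4))
        for (try in seq_len(100L)) {
          chrom <- sample(genome$chrom, 1L)
          start <- floor(stats::runif(1, 1,
                                      chrom_length(genome, chrom) - len + 2))
          prev <- per_sample_iv[[sample_ids[a]]]
          clear <- is.null(prev) ||
            !any(prev$chrom == chrom & start <= prev$end &
                   start + len - 1 >= prev$start)
          if (clear) break
        }
        if (!clear) next
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_ids[a], chrom = chrom, start = start,
          end = start + len - 1,
          cn = if (stats::runif(1) < 0.5) 1L else 3L,
          stringsAsFactors = FALSE)
        per_sample_iv[[sample_ids[a]]] <-
          rbind(prev, data.frame(chrom = chrom, start = start,
                                 end = start + len - 1))
      }
    }
  }
  if (length(rows) == 0L) {
    return(cnv_calls(character(), character(), numeric(), numeric(),
                     integer(), integer()))
  }
  df <- do.call(rbind, rows)
  # probe support of each call
  num_snps <- integer(nrow(df))
  for (chrom in unique(df$chrom)) {
    pos <- probe_map$pos[probe_map$chrom == chrom]
    sel <- which(df$chrom == chrom)
    num_snps[sel] <- vapply(sel, function(i) {
      max(1L, sum(pos >= df$start[i] & pos <= df$end[i]))
    }, integer(1))
  }
  ord <- order(df$sample_id, match(df$chrom, genome$chrom), df$start)
  df <- df[ord, , drop = FALSE]
  cnv_calls(df$sample_id, df$chrom, df$start, df$end, df$cn, num_snps[ord])
}

#' Simulate a dosage-effect quantitative phenotype
#'
#' `y_i = mu + sum_l beta_l * (CN_il - 2) + eps_i` with Gaussian residuals:
#' each causal locus shifts the phenotype additively per copy gained or
#' lost. With zero residual SD the phenotype is an exact linear function of
#' the true copy numbers.
#'
#' @param truth Ground truth from [simulate_population()].
#' @param config The same [sim_config()].
#' @return A phenotype table (`sample_id`, `phenotype`).
#' @export
simulate_phenotype <- function(truth, config) {
  seed_stream(config$seed, "phenotype")
  y <- rep(config$phenotype_mu, length(truth$sample_ids))
  for (i in seq_along(config$causal_loci)) {
    l <- config$causal_loci[i]
    y <- y + config$causal_beta[i] * (truth$cn[, l] - 2)
  }
  if (config$phenotype_noise_sd > 0) {
    y <- y + stats::rnorm(length(y), 0, config$phenotype_noise_sd)
  }
  data.frame(sample_id = truth$sample_ids, phenotype = y,
             stringsAsFactors = FALSE)
}

#' Simulate an annotation track with controllable placement bias
#'
#' Places `n_intervals` intervals uniformly, or rejection-samples placements
#' that avoid the true CNV loci (`"avoid_loci"`, emulating the depletion of
#' functional elements in variable regions), or forces each interval to
#' overlap a true locus (`"inside_loci"`).
#'
#' @param genome A `genome_build`.
#' @param truth Ground truth from [simulate_population()].
#' @param n_intervals Number of intervals.
#' @param placement `"uniform"`, `"avoid_loci"`, or `"inside_loci"`.
#' @param seed Integer seed.
#' @param label Track label.
#' @param length_range Interval lengths, drawn uniformly from this range.
#' @return An `annotation_track`.
#' @export
simulate_annotation <- function(genome, truth, n_intervals = 200,
                                placement = c("uniform", "avoid_loci",
                                              "inside_loci"),
                                seed = 1L, label = placement,
                                length_range = c(1e3, 2e4)) {
  placement <- match.arg(placement)
  seed_stream(seed, "annotation")
  loci <- truth$loci
  chroms <- character(n_intervals)
  starts <- ends <- numeric(n_intervals)
  for (i in seq_len(n_intervals)) {
    len <- round(stats::runif(1, length_range[1], length_range[2]))
    placed <- FALSE
    for (try in seq_len(10000L)) {
      if (placement == "inside_loci") {
        l <- sample(nrow(loci), 1L)
        chrom <- loci$chrom[l]
        # force >= 1 bp overlap with the chosen locus
        lo <- max(1, loci$start[l] - len + 1)
        hi <- min(chrom_length(genome, chrom) - len + 1, loci$end[l])
        if (hi < lo) next
        start <- floor(stats::runif(1, lo, hi + 1))
      } else {
        chrom <- sample(genome$chrom, 1L)
        room <- chrom_length(genome, chrom) - len + 1
        if (room < 1) next
        start <- floor(stats::runif(1, 1, room + 1))
      }
      if (placement == "avoid_loci") {
        clash <- any(loci$chrom == chrom & start <= loci$end &
                       start + len - 1 >= loci$start)
        if (clash) next
      }
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place annotation interval ", i,
           " under placement '", placement, "'")
    }
    chroms[i] <- chrom
    starts[i] <- start
    ends[i] <- start + len - 1
  }
  annotation_track(chroms, starts, ends,
                   name = sprintf("%s_%d", label, seq_len(n_intervals)),
                   label = label)
}

#' Simulate qPCR plates for selected loci
#'
#' Generates triplicate cycle thresholds per sample and locus under the
#' relative-quantification model the analysis inverts: the corrected target
#' Ct is `base_ct - log2(CN/2)` plus Gaussian replicate noise, the control
#' Ct is `base_ct` plus noise, and a true copy number of 0 yields no
#' amplification. Emitted raw Ct values are scaled by `1/log2(E)` so that
#' efficiency correction at efficiency `E` recovers the model exactly.
#'
#' @param truth Ground truth from [simulate_population()].
#' @param loci Locus indices (into `truth$loci`) to assay.
#' @param samples Sample ids to assay (default: all).
#' @param config The [sim_config()].
#' @return A qPCR plate data.frame (see [read_qpcr_plate()]); `region_id` is
#'   the locus id.
#' @export
simulate_qpcr <- function(truth, loci, samples = NULL, config) {
  if (is.null(samples)) samples <- truth$sample_ids
  seed_stream(config$seed, "qpcr")
  eff <- config$qpcr_efficiency
  nrep <- config$qpcr_n_replicates
  noise <- function(n) {
    if (config$qpcr_ct_noise_sd > 0) {
      stats::rnorm(n, 0, config$qpcr_ct_noise_sd)
    } else rep(0, n)
  }
  rows <- list()
  for (l in loci) {
    lid <- truth$loci$locus_id[l]
    for (s in samples) {
      true_cn <- truth$cn[s, l]
      amplified <- true_cn > 0L
      if (amplified) {
        target <- (config$qpcr_base_ct - log2(true_cn / 2) + noise(nrep)) /
          log2(eff)
      } else {
        target <- rep(NA_real_, nrep)
      }
      control <- (config$qpcr_base_ct + noise(nrep)) / log2(eff)
      row <- data.frame(sample_id = s, primer_id = paste0("primer_", lid),
                        region_id = lid, stringsAsFactors = FALSE)
      for (r in seq_len(nrep)) row[[paste0("target_ct", r)]] <- target[r]
      for (r in seq_len(nrep)) row[[paste0("control_ct", r)]] <- control[r]
      row$efficiency <- eff
      row$amplified <- amplified
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Array copy number of each sample at each locus, as a lookup table
#'
#' Convenience view of the ground truth used as the `array_cn` argument of
#' [analyze_qpcr()] (in a real study this table would come from the array
#' calls over the tested regions).
#'
#' @param truth Ground truth from [simulate_population()].
#' @param loci Locus indices.
#' @return Data.frame `sample_id`, `region_id`, `cn`.
#' @export
truth_array_cn <- function(truth, loci = seq_len(nrow(truth$loci))) {
  do.call(rbind, lapply(loci, function(l) {
    data.frame(sample_id = truth$sample_ids,
               region_id = truth$loci$locus_id[l],
               cn = truth$cn[, l], stringsAsFactors = FALSE)
  }))
}

#' Ground-truth loci as a region table
#'
#' @param truth Ground truth from [simulate_population()].
#' @return Data.frame with `region_id`, `chrom`, `start`, `end`, `type`,
#'   `frequency` (the loci, renamed for use wherever a region set is
#'   expected).
#' @export
truth_regions <- function(truth) {
  df <- truth$loci
  names(df)[names(df) == "locus_id"] <- "region_id"
  df
}

#' Write a simulated dataset to a directory
#'
#' Emits exactly the plain-text formats the readers consume: `calls.rawcnv`,
#' `chrom.sizes`, `probes.tsv`, `phenotypes.tsv`, plus ground-truth tables
#' `truth_loci.tsv` and `truth_cn.tsv` for assertions.
#'
#' @param sim Output of [simulate_population()].
#' @param dir Output directory (created if needed).
#' @param phenotypes Optional phenotype table to include.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, phenotypes = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_penncnv_calls(sim$calls, file.path(dir, "calls.rawcnv"))
  utils::write.table(
    data.frame(chrom = sim$genome$chrom,
               length = format(sim$genome$length, scientific = FALSE,
                               trim = TRUE)),
    file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_probe_map(sim$probe_map, file.path(dir, "probes.tsv"))
  loci <- sim$truth$loci
  loci$frequency <- sprintf("%.6f", loci$frequency)
  utils::write.table(loci, file.path(dir, "truth_loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cn_df <- data.frame(sample_id = rownames(sim$truth$cn), sim$truth$cn,
                      check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cn_df, file.path(dir, "truth_cn.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(phenotypes)) {
    write_phenotypes(phenotypes, file.path(dir, "phenotypes.tsv"))
  }
  invisible(dir)
}
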