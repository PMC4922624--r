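#' Compile per-sample CNV calls into population CNV regions
#'
#' Overlapping calls from different animals are concatenated into CNV regions
#' (CNVRs) with density-based trimming, the standard population-level summary
#' of SNP-array CNV maps:
#'
#' 1. Calls are partitioned into losses (cn < 2) and gains (cn > 2).
#' 2. Within each partition and chromosome, transitively overlapping calls
#'    (at least one shared base) form a cluster.
#' 3. Within a cluster of `n` calls, the per-base density is the number of
#'    member calls covering that base divided by `n`. Bases with density
#'    strictly below `recurrence` are trimmed away; low-density edges, which
#'    are enriched for boundary errors of single outlier calls, are thereby
#'    removed. Each maximal surviving run becomes a region (a cluster may
#'    split into several).
#' 4. Overlapping gain and loss regions are merged (transitively) into single
#'    regions of type `"both"`, spanning their union.
#' 5. Member calls are all calls overlapping the final region by >= 1 base;
#'    the region frequency is the number of distinct samples among members
#'    divided by `population_size`.
#' 6. Regions are numbered `CNVR_1, CNVR_2, ...` by (chromosome order,
#'    start).
#'
#' @param calls A `cnv_calls` data.frame (already quality filtered).
#' @param genome A `genome_build` (fixes chromosome order).
#' @param population_size Number of animals in the population the frequency
#'   is referred to; must be at least the number of distinct samples in
#'   `calls`.
#' @param recurrence Density threshold in `[0, 1)`. Bases covered by a
#'   fraction of cluster calls strictly below this are trimmed; `0` disables
#'   trimming.
#' @param separate_gain_loss Compile gains and losses separately before the
#'   type merge (step 1). With `FALSE` all calls are clustered together and
#'   region type is derived from member states.
#' @return A `cnv_regions` data.frame with columns `region_id`, `chrom`,
#'   `start`, `end`, `length`, `type` (loss/gain/both), `n_calls`,
#'   `n_samples`, `frequency`, `polymorphic`, `fixed_state`, and a
#'   list-column `member_calls` of row indices into `calls`.
#' @export
compile_cnvrs <- function(calls, genome, population_size,
                          recurrence = 0.1, separate_gain_loss = TRUE) {
  stopifnot(inherits(genome, "genome_build"))
  if (recurrence < 0 || recurrence >= 1) {
    stop("recurrence must be in [0, 1)")
  }
  n_samples_obs <- length(unique(calls$sample_id))
  if (population_size < n_samples_obs) {
    stop("population_size (", population_size, ") is smaller than the ",
         "number of distinct samples observed (", n_samples_obs, ")")
  }
  if (nrow(calls) == 0L) return(empty_regions())

  types <- if (separate_gain_loss) {
    ifelse(calls$cn < 2L, "loss", "gain")
  } else {
    rep("all", nrow(calls))
  }

  proto <- list()  # per-chromosome raw typed regions before the both-merge
  for (chrom in intersect(genome$chrom, unique(calls$chrom))) {
    on_chr <- which(calls$chrom == chrom)
    typed <- list()
    for (ty in unique(types[on_chr])) {
      idx <- on_chr[types[on_chr] == ty]
      ir <- IRanges::IRanges(start = calls$start[idx], end = calls$end[idx])
      clusters <- IRanges::reduce(ir, min.gapwidth = 0L)
      hit <- IRanges::findOverlaps(ir, clusters, minoverlap = 1L)
      cl_of <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
      for (cl in seq_along(clusters)) {
        member <- which(cl_of == cl)
        runs <- trim_cluster(ir[member], recurrence)
        if (length(runs) > 0L) {
          typed[[length(typed) + 1L]] <- data.frame(
            chrom = chrom, start = IRanges::start(runs),
            end = IRanges::end(runs), type = ty, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(typed) > 0L) {
      proto[[chrom]] <- merge_gain_loss(do.call(rbind, typed))
    }
  }
  if (length(proto) == 0L) return(empty_regions())
  reg <- do.call(rbind, proto)

  # order by (chromosome order, start) and number
  reg <- reg[order(match(reg$chrom, genome$chrom), reg$start), , drop = FALSE]
  rownames(reg) <- NULL
  reg$region_id <- sprintf("CNVR_%d", seq_len(nrow(reg)))
  reg$length <- reg$end - reg$start + 1

  # membership: any call sharing >= 1 bp with the final region
  members <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    members[[i]] <- which(calls$chrom == reg$chrom[i] &
                            calls$start <= reg$end[i] &
                            calls$end >= reg$start[i])
  }
  reg$n_calls <- lengths(members)
  reg$n_samples <- vapply(members, function(m) {
    length(unique(calls$sample_id[m]))
  }, integer(1))
  reg$frequency <- reg$n_samples / population_size
  reg$polymorphic <- NA
  reg$fixed_state <- NA
  reg$member_calls <- members
  reg <- reg[, c("region_id", "chrom", "start", "end", "length", "type",
                 "n_calls", "n_samples", "frequency", "polymorphic",
                 "fixed_state", "member_calls")]
  attr(reg, "population_size") <- population_size
  class(reg) <- c("cnv_regions", "data.frame")
  reg
}

empty_regions <- function() {
  reg <- data.frame(region_id = character(), chrom = character(),
                    start = numeric(), end = numeric(), length = numeric(),
                    type = character(), n_calls = integer(),
                    n_samples = integer(), frequency = numeric(),
                    polymorphic = logical(), fixed_state = logical(),
                    stringsAsFactors = FALSE)
  reg$member_calls <- list()
  class(reg) <- c("cnv_regions", "data.frame")
  reg
}

# Trim a cluster of call ranges to the bases covered by at least a fraction
# `recurrence` of the cluster's calls; returns the maximal surviving runs.
trim_cluster <- function(ir, recurrence) {
  n <- length(ir)
  # smallest integer depth d with d/n >= recurrence (>= 1 so a base must be
  # covered at all); tolerance guards ceiling() against floating point
  min_depth <- max(1L, as.integer(ceiling(recurrence * n - 1e-9)))
  if (min_depth == 1L) {
    return(IRanges::reduce(ir, min.gapwidth = 0L))
  }
  cov <- IRanges::coverage(ir)
  IRanges::slice(cov, lower = min_depth, rangesOnly = TRUE)
}

# Merge overlapping gain and loss regions (transitively) into "both" regions
# spanning their union; single-type components pass through unchanged.
merge_gain_loss <- function(reg) {
  if (nrow(reg) <= 1L || length(unique(reg$type)) == 1L) return(reg)
  ir <- IRanges::IRanges(start = reg$start, end = reg$end)
  comp <- IRanges::reduce(ir, min.gapwidth = 0L)
  hit <- IRanges::findOverlaps(ir, comp, minoverlap = 1L)
  comp_of <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  out <- list()
  for (ci in seq_along(comp)) {
    member <- which(comp_of == ci)
    tys <- unique(reg$type[member])
    if (length(tys) > 1L) {
      out[[ci]] <- data.frame(chrom = reg$chrom[member[1]],
                              start = min(reg$start[member]),
                              end = max(reg$end[member]),
                              type = "both", stringsAsFactors = FALSE)
    } else {
      out[[ci]] <- reg[member, , drop = FALSE]
    }
  }
  do.call(rbind, out)
}

#' Flag polymorphic CNV regions
#'
#' A region is called polymorphic when its carrier frequency is strictly
#' greater than `threshold` (default: more than 1% of the population).
#'
#' @param regions A `cnv_regions` data.frame.
#' @param threshold Frequency threshold (strict).
#' @return `regions` with the `polymorphic` column set.
#' @export
classify_polymorphic <- function(regions, threshold = 0.01) {
  regions$polymorphic <- regions$frequency > threshold
  regions
}

#' Flag high-frequency regions with a near-fixed CNV state
#'
#' For regions carried by more than `freq_threshold` of the population, flags
#' those in which a single copy number state accounts for more than
#' `state_fraction` of the member calls. A high-frequency region fixed for
#' one state suggests a reference-assembly difference (a mapping artifact)
#' rather than segregating variation within the study population.
#'
#' @param regions A `cnv_regions` data.frame with `member_calls` attached.
#' @param calls The `cnv_calls` the regions were compiled from.
#' @param freq_threshold Frequency gate: only regions with frequency strictly
#'   above this are examined (others get `FALSE`).
#' @param state_fraction A region is flagged when some single cn value
#'   accounts for strictly more than this fraction of member calls.
#' @return `regions` with the `fixed_state` column set.
#' @export
flag_fixed_state <- function(regions, calls, freq_threshold = 0.75,
                             state_fraction = 0.95) {
  flag <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    if (regions$frequency[i] > freq_threshold) {
      states <- calls$cn[regions$member_calls[[i]]]
      if (length(states) > 0L) {
        flag[i] <- max(table(states)) / length(states) > state_fraction
      }
    }
  }
  regions$fixed_state <- flag
  regions
}

#' Histogram of CNV region lengths
#'
#' Bins region lengths into half-open bins `[e1, e2), [e2, e3), ...` given a
#' sorted edge vector (the last edge is typically `Inf`).
#'
#' @param regions A `cnv_regions` data.frame.
#' @param edges Sorted bin edges in bp; `k+1` edges define `k` bins.
#' @return A `length_histogram` list with `edges`, `counts`, `fractions`.
#' @export
length_histogram <- function(regions,
                             edges = c(5e3, 5e4, 1e5, 2.5e5, 5e5, 1e6, Inf)) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  lens <- regions$length
  counts <- integer(length(edges) - 1L)
  for (i in seq_along(counts)) {
    counts[i] <- sum(lens >= edges[i] & lens < edges[i + 1L])
  }
  if (length(lens) == 0L) {
    warning("no regions: fractions reported as 0")
    fractions <- rep(0, length(counts))
  } else {
    fractions <- counts / sum(counts)
  }
  structure(list(edges = edges, counts = counts, fractions = fractions),
            class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  lab <- sprintf("[%s, %s)",
                 format(x$edges[-length(x$edges)], big.mark = ",", trim = TRUE),
                 format(x$edges[-1], big.mark = ",", trim = TRUE))
  print(data.frame(bin = lab, count = x$counts,
                   fraction = round(x$fractions, 4)))
  invisible(x)
}

#' Write a length histogram as TSV
#' @param hist A `length_histogram`.
#' @param path Output path.
#' @export
write_length_histogram <- function(hist, path) {
  df <- data.frame(bin_lo = hist$edges[-length(hist$edges)],
                   bin_hi = hist$edges[-1],
                   count = hist$counts, fraction = hist$fractions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a CNV region set
#'
#' @param regions A `cnv_regions` data.frame.
#' @param genome A `genome_build`; the genome fraction is relative to the
#'   total autosomal length.
#' @return A `cnvr_summary` list: counts by type, total bp, fraction of the
#'   autosomal genome, mean/min/max region length, and a per-chromosome
#'   coverage table.
#' @export
summarize_regions <- function(regions, genome) {
  stopifnot(inherits(genome, "genome_build"))
  auto_len <- sum(genome$length[genome$chrom %in% autosomes(genome)])
  per_chrom <- data.frame(chrom = genome$chrom,
                          covered_bp = 0, fraction = 0,
                          stringsAsFactors = FALSE)
  if (nrow(regions) > 0L) {
    cov <- tapply(regions$length, regions$chrom, sum)
    idx <- match(names(cov), per_chrom$chrom)
    per_chrom$covered_bp[idx] <- as.numeric(cov)
    per_chrom$fraction <- per_chrom$covered_bp / genome$length
  }
  structure(list(
    n_regions = nrow(regions),
    n_loss = sum(regions$type == "loss"),
    n_gain = sum(regions$type == "gain"),
    n_both = sum(regions$type == "both"),
    n_polymorphic = sum(regions$polymorphic %in% TRUE),
    total_bp = sum(regions$length),
    genome_fraction = if (auto_len > 0) sum(regions$length) / auto_len else 0,
    mean_length = if (nrow(regions) > 0L) mean(regions$length) else 0,
    min_length = if (nrow(regions) > 0L) min(regions$length) else 0,
    max_length = if (nrow(regions) > 0L) max(regions$length) else 0,
    per_chromosome = per_chrom
  ), class = "cnvr_summary")
}

#' @export
print.cnvr_summary <- function(x, ...) {
  cat(sprintf("CNV regions: %d (loss %d, gain %d, both %d; polymorphic %d)\n",
              x$n_regions, x$n_loss, x$n_gain, x$n_both, x$n_polymorphic))
  cat(sprintf("  total %.1f kb = %.1f%% of autosomal genome\n",
              x$total_bp / 1e3, 100 * x$genome_fraction))
  cat(sprintf("  length mean %.1f kb, range %.1f-%.1f kb\n",
              x$mean_length / 1e3, x$min_length / 1e3, x$max_length / 1e3))
  invisible(x)
}

#' Write a region summary as TSV
#' @param summary A `cnvr_summary`.
#' @param path Output path.
#' @export
write_region_summary <- function(summary, path) {
  df <- data.frame(
    metric = c("n_regions", "n_loss", "n_gain", "n_both", "n_polymorphic",
               "total_bp", "genome_fraction", "mean_length", "min_length",
               "max_length"),
    value = c(summary$n_regions, summary$n_loss, summary$n_gain,
              summary$n_both, summary$n_polymorphic, summary$total_bp,
              summary$genome_fraction, summary$mean_length,
              summary$min_length, summary$max_length))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write CNV regions as BED6+
#'
#' Columns: chrom, start, end, region_id, score = number of carrier samples,
#' strand = ".", then type, frequency, polymorphic, fixed_state.
#'
#' @param regions A `cnv_regions` data.frame.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(chrom = regions$chrom, start = regions$start,
                   end = regions$end, name = regions$region_id,
                   score = regions$n_samples, strand = ".",
                   type = regions$type,
                   frequency = sprintf("%.6g", regions$frequency),
                   polymorphic = regions$polymorphic,
                   fixed_state = regions$fixed_state,
                   stringsAsFactors = FALSE)
  write_bed_track(df, path, extra_cols = c("score", "strand", "type",
                                           "frequency", "polymorphic",
                                           "fixed_state"))
}

#' Format a ratio as a printed percentage
#'
#' The single formatting rule used in all package summaries: `100 * n / d`
#' rounded half-up to `digits` decimal places, as percentages are printed in
#' CNV survey tables (e.g. 1/723 -> "0.1", 722/723 -> "99.8").
#'
#' @param n Numerator.
#' @param d Denominator.
#' @param digits Decimal places.
#' @return Character vector of formatted percentages (no "%" sign).
#' @export
percent_of <- function(n, d, digits = 1) {
  # round half away from zero, the convention of printed tables
  x <- 100 * n / d
  scaled <- x * 10^digits
  sprintf(paste0("%.", digits, "f"),
          sign(scaled) * floor(abs(scaled) + 0.5) / 10^digits)
}
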