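#' Assign integer copy number to every probe in every sample
#'
#' Builds the probes x samples copy number matrix that is the substrate of
#' the association scan: a probe falling inside a sample's CNV call takes
#' that call's state; everywhere else the diploid default 2. Two calls of the
#' same sample covering one probe indicate invalid upstream calling and are
#' rejected.
#'
#' @param calls A `cnv_calls` data.frame.
#' @param probe_map Probe map (see [read_probe_map()]), sorted.
#' @param samples Character vector of sample ids defining the matrix columns
#'   (defaults to the samples present in `calls`).
#' @return A `probe_cn_matrix`: list with `cn` (integer matrix, rows = probes
#'   in map order, columns = samples), `probe_map`, and `deviation_fraction`
#'   (per probe, fraction of samples with cn != 2).
#' @export
assign_probe_cn <- function(calls, probe_map, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  np <- nrow(probe_map)
  cn <- matrix(2L, nrow = np, ncol = length(samples),
               dimnames = list(probe_map$probe_id, samples))
  for (chrom in unique(probe_map$chrom)) {
    pi <- which(probe_map$chrom == chrom)
    pr <- IRanges::IRanges(start = probe_map$pos[pi], width = 1L)
    ci <- which(calls$chrom == chrom & calls$sample_id %in% samples)
    if (length(ci) == 0L) next
    cr <- IRanges::IRanges(start = calls$start[ci], end = calls$end[ci])
    hit <- IRanges::findOverlaps(pr, cr)
    if (length(hit) == 0L) next
    ph <- pi[S4Vectors::queryHits(hit)]
    ch <- ci[S4Vectors::subjectHits(hit)]
    key <- paste(ph, calls$sample_id[ch])
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1]
      stop("overlapping calls for sample ", calls$sample_id[ch[d]],
           " cover probe ", probe_map$probe_id[ph[d]],
           "; per-sample calls must be non-overlapping")
    }
    cn[cbind(ph, match(calls$sample_id[ch], samples))] <- calls$cn[ch]
  }
  structure(list(cn = cn, probe_map = probe_map,
                 deviation_fraction = rowMeans(cn != 2L)),
            class = "probe_cn_matrix")
}

#' Select copy-number-variable probes
#'
#' Keeps probes deviating from the diploid state in at least `min_dev` of the
#' population (common copy number polymorphisms), in map order.
#'
#' @param matrix A `probe_cn_matrix`.
#' @param min_dev Minimum deviation fraction (inclusive).
#' @return Character vector of probe ids, original order preserved.
#' @export
select_variable_probes <- function(matrix, min_dev = 0.05) {
  stopifnot(inherits(matrix, "probe_cn_matrix"))
  rownames(matrix$cn)[matrix$deviation_fraction >= min_dev]
}

#' Per-probe association of copy number with a quantitative phenotype
#'
#' Ordinary least squares of phenotype on integer copy number (0-4), with a
#' two-sided t test on the slope at n - 2 degrees of freedom. Samples without
#' a phenotype are dropped pairwise. A probe with constant copy number among
#' phenotyped samples is degenerate: it is flagged and reported with
#' `beta = 0`, `p = 1`.
#'
#' @param cn_row Integer copy numbers, named by sample id.
#' @param phenotypes Phenotype table (`sample_id`, `phenotype`).
#' @return A one-row data.frame: `beta`, `se`, `t_stat`, `p_value`, `n_used`,
#'   `degenerate`.
#' @export
probe_association <- function(cn_row, phenotypes) {
  y <- phenotypes$phenotype[match(names(cn_row), phenotypes$sample_id)]
  ok <- is.finite(y)
  x <- as.numeric(cn_row[ok])
  y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::var(x) == 0) {
    return(data.frame(beta = 0, se = NA_real_, t_stat = NA_real_,
                      p_value = 1, n_used = n, degenerate = TRUE))
  }
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mean(x)
  rss <- sum((y - alpha - beta * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t_stat <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  data.frame(beta = beta, se = se, t_stat = t_stat,
             p_value = max(p, .Machine$double.xmin), n_used = n,
             degenerate = FALSE)
}

# Association for every probe in `probes` (rows of matrix$cn); returns a
# data.frame keyed by probe_id.
probe_association_all <- function(matrix, probes, phenotypes) {
  rows <- lapply(probes, function(p) {
    cbind(probe_id = p, probe_association(matrix$cn[p, ], phenotypes),
          stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Chain variable probes into copy-number segments
#'
#' Adjacent probes on an array frequently measure the same underlying CNV
#' event. Selected (variable) probes are chained greedily left to right: a
#' probe joins the open segment when it lies on the same chromosome as the
#' previous selected probe and the two have identical copy number in at least
#' `identity_frac` of the samples; otherwise a new segment opens. Probes in a
#' segment are identical by state, not necessarily by descent. Intervening
#' non-variable probes do not break a segment.
#'
#' @param selected_probes Probe ids from [select_variable_probes()], in map
#'   order.
#' @param matrix A `probe_cn_matrix`.
#' @param identity_frac Minimum fraction of samples with identical state
#'   (inclusive).
#' @return A `cnv_segments` data.frame: `segment_id`, `chrom`, `start`,
#'   `end`, `n_probes`, list-column `probe_ids`.
#' @export
build_segments <- function(selected_probes, matrix, identity_frac = 0.95) {
  stopifnot(inherits(matrix, "probe_cn_matrix"))
  pm <- matrix$probe_map
  if (length(selected_probes) == 0L) {
    seg <- data.frame(segment_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_probes = integer(), stringsAsFactors = FALSE)
    seg$probe_ids <- list()
    class(seg) <- c("cnv_segments", "data.frame")
    return(seg)
  }
  idx <- match(selected_probes, pm$probe_id)
  stopifnot(!anyNA(idx), !is.unsorted(idx))
  seg_of <- integer(length(selected_probes))
  seg_of[1] <- 1L
  for (j in seq_along(selected_probes)[-1]) {
    same_chrom <- pm$chrom[idx[j]] == pm$chrom[idx[j - 1]]
    ident <- mean(matrix$cn[idx[j], ] == matrix$cn[idx[j - 1], ])
    seg_of[j] <- if (same_chrom && ident >= identity_frac) {
      seg_of[j - 1]
    } else {
      seg_of[j - 1] + 1L
    }
  }
  segs <- lapply(split(seq_along(selected_probes), seg_of), function(m) {
    data.frame(chrom = pm$chrom[idx[m[1]]],
               start = pm$pos[idx[m[1]]],
               end = pm$pos[idx[m[length(m)]]],
               n_probes = length(m), stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, segs)
  seg$segment_id <- sprintf("SEG_%d", seq_len(nrow(seg)))
  seg$probe_ids <- split(selected_probes, seg_of)
  seg <- seg[, c("segment_id", "chrom", "start", "end", "n_probes",
                 "probe_ids")]
  rownames(seg) <- NULL
  class(seg) <- c("cnv_segments", "data.frame")
  seg
}

#' Score segments with a representative probe
#'
#' The probe with the smallest association p-value represents its segment
#' (ties broken by the leftmost probe); the segment inherits its p-value,
#' effect size, and the per-state sample counts observed at that probe.
#'
#' @param segments A `cnv_segments` data.frame.
#' @param probe_assocs Output of the per-probe association (data.frame with
#'   `probe_id`, `beta`, `p_value`, ...).
#' @param matrix A `probe_cn_matrix` (for per-state counts).
#' @return `segments` with columns `representative_probe`, `beta`, `p_value`,
#'   and `n_cn0` .. `n_cn4`.
#' @export
score_segments <- function(segments, probe_assocs, matrix) {
  rep_probe <- character(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    ids <- segments$probe_ids[[i]]
    ps <- probe_assocs$p_value[match(ids, probe_assocs$probe_id)]
    if (anyNA(ps)) stop("missing association result for a segment probe")
    rep_probe[i] <- ids[which.min(ps)]  # which.min takes the leftmost tie
  }
  hit <- match(rep_probe, probe_assocs$probe_id)
  segments$representative_probe <- rep_probe
  segments$beta <- probe_assocs$beta[hit]
  segments$p_value <- probe_assocs$p_value[hit]
  counts <- t(vapply(rep_probe, function(p) {
    tabulate(matrix$cn[p, ] + 1L, nbins = 5L)
  }, integer(5)))
  colnames(counts) <- paste0("n_cn", 0:4)
  cbind(segments, as.data.frame(counts))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (q-values) controlling the FDR across the
#' segment tests; a thin wrapper over [stats::p.adjust()] with input checks.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Annotate segments with neighboring genes
#'
#' Reports genes overlapping a window extending `window_bp` up- and
#' downstream of each segment (clamped at the chromosome ends), ordered by
#' distance to the segment; overlapping genes have distance 0. Copy number
#' changes can perturb the expression of genes several hundred kb away, hence
#' the wide default window.
#'
#' @param segments A `cnv_segments` data.frame.
#' @param gene_track An `annotation_track` of genes.
#' @param window_bp Window half-width in bp.
#' @param genome Optional `genome_build` for clamping.
#' @return `segments` with list-column `neighbor_genes` (data.frames with
#'   `name`, `distance`) and column `n_neighbor_genes`.
#' @export
annotate_neighbors <- function(segments, gene_track, window_bp = 450000,
                               genome = NULL) {
  nb <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    lo <- max(1, segments$start[i] - window_bp)
    hi <- segments$end[i] + window_bp
    if (!is.null(genome)) {
      hi <- min(hi, chrom_length(genome, segments$chrom[i]))
    }
    g <- gene_track[gene_track$chrom == segments$chrom[i] &
                      gene_track$start <= hi & gene_track$end >= lo,
                    , drop = FALSE]
    if (nrow(g) == 0L) {
      nb[[i]] <- data.frame(name = character(), distance = numeric(),
                            stringsAsFactors = FALSE)
      next
    }
    dist <- pmax(0, pmax(segments$start[i] - g$end,
                         g$start - segments$end[i]))
    ord <- order(dist, g$start)
    nb[[i]] <- data.frame(name = g$name[ord], distance = dist[ord],
                          stringsAsFactors = FALSE)
  }
  segments$neighbor_genes <- nb
  segments$n_neighbor_genes <- vapply(nb, nrow, integer(1))
  segments
}

#' Genome-wide association of copy number state with a quantitative trait
#'
#' The full six-step scan: (1) assign per-probe copy number from the calls;
#' (2) select probes deviating from 2n in at least `min_dev` of the
#' population; (3) regress the phenotype on copy number probe by probe;
#' (4) chain selected probes with >= `identity_frac` state identity into
#' segments; (5) represent each segment by its most significant probe;
#' (6) adjust segment p-values for multiple testing by the
#' Benjamini-Hochberg FDR. Optionally annotates neighboring genes.
#'
#' @param calls A `cnv_calls` data.frame.
#' @param probe_map Sorted probe map.
#' @param phenotypes Phenotype table (`sample_id`, `phenotype`); samples
#'   absent from it are excluded from the association.
#' @param gene_track Optional gene `annotation_track` for neighbor
#'   annotation.
#' @param min_dev,identity_frac,window_bp Stage parameters (see the
#'   stage functions).
#' @param genome Optional `genome_build`.
#' @return A `cnv_segments` data.frame with association columns (`beta`,
#'   `p_value`, `fdr_q`, per-state counts, representative probe, neighbor
#'   genes), one row per segment, ordered by genome position. Empty (with a
#'   warning) when no probe passes selection.
#' @export
run_cnv_gwas <- function(calls, probe_map, phenotypes, gene_track = NULL,
                         min_dev = 0.05, identity_frac = 0.95,
                         window_bp = 450000, genome = NULL) {
  samples <- sort(unique(c(calls$sample_id, phenotypes$sample_id)))
  mat <- assign_probe_cn(calls, probe_map, samples)
  selected <- select_variable_probes(mat, min_dev = min_dev)
  if (length(selected) == 0L) {
    warning("no probe deviates from 2n in >= ", min_dev,
            " of the population; empty association table")
    seg <- build_segments(character(), mat, identity_frac)
    seg$representative_probe <- character()
    seg$beta <- numeric()
    seg$p_value <- numeric()
    seg$fdr_q <- numeric()
    return(seg)
  }
  assoc <- probe_association_all(mat, selected, phenotypes)
  seg <- build_segments(selected, mat, identity_frac = identity_frac)
  seg <- score_segments(seg, assoc, mat)
  seg$fdr_q <- fdr_adjust(seg$p_value)
  if (!is.null(gene_track)) {
    seg <- annotate_neighbors(seg, gene_track, window_bp = window_bp,
                              genome = genome)
  }
  seg
}

#' Write an association table as TSV
#'
#' One row per segment: location, probe count, probe ids, representative
#' probe, effect, p-value, q-value, per-state animal counts, and (when
#' annotated) the neighboring genes.
#'
#' @param segments Output of [run_cnv_gwas()].
#' @param path Output path.
#' @export
write_assoc_table <- function(segments, path) {
  df <- as.data.frame(segments[, !(names(segments) %in%
                                     c("probe_ids", "neighbor_genes"))])
  if ("probe_ids" %in% names(segments)) {
    df$probe_ids <- vapply(segments$probe_ids, paste, character(1),
                           collapse = ",")
  }
  if ("neighbor_genes" %in% names(segments)) {
    df$neighbor_genes <- vapply(segments$neighbor_genes, function(g) {
      paste(g$name, collapse = ",")
    }, character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
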