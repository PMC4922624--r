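#' All pairwise overlaps between two interval sets
#'
#' Reports every (query, target) pair sharing at least `min_bp` bases, with
#' the shared width, the fraction of each interval covered, and a
#' classification of the overlap geometry.
#'
#' @param query,target `annotation_track`s or `cnv_regions` (any data.frame
#'   with `chrom`, `start`, `end` and an id column `name` or `region_id`).
#' @param min_bp Minimum shared bases for a pair to be reported.
#' @return A data.frame with columns `query_id`, `target_id`, `overlap_bp`,
#'   `query_fraction`, `target_fraction`, `overlap_type` (one of
#'   `"identical"`, `"query_within_target"`, `"target_within_query"`,
#'   `"partial"`).
#' @export
find_overlaps <- function(query, target, min_bp = 1L) {
  qid <- interval_ids(query)
  tid <- interval_ids(target)
  out <- list()
  for (chrom in intersect(unique(query$chrom), unique(target$chrom))) {
    qi <- which(query$chrom == chrom)
    ti <- which(target$chrom == chrom)
    qr <- IRanges::IRanges(start = query$start[qi], end = query$end[qi])
    tr <- IRanges::IRanges(start = target$start[ti], end = target$end[ti])
    hit <- IRanges::findOverlaps(qr, tr, minoverlap = min_bp)
    if (length(hit) == 0L) next
    qh <- S4Vectors::queryHits(hit)
    th <- S4Vectors::subjectHits(hit)
    ov <- IRanges::width(IRanges::pintersect(qr[qh], tr[th]))
    qw <- IRanges::width(qr[qh])
    tw <- IRanges::width(tr[th])
    type <- ifelse(ov == qw & ov == tw, "identical",
            ifelse(ov == qw, "query_within_target",
            ifelse(ov == tw, "target_within_query", "partial")))
    out[[chrom]] <- data.frame(
      query_id = qid[qi[qh]], target_id = tid[ti[th]],
      overlap_bp = ov, query_fraction = ov / qw, target_fraction = ov / tw,
      overlap_type = type, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(query_id = character(), target_id = character(),
                      overlap_bp = integer(), query_fraction = numeric(),
                      target_fraction = numeric(), overlap_type = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

interval_ids <- function(x) {
  if ("region_id" %in% names(x)) return(x$region_id)
  if ("name" %in% names(x)) return(x$name)
  as.character(seq_len(nrow(x)))
}

#' Match intervals between two studies by mutual overlap
#'
#' Two intervals are considered the same event when each covers strictly more
#' than `threshold` of the other (reciprocal overlap), the usual rule for
#' declaring a CNVR "detected by both studies".
#'
#' @param set_a,set_b Interval sets (see [find_overlaps()]).
#' @param threshold Mutual overlap fraction (strict).
#' @return A data.frame of matched pairs (subset of [find_overlaps()] rows
#'   renamed `a_id`/`b_id`).
#' @export
mutual_overlap_match <- function(set_a, set_b, threshold = 0.7) {
  ov <- find_overlaps(set_a, set_b)
  keep <- ov$query_fraction > threshold & ov$target_fraction > threshold
  res <- ov[keep, , drop = FALSE]
  names(res)[names(res) == "query_id"] <- "a_id"
  names(res)[names(res) == "target_id"] <- "b_id"
  rownames(res) <- NULL
  res
}

#' Randomize regions preserving size and chromosome
#'
#' Replaces each region by a uniformly placed interval of identical length,
#' by default on the same chromosome, the null model of the permutation
#' overlap test. Regions longer than `max_len_bp` are removed first (very
#' long regions are extreme outliers that cannot be placed representatively).
#' Randomized regions may overlap one another unless `allow_overlap = FALSE`.
#'
#' @param regions Interval set with `chrom`, `start`, `end`.
#' @param genome A `genome_build`.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param same_chromosome Keep each region on its own chromosome (default);
#'   otherwise a chromosome is drawn with probability proportional to its
#'   number of valid placements.
#' @param max_len_bp Regions strictly longer than this are dropped.
#' @param allow_overlap Permit randomized regions to overlap each other.
#' @return A data.frame with `chrom`, `start`, `end`, `name`.
#' @export
randomize_regions <- function(regions, genome, seed = NULL,
                              same_chromosome = TRUE, max_len_bp = 1e6,
                              allow_overlap = TRUE) {
  stopifnot(inherits(genome, "genome_build"))
  if (!is.null(seed)) set.seed(seed)
  lens <- regions$end - regions$start + 1
  keep <- lens <= max_len_bp
  regions <- regions[keep, , drop = FALSE]
  lens <- lens[keep]
  n <- nrow(regions)
  if (n == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), stringsAsFactors = FALSE))
  }
  chroms <- character(n)
  starts <- numeric(n)
  placed <- list()
  for (i in seq_len(n)) {
    if (same_chromosome) {
      chrom <- regions$chrom[i]
      room <- chrom_length(genome, chrom) - lens[i] + 1
      if (is.na(room) || room < 1) {
        stop("region ", interval_ids(regions)[i], " of length ", lens[i],
             " does not fit on chromosome ", chrom)
      }
    } else {
      rooms <- pmax(genome$length - lens[i] + 1, 0)
      if (sum(rooms) < 1) {
        stop("region of length ", lens[i], " does not fit on any chromosome")
      }
      chrom <- sample(genome$chrom, 1L, prob = rooms / sum(rooms))
      room <- chrom_length(genome, chrom) - lens[i] + 1
    }
    for (try in seq_len(200L)) {
      s <- if (room == 1) 1 else floor(stats::runif(1, 1, room + 1))
      s <- min(s, room)  # guard the open upper bound of runif
      if (allow_overlap) break
      prev <- placed[[chrom]]
      cand <- IRanges::IRanges(start = s, width = lens[i])
      if (is.null(prev) ||
          length(IRanges::findOverlaps(cand, prev, minoverlap = 1L)) == 0L) {
        break
      }
      if (try == 200L) {
        stop("could not place non-overlapping random region after 200 tries")
      }
    }
    if (!allow_overlap) {
      prev <- placed[[chrom]]
      cur <- IRanges::IRanges(start = s, width = lens[i])
      placed[[chrom]] <- if (is.null(prev)) cur else c(prev, cur)
    }
    chroms[i] <- chrom
    starts[i] <- s
  }
  data.frame(chrom = chroms, start = starts, end = starts + lens - 1,
             name = paste0("rand_", seq_len(n)), stringsAsFactors = FALSE)
}

#' Empirical permutation p-value with the add-one estimator
#'
#' `p = (k + 1) / (n_perm + 1)` where `k` is the number of permutations at
#' least as extreme as the observed value. The estimator counts the observed
#' arrangement itself as one permutation, so `p` is never 0 and the smallest
#' attainable value is `1/(n_perm + 1)`; with 1000 permutations and `k = 0`
#' the result prints as "< 0.001".
#'
#' @param k Number of permutations at least as extreme as observed.
#' @param n_perm Number of permutations.
#' @return The empirical p-value.
#' @export
empirical_pvalue <- function(k, n_perm) {
  stopifnot(all(k >= 0), all(k <= n_perm), all(n_perm >= 1))
  (k + 1) / (n_perm + 1)
}

#' Permutation test of genomic overlap
#'
#' Tests whether `query` regions overlap `target` more or less than expected
#' by chance, by repeatedly replacing the query with random regions matched
#' in size and chromosomal distribution ([randomize_regions()]) and
#' recomputing the overlap measure. Two measures are available: the number of
#' query regions overlapping at least one target region (`"region_count"`),
#' and the total genomic size in bp shared between the two sets
#' (`"total_bp"`, symmetric in query and target). Query regions longer than
#' `max_len_bp` are excluded from both the observed measure and the null, so
#' the two are comparable. Permutations whose measure equals the observed
#' value count as extreme; the p-value uses the add-one estimator of
#' [empirical_pvalue()] and is one-sided.
#'
#' @param query,target Interval sets with `chrom`, `start`, `end`.
#' @param genome A `genome_build`.
#' @param n_perm Number of permutations (>= 1).
#' @param measure `"region_count"` or `"total_bp"`.
#' @param alternative `"less"`, `"greater"`, or `"auto"` (pick by the sign of
#'   observed minus null mean).
#' @param seed Integer seed; the result is bit-identical for the same seed.
#' @param max_len_bp Query regions strictly longer than this are excluded.
#' @param allow_overlap Passed to [randomize_regions()].
#' @return A `permutation_result` list: `measure`, `observed`, `null_mean`,
#'   `null_sd`, `n_perm`, `alternative`, `p_value`, `seed`, and the vector of
#'   permuted measures `null_values`.
#' @export
permutation_overlap_test <- function(query, target, genome, n_perm = 1000,
                                     measure = c("region_count", "total_bp"),
                                     alternative = c("auto", "less", "greater"),
                                     seed = NULL, max_len_bp = 1e6,
                                     allow_overlap = TRUE) {
  measure <- match.arg(measure)
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 1)
  if (nrow(query) == 0L) stop("empty query region set")
  lens <- query$end - query$start + 1
  query <- query[lens <= max_len_bp, , drop = FALSE]
  if (nrow(query) == 0L) stop("no query regions left after length exclusion")

  observed <- overlap_measure(query, target, measure)
  if (!is.null(seed)) set.seed(seed)
  null_values <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    rand <- randomize_regions(query, genome, seed = NULL,
                              same_chromosome = TRUE, max_len_bp = max_len_bp,
                              allow_overlap = allow_overlap)
    null_values[b] <- overlap_measure(rand, target, measure)
  }
  null_mean <- mean(null_values)
  null_sd <- stats::sd(null_values)
  if (n_perm == 1L) null_sd <- 0
  if (alternative == "auto") {
    alternative <- if (observed >= null_mean) "greater" else "less"
  }
  k <- if (alternative == "less") sum(null_values <= observed) else
    sum(null_values >= observed)
  structure(list(measure = measure, observed = observed,
                 null_mean = null_mean, null_sd = null_sd, n_perm = n_perm,
                 alternative = alternative,
                 p_value = empirical_pvalue(k, n_perm), seed = seed,
                 null_values = null_values),
            class = "permutation_result")
}

overlap_measure <- function(query, target, measure) {
  if (nrow(target) == 0L) return(0)
  if (measure == "region_count") {
    n <- 0L
    for (chrom in intersect(unique(query$chrom), unique(target$chrom))) {
      qr <- IRanges::IRanges(start = query$start[query$chrom == chrom],
                             end = query$end[query$chrom == chrom])
      tr <- IRanges::IRanges(start = target$start[target$chrom == chrom],
                             end = target$end[target$chrom == chrom])
      n <- n + sum(IRanges::overlapsAny(qr, tr, minoverlap = 1L))
    }
    n
  } else {
    bp <- 0
    for (chrom in intersect(unique(query$chrom), unique(target$chrom))) {
      qr <- IRanges::reduce(IRanges::IRanges(
        start = query$start[query$chrom == chrom],
        end = query$end[query$chrom == chrom]))
      tr <- IRanges::reduce(IRanges::IRanges(
        start = target$start[target$chrom == chrom],
        end = target$end[target$chrom == chrom]))
      bp <- bp + sum(IRanges::width(IRanges::intersect(qr, tr)))
    }
    bp
  }
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation overlap test (%s, alternative=%s, N=%d)\n",
              x$measure, x$alternative, x$n_perm))
  cat(sprintf("  observed %.4g, null %.4g +/- %.4g, p = %.4g%s\n",
              x$observed, x$null_mean, x$null_sd, x$p_value,
              if (x$p_value <= 1 / (x$n_perm + 1))
                sprintf(" (< %.3g)", 1 / x$n_perm) else ""))
  invisible(x)
}

#' Batch permutation tests against several annotation tracks
#'
#' Runs [permutation_overlap_test()] of one query set against each track in
#' a named list, producing the one-row-per-track table of observed overlap,
#' null mean and sd, and permutation p-value.
#'
#' @param query Interval set.
#' @param tracks Named list of annotation tracks.
#' @param genome A `genome_build`.
#' @param seed Root seed; track `i` uses `seed + i - 1`.
#' @param ... Passed to [permutation_overlap_test()].
#' @return A data.frame with columns `track`, `measure`, `observed`,
#'   `null_mean`, `null_sd`, `alternative`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_overlap_batch <- function(query, tracks, genome, seed = 1, ...) {
  stopifnot(length(tracks) > 0, !is.null(names(tracks)))
  rows <- lapply(seq_along(tracks), function(i) {
    r <- permutation_overlap_test(query, tracks[[i]], genome,
                                  seed = seed + i - 1, ...)
    data.frame(track = names(tracks)[i], measure = r$measure,
               observed = r$observed, null_mean = r$null_mean,
               null_sd = r$null_sd, alternative = r$alternative,
               p_value = r$p_value, n_perm = r$n_perm, seed = r$seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
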