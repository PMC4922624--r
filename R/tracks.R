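#' Construct an annotation track
#'
#' An annotation track is a labelled set of genomic intervals (genes, QTLs,
#' known CNV regions, ...). Internally all intervals are 1-based and
#' inclusive on both ends; conversion from BED's 0-based half-open convention
#' happens only in [read_bed_track()] / [write_bed_track()].
#'
#' @param chrom,start,end,name Interval columns (name optional).
#' @param label Track label, e.g. `"genes"`.
#' @return An `annotation_track` data.frame with columns `chrom`, `start`,
#'   `end`, `name` and a `label` attribute.
#' @export
annotation_track <- function(chrom, start, end, name = NULL, label = "track") {
  if (is.null(name)) name <- paste0(label, "_", seq_along(chrom))
  if (length(chrom) == 0L) name <- character()
  df <- data.frame(chrom = normalize_chrom(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   name = as.character(name), stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("interval start > end")
  if (any(df$start < 1)) stop("intervals must have start >= 1 (1-based)")
  attr(df, "label") <- label
  class(df) <- c("annotation_track", "data.frame")
  df
}

#' @rdname annotation_track
#' @param track An `annotation_track`.
#' @export
track_label <- function(track) attr(track, "label")

#' Read a BED3+ file as an annotation track
#'
#' BED coordinates (0-based, half-open) are converted to the internal 1-based
#' inclusive convention on read. Intervals on chromosomes absent from
#' `genome`, or extending past the chromosome end, are skipped with a warning
#' (or rejected, with `on_invalid = "error"`).
#'
#' @param path Path to a BED file (tab separated, no header; track/browser
#'   lines and `#` comments are ignored).
#' @param label Track label.
#' @param genome Optional `genome_build` used to validate intervals.
#' @param on_invalid `"skip"` (default) or `"error"` for out-of-bounds or
#'   unknown-chromosome intervals.
#' @return An `annotation_track`.
#' @export
read_bed_track <- function(path, label = "track", genome = NULL,
                           on_invalid = c("skip", "error")) {
  on_invalid <- match.arg(on_invalid)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    return(annotation_track(character(), numeric(), numeric(), label = label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3L) stop("BED file '", path, "' has fewer than 3 columns")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- as.numeric(vapply(fields, `[[`, character(1), 2L))
  end0 <- as.numeric(vapply(fields, `[[`, character(1), 3L))
  if (any(is.na(start0)) || any(is.na(end0))) {
    stop("non-numeric coordinates in BED file '", path, "'")
  }
  if (any(start0 > end0)) stop("BED interval with start > end in '", path, "'")
  name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4]] else NA_character_,
                 character(1))
  if (all(is.na(name))) name <- NULL
  # BED half-open [start0, end0) -> 1-based inclusive [start0 + 1, end0]
  tr <- annotation_track(chrom, start0 + 1, pmax(end0, start0 + 1),
                         name = name, label = label)
  if (!is.null(genome)) {
    known <- tr$chrom %in% genome$chrom
    within <- known & tr$end <= chrom_length(genome, tr$chrom)
    ok <- known & within
    if (any(!ok)) {
      msg <- sprintf("%d interval(s) outside genome bounds in '%s'",
                     sum(!ok), path)
      if (on_invalid == "error") stop(msg)
      warning(msg, "; skipped")
      tr <- tr[ok, , drop = FALSE]
      attr(tr, "label") <- label
      class(tr) <- c("annotation_track", "data.frame")
    }
  }
  tr
}

#' Write an annotation track (or CNV regions) as BED
#'
#' Internal 1-based inclusive intervals are converted back to BED's 0-based
#' half-open convention, so `write_bed_track()` then [read_bed_track()] is the
#' identity on (chrom, start, end, name).
#'
#' @param track An `annotation_track` or any data.frame with `chrom`, `start`,
#'   `end` columns (optionally `name` and extra columns, written as columns
#'   5+).
#' @param path Output path.
#' @param extra_cols Character vector of additional column names to append
#'   after the BED name column.
#' @export
write_bed_track <- function(track, path, extra_cols = NULL) {
  name <- if ("name" %in% names(track)) track$name else
    paste0("iv_", seq_len(nrow(track)))
  out <- data.frame(chrom = paste0("chr", track$chrom),
                    start = format(track$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(track$end, scientific = FALSE, trim = TRUE),
                    name = name, stringsAsFactors = FALSE)
  for (col in extra_cols) out[[col]] <- track[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample-to-phenotype table
#'
#' Two-column TSV with header `sample_id<TAB>phenotype`, one row per sample.
#' Duplicate samples or non-finite values are rejected: a phenotype table is
#' a mapping, not a long table of repeated measures.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `sample_id` and `phenotype`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric"))
  names(df) <- c("sample_id", "phenotype")
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in phenotype table '", path, "'")
  }
  if (any(!is.finite(df$phenotype))) {
    stop("non-finite phenotype values in '", path, "'")
  }
  df
}

#' Write a phenotype table
#' @param phenotypes Data.frame with `sample_id`, `phenotype`.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes[, c("sample_id", "phenotype")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an array probe map
#'
#' Three-column TSV with header `probe_id<TAB>chrom<TAB>pos` giving the
#' genomic position of each array probe. The map is sorted stably by
#' (chromosome in `genome` order if supplied, else first appearance; then
#' position; then probe id), the order all downstream probe-wise operations
#' assume.
#'
#' @param path Path to the TSV.
#' @param genome Optional `genome_build` fixing the chromosome order.
#' @return A data.frame with columns `probe_id`, `chrom`, `pos`, sorted.
#' @export
read_probe_map <- function(path, genome = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"))
  names(df) <- c("probe_id", "chrom", "pos")
  df$chrom <- normalize_chrom(df$chrom)
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe ids in probe map '", path, "'")
  }
  sort_probe_map(df, genome)
}

sort_probe_map <- function(df, genome = NULL) {
  chrom_levels <- if (!is.null(genome)) {
    genome$chrom
  } else {
    # numeric-aware natural order: "2" before "10", names after numbers
    u <- unique(df$chrom)
    num <- suppressWarnings(as.numeric(u))
    u[order(!is.na(num), num, u, decreasing = c(TRUE, FALSE, FALSE),
            method = "radix")]
  }
  ord <- order(match(df$chrom, chrom_levels), df$pos, df$probe_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a probe map
#' @param probe_map Data.frame with `probe_id`, `chrom`, `pos`.
#' @param path Output path.
#' @export
write_probe_map <- function(probe_map, path) {
  out <- probe_map[, c("probe_id", "chrom", "pos")]
  out$pos <- format(out$pos, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
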