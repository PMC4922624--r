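#' Construct a CNV call table
#'
#' A CNV call is one per-sample event emitted by an HMM-based caller: a
#' chromosome interval, an integer copy number state (0n-4n, never 2n since a
#' call is by definition a deviation from the diploid state), and the number
#' of array probes supporting it. Coordinates are 1-based and inclusive on
#' both ends, the convention of the PennCNV text format; `length` is always
#' `end - start + 1`.
#'
#' @param sample_id,chrom,start,end,cn,num_snps Vectors of equal length
#'   (recycled where length 1).
#' @return A `cnv_calls` data.frame with columns `sample_id`, `chrom`,
#'   `start`, `end`, `cn`, `num_snps`, `length`.
#' @export
cnv_calls <- function(sample_id, chrom, start, end, cn, num_snps = 1L) {
  df <- data.frame(sample_id = as.character(sample_id),
                   chrom = normalize_chrom(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   cn = as.integer(cn), num_snps = as.integer(num_snps),
                   stringsAsFactors = FALSE)
  bad <- df$start > df$end
  if (any(bad)) {
    stop("start > end for ", sum(bad), " call(s)")
  }
  if (any(df$cn < 0L | df$cn > 4L)) {
    stop("copy number states must be integers in 0..4")
  }
  if (any(df$cn == 2L)) {
    stop("cn=2 records are not CNV calls (diploid state); reject upstream")
  }
  if (any(df$num_snps < 1L)) stop("num_snps must be >= 1")
  df$length <- df$end - df$start + 1
  class(df) <- c("cnv_calls", "data.frame")
  df
}

#' Read per-sample CNV calls in the PennCNV text format
#'
#' Parses the whitespace-delimited "rawcnv" dialect, one call per line:
#'
#' ```
#' chr3:22796624-22815905  numsnp=10  length=19,282  state5,cn=3  SAMPLE  startsnp=p1 endsnp=p10
#' ```
#'
#' Thousands separators in the `length` field are stripped. The stated length
#' is cross-checked against `end - start + 1`; a discrepancy over 1 bp is
#' reported with a warning and the coordinates win. Records with `cn=2` or
#' `cn` outside 0..4 are rejected with an error (a call must deviate from the
#' diploid state).
#'
#' @param path Path to a rawcnv file.
#' @param sample_id Fallback sample identifier used when a line carries no
#'   sample field; defaults to the file name without extension.
#' @return A `cnv_calls` data.frame (zero rows for an empty file).
#' @export
read_penncnv_calls <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(cnv_calls(character(), character(), numeric(),
                     numeric(), integer(), integer()))
  }
  loc_re <- "^(chr)?([^:[:space:]]+):([0-9,]+)-([0-9,]+)$"
  n <- length(lines)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(tok) < 4L || !grepl(loc_re, tok[1])) {
      stop(sprintf("malformed rawcnv line %d in '%s': %s", i, path, lines[[i]]))
    }
    chrom <- sub(loc_re, "\\2", tok[1])
    start <- as.numeric(gsub(",", "", sub(loc_re, "\\3", tok[1])))
    end   <- as.numeric(gsub(",", "", sub(loc_re, "\\4", tok[1])))
    numsnp_tok <- grep("^numsnp=", tok, value = TRUE)
    len_tok    <- grep("^length=", tok, value = TRUE)
    cn_tok     <- grep("cn=", tok, value = TRUE)
    if (length(numsnp_tok) != 1L || length(cn_tok) != 1L) {
      stop(sprintf("malformed rawcnv line %d in '%s': missing numsnp= or cn= field",
                   i, path))
    }
    num_snps <- as.integer(sub("^numsnp=", "", numsnp_tok))
    cn <- suppressWarnings(as.integer(sub("^.*cn=", "", cn_tok)))
    if (is.na(cn) || cn < 0L || cn > 4L) {
      stop(sprintf("line %d in '%s': copy number state outside 0..4", i, path))
    }
    if (cn == 2L) {
      stop(sprintf("line %d in '%s': cn=2 is the diploid state, not a CNV call",
                   i, path))
    }
    if (length(len_tok) == 1L) {
      stated <- as.numeric(gsub(",", "", sub("^length=", "", len_tok)))
      if (is.finite(stated) && abs(stated - (end - start + 1)) > 1) {
        warning(sprintf(
          "line %d in '%s': stated length %g disagrees with coordinates (%g); using coordinates",
          i, path, stated, end - start + 1))
      }
    }
    # the sample field is the first bare token after the three key=value fields
    bare <- tok[-1]
    bare <- bare[!grepl("=", bare)]
    samp <- if (length(bare) >= 1L) bare[1] else sample_id
    out[[i]] <- list(samp, chrom, start, end, cn, num_snps)
  }
  m <- do.call(rbind, lapply(out, function(x) {
    data.frame(sample_id = x[[1]], chrom = x[[2]], start = x[[3]],
               end = x[[4]], cn = x[[5]], num_snps = x[[6]],
               stringsAsFactors = FALSE)
  }))
  cnv_calls(m$sample_id, m$chrom, m$start, m$end, m$cn, m$num_snps)
}

#' Write CNV calls in the PennCNV text format
#'
#' @param calls A `cnv_calls` data.frame.
#' @param path Output path.
#' @export
write_penncnv_calls <- function(calls, path) {
  # state field mirrors PennCNV's state numbering for the four CNV states
  state_of <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)
  lines <- sprintf("chr%s:%d-%d numsnp=%d length=%d state%d,cn=%d %s startsnp=NA endsnp=NA",
                   calls$chrom, as.integer(calls$start), as.integer(calls$end),
                   calls$num_snps, as.integer(calls$length),
                   state_of[as.character(calls$cn)], calls$cn, calls$sample_id)
  writeLines(lines, path)
  invisible(path)
}

#' Quality-filter CNV calls
#'
#' Applies the standard call-level QC used for SNP-array CNV maps:
#' low-quality samples with more than `max_calls_per_sample` calls are dropped
#' entirely (an inflated call count indicates noisy intensity data), calls
#' shorter than `min_len_bp` are removed (short calls are poorly concordant
#' with CGH), and calls on non-autosomal chromosomes are removed. Sample
#' exclusion uses the pre-filter call count, as the caller's own QC does.
#' Each removed call is tallied under exactly one reason with precedence
#' sample > chromosome > length.
#'
#' @param calls A `cnv_calls` data.frame.
#' @param genome A `genome_build` defining the autosomes.
#' @param min_len_bp Minimum call length retained, in bp. Calls strictly
#'   shorter are removed; a call of exactly `min_len_bp` survives.
#' @param max_calls_per_sample Samples with strictly more calls than this are
#'   excluded.
#' @param autosomes_only Drop calls on non-autosomal chromosomes.
#' @return A list with elements `calls` (the surviving `cnv_calls`) and
#'   `qc` (a `cnv_qc_report`).
#' @export
filter_calls <- function(calls, genome, min_len_bp = 5000,
                         max_calls_per_sample = 150, autosomes_only = TRUE) {
  stopifnot(inherits(genome, "genome_build"))
  n_input <- nrow(calls)
  counts <- table(calls$sample_id)
  bad_samples <- names(counts)[counts > max_calls_per_sample]
  removed_samples <- as.integer(counts[bad_samples])
  names(removed_samples) <- bad_samples

  keep <- !(calls$sample_id %in% bad_samples)
  n_removed_sample <- sum(!keep)
  surv <- calls[keep, , drop = FALSE]

  if (autosomes_only) {
    on_auto <- surv$chrom %in% autosomes(genome)
  } else {
    on_auto <- surv$chrom %in% genome$chrom
  }
  n_removed_sex <- sum(!on_auto)
  surv <- surv[on_auto, , drop = FALSE]

  long_enough <- surv$length >= min_len_bp
  n_removed_short <- sum(!long_enough)
  surv <- surv[long_enough, , drop = FALSE]
  rownames(surv) <- NULL
  class(surv) <- c("cnv_calls", "data.frame")

  qc <- structure(list(
    n_input_calls = n_input,
    n_removed_short = n_removed_short,
    n_removed_sex_chrom = n_removed_sex,
    removed_samples = removed_samples,
    n_removed_sample_qc = n_removed_sample,
    n_output_calls = nrow(surv)
  ), class = "cnv_qc_report")
  stopifnot(qc$n_output_calls ==
    qc$n_input_calls - qc$n_removed_short - qc$n_removed_sex_chrom -
      qc$n_removed_sample_qc)
  list(calls = surv, qc = qc)
}

#' @export
print.cnv_qc_report <- function(x, ...) {
  cat("CNV call QC report\n")
  cat(sprintf("  input calls:            %d\n", x$n_input_calls))
  cat(sprintf("  removed, sample QC:     %d (%d sample(s) > call limit)\n",
              x$n_removed_sample_qc, length(x$removed_samples)))
  cat(sprintf("  removed, non-autosomal: %d\n", x$n_removed_sex_chrom))
  cat(sprintf("  removed, short:         %d\n", x$n_removed_short))
  cat(sprintf("  output calls:           %d\n", x$n_output_calls))
  invisible(x)
}

#' Serialize a QC report as a two-column TSV
#'
#' @param qc A `cnv_qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(qc, path) {
  dropped <- names(qc$removed_samples) %||% character()
  df <- data.frame(
    metric = c("n_input_calls", "n_removed_sample_qc", "n_removed_sex_chrom",
               "n_removed_short", "n_output_calls",
               if (length(dropped)) paste0("removed_sample:", dropped)),
    value = c(qc$n_input_calls, qc$n_removed_sample_qc, qc$n_removed_sex_chrom,
              qc$n_removed_short, qc$n_output_calls,
              unname(qc$removed_samples)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
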