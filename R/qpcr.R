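#' Efficiency-correct a qPCR cycle threshold
#'
#' A primer with amplification efficiency `E` multiplies template by `E` per
#' cycle rather than doubling it, so `ct` cycles at efficiency `E` correspond
#' to `ct * log2(E)` cycles of a perfectly doubling reaction. Correction puts
#' all primers on the base-2 cycle scale that the Delta-Delta-Ct arithmetic
#' assumes; at `E = 2` it is the identity.
#'
#' @param ct Cycle threshold value(s).
#' @param efficiency Amplification factor per cycle, in (1, 2].
#' @return Corrected cycle threshold(s).
#' @export
efficiency_correct <- function(ct, efficiency) {
  if (any(efficiency <= 1) || any(efficiency > 2)) {
    stop("efficiency must be in (1, 2]")
  }
  ct * log2(efficiency)
}

#' Normalized ratio from Delta-Delta-Ct
#'
#' `NR = 2 * 2^(-ddct)`: the copy number estimate implied by a
#' Delta-Delta-Ct value relative to a diploid (2n) reference. `ddct = 0`
#' gives 2 copies, each cycle earlier (-1) doubles the estimate.
#'
#' @param ddct Delta-Delta-Ct value(s).
#' @return Normalized ratio(s).
#' @export
normalized_ratio <- function(ddct) {
  2 * 2^(-ddct)
}

#' Categorize a normalized ratio into a copy number state
#'
#' State boundaries are the geometric means of adjacent integer copy numbers:
#' state `n` (1-4) is assigned when `sqrt(n(n-1)) < NR <= sqrt(n(n+1))`, and
#' ratios above `sqrt(20)` become state 5 (gain of more than two copies). A
#' ratio exactly on a boundary takes the lower state. Lack of amplification
#' is a complete deletion, state 0, regardless of the ratio.
#'
#' @param nr Normalized ratio(s); must be > 0 where `amplified` is `TRUE`.
#' @param amplified Logical; `FALSE` forces state 0.
#' @return Integer copy number state(s) 0-5.
#' @export
categorize_cn <- function(nr, amplified = TRUE) {
  n <- max(length(nr), length(amplified))
  nr <- rep_len(nr, n)
  amplified <- rep_len(amplified, n)
  if (any(amplified & (!is.finite(nr) | nr <= 0))) {
    stop("normalized ratio must be positive for amplified reactions")
  }
  upper <- sqrt((1:4) * (2:5))  # sqrt(2), sqrt(6), sqrt(12), sqrt(20)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (!amplified[i]) {
      out[i] <- 0L
    } else {
      k <- which(nr[i] <= upper)
      out[i] <- if (length(k) == 0L) 5L else k[1]
    }
  }
  out
}

#' Read a qPCR plate table
#'
#' TSV with header and columns `sample_id`, `primer_id`, `region_id`,
#' `target_ct1..3`, `control_ct1..3`, `efficiency`, `amplified`
#' (TRUE/FALSE). The control columns are the control-gene triplicate of the
#' same sample.
#'
#' @param path Path to the TSV.
#' @return A data.frame of plate records.
#' @export
read_qpcr_plate <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "primer_id", "region_id",
            paste0("target_ct", 1:3), paste0("control_ct", 1:3),
            "efficiency", "amplified")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("qPCR plate '", path, "' is missing columns: ",
         paste(miss, collapse = ", "))
  }
  df$amplified <- as.logical(df$amplified)
  df
}

#' Write a qPCR plate table
#' @param plate Plate data.frame (see [read_qpcr_plate()]).
#' @param path Output path.
#' @export
write_qpcr_plate <- function(plate, path) {
  utils::write.table(plate, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quantify copy number from a qPCR plate
#'
#' For each record: the triplicate target and control cycle thresholds are
#' efficiency-corrected and averaged (optionally after dropping a single
#' outlier replicate deviating more than 1 cycle from the replicate median);
#' `dct` is mean target minus mean control; `ddct` is `dct` minus the
#' reference `dct`, which is the average `dct` over the samples called
#' diploid by the array for that primer; `nr = 2 * 2^(-ddct)`; and the state
#' is assigned by [categorize_cn()]. Records without amplification become
#' state 0 directly.
#'
#' @param plate Plate data.frame (see [read_qpcr_plate()]).
#' @param array_cn Data.frame `sample_id`, `region_id`, `cn` giving the
#'   array-derived copy number of each tested sample in each tested region
#'   (2 = diploid). Used only to identify the 2n reference samples.
#' @param drop_outlier_replicate Drop one replicate deviating > 1 cycle from
#'   the median of its triplicate (off by default).
#' @return `plate` with added columns `dct`, `ddct`, `nr`, `cn_category`.
#' @export
analyze_qpcr <- function(plate, array_cn, drop_outlier_replicate = FALSE) {
  agg_ct <- function(cts, eff) {
    cts <- efficiency_correct(cts[is.finite(cts)], eff)
    if (drop_outlier_replicate && length(cts) >= 3L) {
      dev <- abs(cts - stats::median(cts))
      if (max(dev) > 1) cts <- cts[-which.max(dev)]
    }
    if (length(cts) == 0L) return(NA_real_)
    mean(cts)
  }
  tmean <- cmean <- numeric(nrow(plate))
  for (i in seq_len(nrow(plate))) {
    tmean[i] <- agg_ct(as.numeric(plate[i, paste0("target_ct", 1:3)]),
                       plate$efficiency[i])
    cmean[i] <- agg_ct(as.numeric(plate[i, paste0("control_ct", 1:3)]),
                       plate$efficiency[i])
  }
  plate$dct <- tmean - cmean

  key <- paste(plate$sample_id, plate$region_id)
  akey <- paste(array_cn$sample_id, array_cn$region_id)
  arr <- array_cn$cn[match(key, akey)]

  plate$ddct <- NA_real_
  for (primer in unique(plate$primer_id)) {
    sel <- plate$primer_id == primer
    ref_sel <- sel & plate$amplified & !is.na(arr) & arr == 2L &
      is.finite(plate$dct)
    if (!any(ref_sel)) {
      stop("no array-diploid reference sample for primer '", primer,
           "'; the Delta-Delta-Ct reference is undefined")
    }
    reference_dct <- mean(plate$dct[ref_sel])
    plate$ddct[sel] <- plate$dct[sel] - reference_dct
  }
  plate$nr <- ifelse(plate$amplified, normalized_ratio(plate$ddct), NA_real_)
  plate$cn_category <- categorize_cn(ifelse(plate$amplified, plate$nr, 1),
                                     plate$amplified)
  plate
}

#' Array copy number per sample over tested regions
#'
#' Derives the per-sample array state used as the Delta-Delta-Ct reference:
#' for each region and sample, the state of the sample's call with the
#' largest overlap with the region, or 2 (diploid) when the sample has no
#' overlapping call.
#'
#' @param calls A `cnv_calls` data.frame.
#' @param regions Data.frame with `region_id`, `chrom`, `start`, `end`.
#' @param samples Sample ids to tabulate.
#' @return Data.frame `sample_id`, `region_id`, `cn`.
#' @export
array_cn_from_calls <- function(calls, regions, samples) {
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    cn <- rep(2L, length(samples))
    for (j in seq_along(samples)) {
      sc <- calls[calls$sample_id == samples[j] &
                    calls$chrom == regions$chrom[i] &
                    calls$start <= regions$end[i] &
                    calls$end >= regions$start[i], , drop = FALSE]
      if (nrow(sc) > 0L) {
        ov <- pmin(sc$end, regions$end[i]) - pmax(sc$start, regions$start[i]) + 1
        cn[j] <- sc$cn[which.max(ov)]
      }
    }
    rows[[i]] <- data.frame(sample_id = samples,
                            region_id = regions$region_id[i], cn = cn,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Concordance between array calls and qPCR states, per region
#'
#' A tested sample's array type for a region is `loss` if any of its calls
#' overlapping the region has cn < 2, `gain` if any has cn > 2, `normal` with
#' no overlapping call; its qPCR type per record follows from the state
#' (< 2 loss, > 2 gain, = 2 normal). A sample is concordant when the array
#' shows a loss or gain and at least one qPCR record of the same type exists,
#' or when the array shows no call and all qPCR records are diploid
#' (normal/normal agreement counts toward the concordance percentage but not
#' toward validation). A region is validated when at least one sample agrees
#' in a non-normal type. Two percentages are reported: over all tested
#' samples, and over samples that are non-normal on either platform.
#'
#' @param records Analyzed plate (see [analyze_qpcr()]), with `cn_category`.
#' @param calls A `cnv_calls` data.frame (array calls of the tested samples).
#' @param regions A `cnv_regions` data.frame (the tested regions; matched by
#'   `region_id`).
#' @return A data.frame, one row per tested region: `region_id`,
#'   `tested_samples`, `concordant_samples`, `concordance_pct`,
#'   `nonnormal_samples`, `concordant_nonnormal`, `concordance_pct_nonnormal`,
#'   `validated`.
#' @export
qpcr_concordance <- function(records, calls, regions) {
  if (!"cn_category" %in% names(records)) {
    stop("records must be analyzed with analyze_qpcr() first")
  }
  out <- list()
  for (rid in unique(records$region_id)) {
    reg <- regions[regions$region_id == rid, , drop = FALSE]
    if (nrow(reg) != 1L) stop("region '", rid, "' not found in regions")
    rec <- records[records$region_id == rid, , drop = FALSE]
    samples <- unique(rec$sample_id)
    if (length(samples) == 0L) stop("region '", rid, "' has no tested sample")
    conc <- nn <- conc_nn <- 0L
    validated <- FALSE
    for (s in samples) {
      sc <- calls[calls$sample_id == s & calls$chrom == reg$chrom &
                    calls$start <= reg$end & calls$end >= reg$start,
                  , drop = FALSE]
      array_types <- unique(ifelse(sc$cn < 2L, "loss", "gain"))
      qcat <- rec$cn_category[rec$sample_id == s]
      qpcr_types <- unique(ifelse(qcat < 2L, "loss",
                                  ifelse(qcat > 2L, "gain", "normal")))
      shared <- intersect(array_types, setdiff(qpcr_types, "normal"))
      is_nn <- length(array_types) == 0L && identical(qpcr_types, "normal")
      if (length(shared) > 0L) {
        conc <- conc + 1L
        conc_nn <- conc_nn + 1L
        validated <- TRUE
      } else if (is_nn) {
        conc <- conc + 1L
      }
      if (!is_nn) nn <- nn + 1L
    }
    out[[rid]] <- data.frame(
      region_id = rid, tested_samples = length(samples),
      concordant_samples = conc,
      concordance_pct = 100 * conc / length(samples),
      nonnormal_samples = nn,
      concordant_nonnormal = conc_nn,
      concordance_pct_nonnormal = if (nn > 0L) 100 * conc_nn / nn else NA_real_,
      validated = validated, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
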