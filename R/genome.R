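#' Construct a genome build
#'
#' A genome build is the coordinate frame for all interval operations: an
#' ordered set of chromosomes with lengths, plus the subset considered
#' autosomal. CNV analysis from SNP arrays is restricted to autosomes because
#' intensity-based calling on sex chromosomes is confounded by hemizygosity.
#'
#' @param chrom Character vector of chromosome names (unique, non-empty).
#'   Names are normalized by stripping a leading "chr" prefix; comparisons
#'   thereafter are case-sensitive.
#' @param length Integer vector of chromosome lengths in base pairs (> 0).
#' @param autosomes Character vector naming the autosomal subset. Defaults to
#'   all chromosomes except X, Y, MT/M/W/Z (after normalization).
#'
#' @return A `genome_build` object: a data.frame with columns `chrom` and
#'   `length`, with the autosome subset stored as an attribute and retrievable
#'   with [autosomes()].
#' @export
#' @examples
#' gb <- genome_build(c("1", "2", "X"), c(5e6, 4e6, 3e6))
#' autosomes(gb)
genome_build <- function(chrom, length, autosomes = NULL) {
  chrom <- normalize_chrom(as.character(chrom))
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    stop("'chrom' and 'length' must have the same length")
  }
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome names: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (is.null(autosomes)) {
    sex_like <- c("X", "Y", "MT", "M", "W", "Z")
    autosomes <- chrom[!chrom %in% sex_like]
  } else {
    autosomes <- normalize_chrom(as.character(autosomes))
    if (!all(autosomes %in% chrom)) {
      stop("autosomes must be a subset of chromosome names")
    }
  }
  gb <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  attr(gb, "autosomes") <- autosomes
  class(gb) <- c("genome_build", "data.frame")
  gb
}

#' @rdname genome_build
#' @param genome A `genome_build` object.
#' @export
autosomes <- function(genome) {
  stopifnot(inherits(genome, "genome_build"))
  attr(genome, "autosomes")
}

#' Chromosome lengths by name
#'
#' @param genome A `genome_build`.
#' @param chrom Chromosome names (normalized or not).
#' @return Numeric vector of lengths, NA for unknown chromosomes.
#' @export
chrom_length <- function(genome, chrom) {
  stopifnot(inherits(genome, "genome_build"))
  genome$length[match(normalize_chrom(chrom), genome$chrom)]
}

#' Read a two-column chromosome sizes table
#'
#' Standard `chrom.sizes` format: chromosome name and length in bp, tab
#' separated, no header.
#'
#' @param path Path to the file.
#' @param autosomes Optional explicit autosome subset (see [genome_build()]).
#' @return A `genome_build`.
#' @export
read_chrom_sizes <- function(path, autosomes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric"),
                          col.names = c("chrom", "length"))
  genome_build(df$chrom, df$length, autosomes = autosomes)
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("genome_build: %d chromosomes (%d autosomal), %.1f Mb total\n",
              nrow(x), length(attr(x, "autosomes")), sum(x$length) / 1e6))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

# Strip a leading "chr" prefix; everything downstream compares normalized
# names case-sensitively.
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}
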