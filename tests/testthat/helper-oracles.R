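# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package: plain per-base loops and union-find.

# Brute-force CNVR compilation: per-base depth within transitive-overlap
# clusters, density threshold, maximal runs, gain/loss merge, membership.
brute_compile <- function(calls, genome, population_size, recurrence = 0.1) {
  typed <- list()
  for (ty in c("loss", "gain")) {
    sel <- if (ty == "loss") calls$cn < 2 else calls$cn > 2
    for (chrom in unique(calls$chrom[sel])) {
      sub <- calls[sel & calls$chrom == chrom, , drop = FALSE]
      parent <- local({
        n <- nrow(sub)
        p <- seq_len(n)
        find <- function(i) { while (p[i] != i) i <- p[i]; i }
        for (i in seq_len(n)) for (j in seq_len(n)) {
          if (i < j && sub$start[i] <= sub$end[j] &&
              sub$end[i] >= sub$start[j]) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) p[rj] <- ri
          }
        }
        vapply(seq_len(n), find, integer(1))
      })
      for (cl in unique(parent)) {
        m <- which(parent == cl)
        off <- min(sub$start[m]) - 1
        width <- max(sub$end[m]) - off
        depth <- integer(width)
        for (i in m) {
          depth[(sub$start[i] - off):(sub$end[i] - off)] <-
            depth[(sub$start[i] - off):(sub$end[i] - off)] + 1L
        }
        keep <- depth >= 1L & depth >= recurrence * length(m) - 1e-9
        r <- rle(keep)
        pos <- cumsum(c(1, r$lengths))
        for (k in seq_along(r$values)) {
          if (r$values[k]) {
            typed[[length(typed) + 1L]] <- data.frame(
              chrom = chrom, start = off + pos[k],
              end = off + pos[k + 1] - 1, type = ty,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(typed) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), type = character(),
                      n_samples = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE))
  }
  reg <- do.call(rbind, typed)
  # transitive gain/loss merge into "both"
  out <- list()
  for (chrom in unique(reg$chrom)) {
    sub <- reg[reg$chrom == chrom, , drop = FALSE]
    n <- nrow(sub)
    p <- seq_len(n)
    find <- function(i) { while (p[i] != i) i <- p[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && sub$start[i] <= sub$end[j] && sub$end[i] >= sub$start[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) p[rj] <- ri
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cl in unique(comp)) {
      m <- which(comp == cl)
      if (length(unique(sub$type[m])) > 1L) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = min(sub$start[m]), end = max(sub$end[m]),
          type = "both", stringsAsFactors = FALSE)
      } else {
        for (i in m) out[[length(out) + 1L]] <- sub[i, , drop = FALSE]
      }
    }
  }
  reg <- do.call(rbind, out)
  reg <- reg[order(reg$chrom, reg$start), , drop = FALSE]
  reg$n_samples <- vapply(seq_len(nrow(reg)), function(i) {
    m <- calls$chrom == reg$chrom[i] & calls$start <= reg$end[i] &
      calls$end >= reg$start[i]
    length(unique(calls$sample_id[m]))
  }, integer(1))
  reg$frequency <- reg$n_samples / population_size
  rownames(reg) <- NULL
  reg
}

# Random toy call set on a small genome for oracle-equivalence checks.
random_toy_calls <- function(genome, n_calls, n_samples = 8) {
  chrom <- sample(genome$chrom, n_calls, replace = TRUE)
  len <- sample(500:30000, n_calls, replace = TRUE)
  room <- chrom_length(genome, chrom) - len + 1
  keep <- room >= 1
  chrom <- chrom[keep]; len <- len[keep]; room <- room[keep]
  start <- floor(runif(length(room), 1, room + 1))
  cnv_calls(sample_id = paste0("s", sample(n_samples, length(room),
                                           replace = TRUE)),
            chrom = chrom, start = start, end = start + len - 1,
            cn = sample(c(0L, 1L, 3L, 4L), length(room), replace = TRUE),
            num_snps = 5L)
}

# Textbook Benjamini-Hochberg step-up, written independently of the package:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j) on the sorted p-values.
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, m * p[ord] / seq_len(m))
  if (m > 1) {
    for (i in seq(m - 1, 1)) {
      q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
    }
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Comparable view of a compiled region set for oracle equality.
region_key <- function(reg) {
  df <- data.frame(chrom = as.character(reg$chrom), start = reg$start,
                   end = reg$end, type = reg$type,
                   n_samples = reg$n_samples, frequency = reg$frequency,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
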