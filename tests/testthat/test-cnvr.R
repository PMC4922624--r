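toy_genome <- function() genome_build(c("1", "2"), c(1e5, 1e5))

test_that("recurrence trimming removes the low-density tail of a cluster", {
  # ten identical 100 bp loss calls plus one long call from an 11th sample:
  # the long tail is covered by 1 of 11 calls (0.091 < 0.1) and is trimmed
  gb <- toy_genome()
  calls <- cnv_calls(c(paste0("s", 1:10), "s11"), "1",
                     c(rep(101, 10), 101), c(rep(200, 10), 1000),
                     1L)
  reg <- compile_cnvrs(calls, gb, population_size = 100)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 101)
  expect_equal(reg$end, 200)
  expect_equal(reg$type, "loss")
  expect_equal(reg$n_samples, 11L)  # the long call still overlaps the region
  expect_equal(reg$frequency, 11 / 100)
})

test_that("a single call becomes a region equal to its own span", {
  reg <- compile_cnvrs(cnv_calls("a", "1", 1, 5000, 3L), toy_genome(),
                       population_size = 50)
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$start, reg$end), c(1, 5000))
  expect_equal(reg$type, "gain")
  expect_equal(reg$frequency, 1 / 50)
  expect_equal(reg$region_id, "CNVR_1")
})

test_that("overlapping gain and loss regions merge into a 'both' region", {
  calls <- cnv_calls(c("a", "b"), "1", c(1, 51), c(100, 150), c(3L, 1L))
  reg <- compile_cnvrs(calls, toy_genome(), population_size = 10)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$type, "both")
  expect_equal(c(reg$start, reg$end), c(1, 150))
  expect_equal(reg$n_samples, 2L)
})

test_that("'both' merging is transitive across alternating chains", {
  calls <- cnv_calls(c("a", "b", "c"), "1", c(1, 51, 121), c(100, 150, 220),
                     c(3L, 1L, 3L))
  reg <- compile_cnvrs(calls, toy_genome(), population_size = 10)
  # gain [1,100] - loss [51,150]: overlap; gain [121,220] overlaps the loss:
  # the whole chain collapses to one region
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$type, "both")
  expect_equal(c(reg$start, reg$end), c(1, 220))
})

test_that("recurrence 0 yields exactly the per-type transitive unions", {
  set.seed(11)
  gb <- toy_genome()
  for (rep in 1:10) {
    calls <- random_toy_calls(gb, sample(3:25, 1))
    reg <- compile_cnvrs(calls, gb, population_size = 10, recurrence = 0)
    oracle <- brute_compile(calls, gb, population_size = 10, recurrence = 0)
    expect_equal(region_key(reg), oracle)
  }
})

test_that("compiled regions match the per-base brute-force oracle", {
  set.seed(23)
  gb <- toy_genome()
  for (rep in 1:25) {
    calls <- random_toy_calls(gb, sample(3:30, 1))
    reg <- compile_cnvrs(calls, gb, population_size = 10)
    oracle <- brute_compile(calls, gb, population_size = 10)
    expect_equal(region_key(reg), oracle)
  }
})

test_that("raising recurrence never enlarges any region span", {
  set.seed(31)
  gb <- toy_genome()
  for (rep in 1:8) {
    calls <- random_toy_calls(gb, 20)
    low <- compile_cnvrs(calls, gb, 10, recurrence = 0.1)
    high <- compile_cnvrs(calls, gb, 10, recurrence = 0.4)
    expect_lte(sum(high$length), sum(low$length))
    # every high-recurrence region is contained in some low-recurrence one
    for (i in seq_len(nrow(high))) {
      inside <- any(low$chrom == high$chrom[i] &
                      low$start <= high$start[i] & low$end >= high$end[i])
      expect_true(inside)
    }
  }
})

test_that("region set is invariant under permutation of input call order", {
  set.seed(41)
  gb <- toy_genome()
  calls <- random_toy_calls(gb, 25)
  shuffled <- calls[sample(nrow(calls)), ]
  class(shuffled) <- class(calls)
  expect_equal(region_key(compile_cnvrs(calls, gb, 10)),
               region_key(compile_cnvrs(shuffled, gb, 10)))
})

test_that("membership and frequency invariants hold", {
  set.seed(47)
  gb <- toy_genome()
  calls <- random_toy_calls(gb, 30)
  reg <- compile_cnvrs(calls, gb, population_size = 12)
  for (i in seq_len(nrow(reg))) {
    m <- reg$member_calls[[i]]
    expect_true(all(calls$chrom[m] == reg$chrom[i] &
                      calls$start[m] <= reg$end[i] &
                      calls$end[m] >= reg$start[i]))
    # frequency * population is the integer carrier count
    expect_equal(reg$frequency[i] * 12, reg$n_samples[i])
  }
  # no call is a member of two regions of the same type
  for (ty in unique(reg$type)) {
    idx <- unlist(reg$member_calls[reg$type == ty])
    expect_equal(anyDuplicated(idx), 0L)
  }
  expect_error(compile_cnvrs(calls, gb, 12, recurrence = 1), "recurrence")
  expect_error(compile_cnvrs(calls, gb, 2), "population_size")
})

test_that("polymorphic classification is strictly greater than 1%", {
  reg <- compile_cnvrs(cnv_calls("a", "1", 1, 5000, 1L), toy_genome(), 10)
  reg <- rbind(reg, reg, reg)
  reg$frequency <- c(8 / 723, 7 / 723, 1.0)
  reg <- classify_polymorphic(reg)
  expect_equal(reg$polymorphic, c(TRUE, FALSE, TRUE))
})

test_that("fixed-state flag requires both high frequency and a dominant state", {
  gb <- toy_genome()
  mk <- function(cns) {
    calls <- cnv_calls(paste0("s", seq_along(cns)), "1", 1, 5000, cns)
    reg <- compile_cnvrs(calls, gb, population_size = length(cns))
    flag_fixed_state(reg, calls)
  }
  expect_true(mk(c(rep(1L, 96), rep(3L, 4)))$fixed_state)    # 0.96 > 0.95
  expect_false(mk(c(rep(1L, 50), rep(3L, 50)))$fixed_state)  # no dominant state
  # frequency gate: 100 carriers of 200 animals = 0.5 <= 0.75
  calls <- cnv_calls(paste0("s", 1:100), "1", 1, 5000, 1L)
  reg <- compile_cnvrs(calls, gb, population_size = 200)
  expect_false(flag_fixed_state(reg, calls)$fixed_state)
})

test_that("length histogram bins are half-open and fractions sum to one", {
  reg <- data.frame(length = c(10e3, 40e3, 60e3))
  h <- length_histogram(reg, edges = c(5e3, 50e3, Inf))
  expect_equal(h$counts, c(2L, 1L))
  expect_equal(h$fractions, c(2 / 3, 1 / 3))

  h1 <- length_histogram(data.frame(length = 7e3), edges = c(5e3, 50e3, Inf))
  expect_equal(h1$counts, c(1L, 0L))
  expect_equal(h1$fractions, c(1, 0))

  expect_warning(h0 <- length_histogram(data.frame(length = numeric()),
                                        edges = c(5e3, 50e3, Inf)),
                 "no regions")
  expect_equal(h0$fractions, c(0, 0))
  expect_error(length_histogram(reg, edges = c(5e3, 1e3, Inf)), "increasing")
})

test_that("region summaries add up", {
  gb <- genome_build("1", 1e5)
  calls <- cnv_calls(c("a", "b"), "1", c(1, 50001), c(1000, 51000),
                     c(1L, 3L))
  reg <- compile_cnvrs(calls, gb, 2)
  s <- summarize_regions(reg, gb)
  expect_equal(s$n_regions, 2L)
  expect_equal(s$n_loss + s$n_gain + s$n_both, s$n_regions)
  expect_equal(s$genome_fraction, 2000 / 1e5)
  expect_equal(s$per_chromosome$fraction, 0.02)

  s0 <- summarize_regions(empty <- compile_cnvrs(
    cnv_calls(character(), character(), numeric(), numeric(), integer(),
              integer()), gb, 2), gb)
  expect_equal(s0$n_regions, 0L)
  expect_equal(s0$total_bp, 0)
})

test_that("regions round-trip through BED with id, score and type columns", {
  gb <- toy_genome()
  calls <- cnv_calls(c("a", "b"), "1", c(1, 51), c(100, 150), c(3L, 1L))
  reg <- classify_polymorphic(compile_cnvrs(calls, gb, 10))
  reg <- flag_fixed_state(reg, calls)
  f <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(reg, f)
  back <- read_bed_track(f, "cnvr")
  expect_equal(back$start, reg$start)
  expect_equal(back$end, reg$end)
  expect_equal(back$name, reg$region_id)
})
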