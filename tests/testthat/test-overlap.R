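mk_track <- function(chrom, start, end, name = NULL, label = "t") {
  annotation_track(chrom, start, end, name = name, label = label)
}

test_that("overlap records carry width, fractions, and geometry class", {
  q <- mk_track("1", 1, 100, "q1")
  expect_equal(find_overlaps(q, mk_track("1", 1, 100, "t1"))$overlap_type,
               "identical")

  r <- find_overlaps(mk_track("1", 11, 20, "q1"), mk_track("1", 1, 100, "t1"))
  expect_equal(r$overlap_bp, 10L)
  expect_equal(r$query_fraction, 1.0)
  expect_equal(r$target_fraction, 0.1)
  expect_equal(r$overlap_type, "query_within_target")

  expect_equal(nrow(find_overlaps(q, mk_track("1", 201, 300))), 0L)
  expect_equal(nrow(find_overlaps(q, mk_track("2", 1, 100))), 0L)

  r2 <- find_overlaps(mk_track("1", 1, 100, "q1"), mk_track("1", 51, 80, "t1"))
  expect_equal(r2$overlap_type, "target_within_query")
  r3 <- find_overlaps(mk_track("1", 1, 100, "q1"), mk_track("1", 51, 150, "t1"))
  expect_equal(r3$overlap_type, "partial")
  expect_equal(r3$overlap_bp, 50L)
})

test_that("find_overlaps equals a brute-force all-pairs scan", {
  set.seed(5)
  gb <- genome_build(c("1", "2"), c(5e4, 5e4))
  rand_track <- function(n, label) {
    chrom <- sample(gb$chrom, n, replace = TRUE)
    start <- sample(4e4, n, replace = TRUE)
    mk_track(chrom, start, start + sample(5000, n, replace = TRUE),
             name = paste0(label, seq_len(n)), label = label)
  }
  q <- rand_track(120, "q")
  t <- rand_track(120, "t")
  got <- find_overlaps(q, t)
  got <- got[order(got$query_id, got$target_id), ]
  brute <- list()
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(t))) {
      if (q$chrom[i] == t$chrom[j]) {
        ov <- min(q$end[i], t$end[j]) - max(q$start[i], t$start[j]) + 1
        if (ov >= 1) {
          brute[[length(brute) + 1]] <- data.frame(
            query_id = q$name[i], target_id = t$name[j], overlap_bp = ov)
        }
      }
    }
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(brute$query_id, brute$target_id), ]
  expect_equal(got$query_id, brute$query_id)
  expect_equal(got$target_id, brute$target_id)
  expect_equal(got$overlap_bp, as.integer(brute$overlap_bp))
})

test_that("study matching requires mutual overlap above the threshold", {
  expect_equal(nrow(mutual_overlap_match(mk_track("1", 1, 100, "a"),
                                         mk_track("1", 1, 100, "b"))), 1L)
  # 50/100 on each side: below 0.7
  expect_equal(nrow(mutual_overlap_match(mk_track("1", 1, 100, "a"),
                                         mk_track("1", 51, 150, "b"))), 0L)
  # fully contained but only 10% of the larger: mutuality fails
  expect_equal(nrow(mutual_overlap_match(mk_track("1", 1, 100, "a"),
                                         mk_track("1", 1, 1000, "b"))), 0L)
  # 80/100 both sides passes
  expect_equal(nrow(mutual_overlap_match(mk_track("1", 1, 100, "a"),
                                         mk_track("1", 21, 120, "b"))), 1L)
})

test_that("randomization preserves size and chromosome and excludes outliers", {
  gb <- genome_build(c("1", "2"), c(1e6, 2e6))
  reg <- data.frame(chrom = c("1", "2", "1"), start = c(1, 100, 200),
                    end = c(10000, 50099, 1000200),
                    name = c("a", "b", "huge"))
  set.seed(1)
  r <- randomize_regions(reg, gb)
  expect_equal(nrow(r), 2L)  # 'huge' is 1,000,000+ bp and is dropped
  expect_equal(r$chrom, c("1", "2"))
  expect_equal(r$end - r$start, c(9999, 49999))
  expect_true(all(r$start >= 1 & r$end <= chrom_length(gb, r$chrom)))

  # a region exactly the chromosome length has one placement
  gb1 <- genome_build("1", 5000)
  fixed <- randomize_regions(data.frame(chrom = "1", start = 1, end = 5000),
                             gb1, max_len_bp = 1e6)
  expect_equal(c(fixed$start, fixed$end), c(1, 5000))
  expect_error(randomize_regions(data.frame(chrom = "1", start = 1, end = 6000),
                                 gb1, max_len_bp = 1e6), "does not fit")
})

test_that("random placement is uniform over valid starts", {
  gb <- genome_build("1", 1e6)
  reg <- data.frame(chrom = "1", start = 1, end = 1e4)
  set.seed(99)
  starts <- replicate(1000, randomize_regions(reg, gb)$start)
  room <- 1e6 - 1e4 + 1
  ks <- suppressWarnings(stats::ks.test(starts, "punif", 1, room + 1))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(starts >= 1 & starts <= room))
})

test_that("permutation p-values obey the add-one estimator and its bounds", {
  expect_equal(empirical_pvalue(0, 1000), 1 / 1001)
  expect_equal(empirical_pvalue(1000, 1000), 1)
  # a reported p of 0.057 corresponds to 56 of 1000 permutations as extreme
  expect_equal(sprintf("%.3f", empirical_pvalue(56, 1000)), "0.057")
  expect_error(empirical_pvalue(-1, 100))
  expect_error(empirical_pvalue(101, 100))
})

test_that("self-overlap is highly significant and results are seed-stable", {
  gb <- genome_build(c("1", "2"), c(1e6, 1e6))
  set.seed(3)
  q <- mk_track(rep(c("1", "2"), 5), seq(1e4, 1e5, length.out = 10),
                seq(1e4, 1e5, length.out = 10) + 5000)
  r1 <- permutation_overlap_test(q, q, gb, n_perm = 99, seed = 7,
                                 measure = "region_count",
                                 alternative = "greater")
  expect_equal(r1$observed, 10)
  expect_gte(r1$p_value, 1 / 100)
  expect_lte(r1$p_value, 0.05)
  r2 <- permutation_overlap_test(q, q, gb, n_perm = 99, seed = 7,
                                 measure = "region_count",
                                 alternative = "greater")
  expect_identical(r1, r2)

  # empty target: nothing can be less extreme than 0
  empty <- mk_track(character(), numeric(), numeric())
  rl <- permutation_overlap_test(q, empty, gb, n_perm = 19, seed = 1,
                                 alternative = "less")
  expect_equal(rl$observed, 0)
  expect_equal(rl$p_value, 1)
  expect_error(permutation_overlap_test(empty, q, gb, n_perm = 9, seed = 1),
               "empty query")
})

test_that("the total_bp measure is symmetric in query and target", {
  set.seed(13)
  gb <- genome_build("1", 1e5)
  a <- mk_track("1", c(1, 2001, 7001), c(1500, 4000, 9000))
  b <- mk_track("1", c(1000, 3500, 8500), c(2500, 5000, 12000))
  ab <- permutation_overlap_test(a, b, gb, n_perm = 1, seed = 1,
                                 measure = "total_bp")$observed
  ba <- permutation_overlap_test(b, a, gb, n_perm = 1, seed = 1,
                                 measure = "total_bp")$observed
  expect_equal(ab, ba)
  # hand arithmetic: [1000,1500] + [2001,2500] + [3500,4000] + [8500,9000]
  expect_equal(ab, 501 + 500 + 501 + 501)
})

test_that("batch mode produces one row per track with distinct seeds", {
  gb <- genome_build("1", 1e6)
  set.seed(2)
  q <- mk_track("1", seq(1e4, 9e5, length.out = 20),
                seq(1e4, 9e5, length.out = 20) + 2000)
  tracks <- list(genes = mk_track("1", c(5e5, 7e5), c(5.1e5, 7.1e5)),
                 qtls = mk_track("1", 1, 9e5))
  res <- permutation_overlap_batch(q, tracks, gb, seed = 5, n_perm = 49)
  expect_equal(res$track, c("genes", "qtls"))
  expect_equal(res$seed, c(5, 6))
  expect_true(all(res$p_value >= 1 / 50 & res$p_value <= 1))
})
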