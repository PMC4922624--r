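toy_probe_map <- function(n = 10, chrom = "1", spacing = 100) {
  data.frame(probe_id = sprintf("p%s_%02d", chrom, seq_len(n)),
             chrom = chrom, pos = spacing * seq_len(n),
             stringsAsFactors = FALSE)
}

test_that("probes take the copy number of the covering call, else 2", {
  pm <- toy_probe_map()
  calls <- cnv_calls("A1", "1", 100, 200, 1L)
  m <- assign_probe_cn(calls, pm, samples = c("A1", "A2"))
  expect_equal(m$cn["p1_01", "A1"], 1L)  # probe at 100 inside [100,200]
  expect_equal(m$cn["p1_02", "A1"], 1L)  # probe at 200: inclusive end
  expect_equal(m$cn["p1_03", "A1"], 2L)  # probe at 300: outside
  expect_true(all(m$cn[, "A2"] == 2L))
  expect_equal(m$deviation_fraction[["p1_01"]], 0.5)
})

test_that("deviation fraction counts samples away from 2n", {
  pm <- toy_probe_map(1)
  calls <- cnv_calls(paste0("s", 1:3), "1", 50, 150, 3L)
  m <- assign_probe_cn(calls, pm, samples = paste0("s", 1:10))
  expect_equal(unname(m$deviation_fraction), 0.3)
})

test_that("overlapping same-sample calls over a probe are rejected by name", {
  pm <- toy_probe_map()
  calls <- cnv_calls(c("A1", "A1"), "1", c(100, 150), c(300, 400),
                     c(1L, 1L))
  expect_error(assign_probe_cn(calls, pm), "sample A1.*probe p1_0")
})

test_that("variable-probe selection is inclusive at the threshold", {
  m <- list(cn = matrix(2L, 3, 1000, dimnames = list(c("a", "b", "c"), NULL)),
            deviation_fraction = c(a = 0.05, b = 0.049, c = 0))
  class(m) <- "probe_cn_matrix"
  expect_equal(select_variable_probes(m), "a")
  m$deviation_fraction[] <- 0
  expect_equal(select_variable_probes(m), character())
})

test_that("a noiseless dosage effect is recovered exactly", {
  cn <- c(rep(1L, 7), rep(2L, 8), rep(3L, 5))
  names(cn) <- paste0("s", seq_along(cn))
  ph <- data.frame(sample_id = names(cn), phenotype = 2 * cn)
  r <- probe_association(cn, ph)
  expect_equal(r$beta, 2, tolerance = 1e-12)
  expect_lt(r$p_value, 1e-12)
  expect_false(r$degenerate)
  expect_equal(r$n_used, 20L)
})

test_that("the closed-form regression agrees with lm", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    cn <- sample(0:4, n, replace = TRUE)
    while (var(cn) == 0) cn <- sample(0:4, n, replace = TRUE)
    names(cn) <- paste0("s", seq_len(n))
    ph <- data.frame(sample_id = names(cn),
                     phenotype = 0.3 * cn + rnorm(n))
    got <- probe_association(cn, ph)
    fit <- summary(lm(ph$phenotype ~ cn))$coefficients
    expect_equal(got$beta, fit["cn", "Estimate"], tolerance = 1e-10)
    expect_equal(got$se, fit["cn", "Std. Error"], tolerance = 1e-10)
    expect_equal(got$p_value, fit["cn", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("constant copy number yields a flagged degenerate result", {
  cn <- rep(3L, 10)
  names(cn) <- paste0("s", 1:10)
  ph <- data.frame(sample_id = names(cn), phenotype = rnorm(10))
  r <- probe_association(cn, ph)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_equal(r$beta, 0)
})

test_that("samples without phenotype are dropped pairwise", {
  cn <- c(s1 = 1L, s2 = 2L, s3 = 3L, s4 = 2L, s5 = 1L, s9 = 3L)
  ph <- data.frame(sample_id = paste0("s", 1:5), phenotype = c(1, 2, 3, 2, 1))
  r <- probe_association(cn, ph)
  expect_equal(r$n_used, 5L)
})

test_that("segment chaining follows the state-identity threshold", {
  pm <- toy_probe_map(3)
  mk_matrix <- function(ident) {
    cn <- matrix(2L, nrow = 3, ncol = 100,
                 dimnames = list(pm$probe_id, paste0("s", 1:100)))
    cn[1, 1:10] <- 1L
    cn[2, 1:10] <- 1L
    # probe 2 disagrees with probe 1 in (100 - ident) samples
    if (ident < 100) cn[2, (ident + 1):100] <- 1L
    cn[3, 1:10] <- 1L
    structure(list(cn = cn, probe_map = pm,
                   deviation_fraction = rowMeans(cn != 2L)),
              class = "probe_cn_matrix")
  }
  m96 <- mk_matrix(96)
  seg <- build_segments(pm$probe_id[1:2], m96)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_probes, 2L)
  expect_equal(c(seg$start, seg$end), c(100, 200))

  m94 <- mk_matrix(94)
  seg <- build_segments(pm$probe_id[1:2], m94)
  expect_equal(nrow(seg), 2L)

  # a single selected probe is a singleton segment
  seg1 <- build_segments(pm$probe_id[1], m96)
  expect_equal(nrow(seg1), 1L)
  expect_equal(seg1$n_probes, 1L)
})

test_that("segments break at chromosome boundaries and partition the probes", {
  pm <- rbind(toy_probe_map(3, "1"), toy_probe_map(3, "2"))
  cn <- matrix(1L, nrow = 6, ncol = 20,
               dimnames = list(pm$probe_id, paste0("s", 1:20)))
  m <- structure(list(cn = cn, probe_map = pm,
                      deviation_fraction = rowMeans(cn != 2L)),
                 class = "probe_cn_matrix")
  seg <- build_segments(pm$probe_id, m)
  expect_equal(nrow(seg), 2L)  # identical states, but two chromosomes
  expect_equal(sum(seg$n_probes), 6L)
  expect_setequal(unlist(seg$probe_ids), pm$probe_id)
})

test_that("lowering the identity threshold never increases segment count", {
  set.seed(29)
  pm <- toy_probe_map(30)
  cn <- matrix(sample(c(1L, 2L, 3L), 30 * 50, replace = TRUE,
                      prob = c(0.2, 0.6, 0.2)), nrow = 30,
               dimnames = list(pm$probe_id, paste0("s", 1:50)))
  m <- structure(list(cn = cn, probe_map = pm,
                      deviation_fraction = rowMeans(cn != 2L)),
                 class = "probe_cn_matrix")
  counts <- vapply(c(0.99, 0.8, 0.5, 0.2, 0), function(f) {
    nrow(build_segments(pm$probe_id, m, identity_frac = f))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the representative probe has the minimum p, leftmost on ties", {
  pm <- toy_probe_map(3)
  cn <- matrix(1L, 3, 10, dimnames = list(pm$probe_id, paste0("s", 1:10)))
  m <- structure(list(cn = cn, probe_map = pm,
                      deviation_fraction = rowMeans(cn != 2L)),
                 class = "probe_cn_matrix")
  seg <- build_segments(pm$probe_id, m)
  pa <- data.frame(probe_id = pm$probe_id, beta = 1:3,
                   p_value = c(0.2, 0.01, 0.05))
  scored <- score_segments(seg, pa, m)
  expect_equal(scored$representative_probe, "p1_02")
  expect_equal(scored$p_value, 0.01)
  expect_equal(scored$n_cn1, 10L)
  expect_equal(scored$n_cn2, 0L)

  pa$p_value <- c(0.01, 0.01, 0.05)
  expect_equal(score_segments(seg, pa, m)$representative_probe, "p1_01")
})

test_that("BH adjustment matches the textbook step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.1, 0)), "0, 1")
  expect_error(fdr_adjust(c(0.1, NA)))
  set.seed(37)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(fdr_adjust(p), bh_stepup(p))
  }
})

test_that("neighbor genes respect the window boundary exactly", {
  seg <- data.frame(segment_id = "s1", chrom = "1", start = 1e6, end = 1.1e6)
  genes <- annotation_track(
    "1", c(1e6 - 450000 - 1000, 1e6 - 450000, 1e6 - 100000, 1.05e6),
    c(1e6 - 450001, 1e6 - 449000, 1e6 - 99000, 1.06e6),
    name = c("too_far", "edge", "upstream", "inside"), label = "genes")
  out <- annotate_neighbors(seg, genes)
  nb <- out$neighbor_genes[[1]]
  expect_setequal(nb$name, c("edge", "upstream", "inside"))
  expect_equal(nb$name[1], "inside")
  expect_equal(nb$distance[nb$name == "inside"], 0)
  expect_equal(nb$distance[nb$name == "upstream"], 1e6 - (1e6 - 99000))
  # the gene ending 450,001 bp upstream is outside the 450 kb window
  expect_false("too_far" %in% nb$name)
})

test_that("the full scan finds a planted causal locus first", {
  cfg <- sim_config(seed = 101, n_animals = 120, n_chromosomes = 2,
                    chrom_length_bp = 5e6, n_cnv_loci = 21,
                    causal_loci = 1L, causal_beta = 1.2,
                    locus_frequency_range = c(0.15, 0.4),
                    boundary_jitter_sd_bp = 0, false_positive_rate = 0)
  sim <- simulate_population(cfg)
  ph <- simulate_phenotype(sim$truth, cfg)
  seg <- run_cnv_gwas(sim$calls, sim$probe_map, ph, genome = sim$genome)
  best <- seg[which.min(seg$fdr_q), ]
  causal <- sim$truth$loci[1, ]
  expect_equal(best$chrom, causal$chrom)
  expect_lte(best$start, causal$end)
  expect_gte(best$end, causal$start)
  expect_lt(best$fdr_q, 0.05)
})

test_that("a permuted phenotype yields no confident segment", {
  cfg <- sim_config(seed = 202, n_animals = 120, n_chromosomes = 2,
                    chrom_length_bp = 5e6, n_cnv_loci = 21,
                    causal_loci = integer(), causal_beta = numeric(),
                    locus_frequency_range = c(0.15, 0.4),
                    boundary_jitter_sd_bp = 0, false_positive_rate = 0)
  sim <- simulate_population(cfg)
  ph <- simulate_phenotype(sim$truth, cfg)
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    ph$phenotype <- sample(ph$phenotype)
    seg <- run_cnv_gwas(sim$calls, sim$probe_map, ph, genome = sim$genome)
    sum(seg$fdr_q < 0.05)
  }, numeric(1))
  expect_true(mean(hits == 0) >= 0.8)
})

test_that("an all-diploid matrix yields an empty table with a warning", {
  pm <- toy_probe_map(5)
  calls <- cnv_calls("only", "1", 5000, 6000, 1L)  # covers no probe
  ph <- data.frame(sample_id = "only", phenotype = 1)
  expect_warning(seg <- run_cnv_gwas(calls, pm, ph), "no probe")
  expect_equal(nrow(seg), 0L)
})
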