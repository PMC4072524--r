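test_that("D statistic closed forms and symmetries", {
  # y = z everywhere: numerator vanishes
  y <- c(0.5, 0.2, 0.8); w <- c(1, 0, 0.5); x <- c(0, 0.5, 0.5)
  expect_equal(d_statistic(y, y, w, x)$D, 0)
  # single site (1, 0, 1, 0) -> D = 1
  expect_equal(d_statistic(1, 0, 1, 0)$D, 1)
  # antisymmetry under Y<->Z and under W<->X
  z <- c(0.1, 0.6, 0.3)
  d0 <- d_statistic(y, z, w, x)$D
  expect_equal(d_statistic(z, y, w, x)$D, -d0)
  expect_equal(d_statistic(y, z, x, w)$D, -d0)
  # allele relabelling at every site leaves D unchanged
  expect_equal(d_statistic(1 - y, 1 - z, 1 - w, 1 - x)$D, d0)
  # undefined denominator flagged
  und <- d_statistic(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  expect_true(und$undefined)
})

test_that("block jackknife matches the classical delete-one formula", {
  # equal-sized blocks: the weighted form reduces to the classical one
  set.seed(3)
  num <- rnorm(30, 0.1); den <- runif(30, 0.5, 1)
  chrom <- rep(c("c1", "c2", "c3"), each = 10)
  bj <- block_jackknife(num, den, chrom)
  theta <- sum(num) / sum(den)
  loo <- vapply(c("c1", "c2", "c3"), function(b)
    sum(num[chrom != b]) / sum(den[chrom != b]), numeric(1))
  g <- 3
  se_classic <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  expect_equal(bj$D, theta)
  expect_equal(unname(bj$leave_one_out), unname(loo))
  expect_equal(bj$se, se_classic, tolerance = 1e-10)
  # identical per-chromosome contributions: zero SE
  same <- block_jackknife(rep(1, 30), rep(2, 30), chrom)
  expect_equal(same$se, 0)
  expect_error(block_jackknife(num, den, rep("c1", 30)), "3 chromosomes")
})

test_that("outlier regions find a planted divergent haplotype", {
  # 4 donor-taxon samples on one 200 kb chromosome; DON1 carries a
  # divergent tract from 60-100 kb
  L <- 2e5
  set.seed(6)
  pos <- sort(sample.int(L, 8000)) - 1L
  g <- matrix(0L, length(pos), 4)
  tract <- pos >= 6e4 & pos < 1e5
  g[tract & runif(length(pos)) < 0.5, 1] <- 1L  # ~2% divergence inside
  panel <- genotype_panel(
    data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T"),
    g, paste0("DON", 1:4), callable = "genome",
    chrom_lengths = c(chr1 = L))
  reg <- find_outlier_regions(panel, paste0("DON", 1:4), window_bp = 5000,
                              pi_threshold = 0.01, region_bp = 2e4,
                              min_sites = 100)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$outlier, "DON1")
  expect_lte(abs(reg$start - 6e4), 5000)
  expect_lte(abs(reg$end - 1e5), 5000)
  # identical panel: nothing to report
  none <- find_outlier_regions(
    genotype_panel(data.frame(chrom = "chr1", pos = pos, ref = "A",
                              alt = "T"),
                   matrix(0L, length(pos), 4), paste0("DON", 1:4),
                   callable = "genome", chrom_lengths = c(chr1 = L)),
    paste0("DON", 1:4))
  expect_equal(nrow(none), 0)
  # two samples divergent in the same windows: not a single outlier
  g2 <- g
  g2[tract & runif(length(pos)) < 0.5, 2] <- 1L
  panel2 <- genotype_panel(
    data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T"),
    matrix(as.integer(g2), length(pos)), paste0("DON", 1:4),
    callable = "genome", chrom_lengths = c(chr1 = L))
  reg2 <- find_outlier_regions(panel2, paste0("DON", 1:4), window_bp = 5000,
                               pi_threshold = 0.01, region_bp = 2e4,
                               min_sites = 100)
  expect_false(any(reg2$start < 1e5 & reg2$end > 6e4))
})

test_that("outlier source test uses the exact binomial tail", {
  # the worked 272-of-490 example against stats::binom.test as oracle
  p <- selfmix:::binom_tail_geq(272, 490, 0.5)
  expect_equal(p, binom.test(272, 490, 0.5,
                             alternative = "greater")$p.value)
  expect_equal(round(p, 3), 0.008)
  expect_gt(selfmix:::binom_tail_geq(245, 490, 0.5), 0.45)
})

test_that("outlier source attribution works on planted data", {
  # four tracts copied from the candidate source -> outlier closer in all
  L <- 6e5
  set.seed(9)
  pos <- sort(sample.int(L, 24000)) - 1L
  n <- length(pos)
  src <- as.integer(runif(n) < 0.5)  # ~2% per-bp divergence from the donors
  g <- cbind(DON1 = 0L, DON2 = 0L, DON3 = 0L, DON4 = 0L, SRC = src)
  tract <- (pos >= 5e4 & pos < 9e4) | (pos >= 2e5 & pos < 2.4e5) |
    (pos >= 3.5e5 & pos < 3.9e5) | (pos >= 5e5 & pos < 5.4e5)
  g[tract, "DON1"] <- src[tract]  # introgressed from SRC
  panel <- genotype_panel(
    data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T"),
    g, colnames(g), callable = "genome", chrom_lengths = c(chr1 = L))
  reg <- find_outlier_regions(panel, paste0("DON", 1:4), window_bp = 5000,
                              pi_threshold = 0.01, region_bp = 2e4,
                              min_sites = 100)
  expect_gte(nrow(reg), 4)
  ot <- outlier_source_test(reg, "SRC", panel, paste0("DON", 1:4))
  expect_equal(ot$k, ot$n)     # every region traces to the source
  expect_lt(ot$p_value, 0.07)  # 4+ successes out of as many regions
})

test_that("null D simulations are centred and calibrated", {
  # smoke-scale version of the calibration (the full 200-replicate run
  # lives in the acceptance suite)
  zs <- numeric(12); dsv <- numeric(12)
  for (r in 1:12) {
    cfg <- sim_config(seed = 900 + r, pi_within = 0.0445,
                      pi_between = 0.0494)
    pan <- simulate_unlinked_loci(cfg, n_loci = 140,
                                  samples_per_pop = c(6, 2), locus_bp = 1e4)
    d <- d_test(pan, Y = c("P1_1", "P1_2"), Z = c("P1_3", "P1_4"),
                W = c("P2_1", "P2_2"), X = c("P1_5", "P1_6"))
    zs[r] <- d$Z; dsv[r] <- d$D
  }
  expect_lt(abs(mean(dsv)), 3 * sd(dsv) / sqrt(length(dsv)))
  expect_gte(mean(abs(zs) < 3), 0.9)
})
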