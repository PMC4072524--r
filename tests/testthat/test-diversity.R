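test_that("pairwise pi counts only co-called sites and is symmetric", {
  panel <- toy_missing_panel()
  # hand count a vs b: co-called sites at pos 0,10,15,25; diffs at 0,15
  r <- pairwise_pi(panel, "a", "b")
  expect_equal(r$n_sites, 4)
  expect_equal(r$n_diff, 2)
  expect_equal(r$pi, 0.5)
  expect_equal(pairwise_pi(panel, "b", "a")[c("n_sites", "n_diff", "pi")],
               r[c("n_sites", "n_diff", "pi")])
  # a vs c: co-called 0,5,15,25; diffs none -> pi 0
  expect_equal(pairwise_pi(panel, "a", "c")$pi, 0)
  # undefined, not zero, when nothing is co-called
  empty <- panel
  empty$geno[, "b"] <- NA_integer_
  u <- pairwise_pi(empty, "a", "b")
  expect_true(u$undefined)
  expect_true(is.na(u$pi))
})

test_that("two differences over 100 co-called sites give pi = 0.02", {
  sites <- data.frame(chrom = "chr1", pos = 0:99, ref = "A", alt = "T")
  g <- cbind(rep(0L, 100), rep(0L, 100))
  g[c(10, 70), 2] <- 1L
  panel <- genotype_panel(sites, g, c("x", "y"))
  expect_equal(pairwise_pi(panel, "x", "y")$pi, 0.02)
})

test_that("windowed pi reduces to pairwise pi and conserves counts", {
  cfg <- sim_config(genome_bp = 4e5, n_chromosomes = 1, seed = 6)
  ds <- simulate_dataset(cfg)
  pan <- ds$panel
  whole <- windowed_pi(pan, "ADM1", "DON1", window_bp = 4e5, slide_bp = 4e5,
                       min_sites = 1)
  gw <- pairwise_pi(pan, "ADM1", "DON1")
  expect_equal(nrow(whole), 1)
  expect_equal(whole$pi, gw$pi)
  # disjoint windows partition the mismatches
  wp <- windowed_pi(pan, "ADM1", "DON1", window_bp = 1e4, slide_bp = 1e4,
                    min_sites = 1)
  expect_equal(sum(wp$n_diff), gw$n_diff)
  expect_equal(sum(wp$n_sites), gw$n_sites)
})

test_that("window-pi histogram modes at the configured divergence", {
  cfg <- sim_config(genome_bp = 2e6, n_chromosomes = 2, seed = 7)
  ds <- simulate_dataset(cfg)
  wp <- windowed_pi(ds$panel, "REC1", "DON1", window_bp = 5000,
                    slide_bp = 1000, min_sites = 100)
  ok <- wp[!wp$insufficient, ]
  # recipient vs donor: pi_between plus two layers of private variation
  expected <- cfg$pi_between + 2 * cfg$pi_within
  expect_lt(abs(median(ok$pi) - expected), 0.005)
})

test_that("insufficient windows are flagged, not zero", {
  sites <- data.frame(chrom = "chr1", pos = c(2L, 9990L), ref = "A", alt = "T")
  panel <- genotype_panel(sites, cbind(c(0L, 1L), c(1L, 1L)), c("x", "y"))
  wp <- windowed_pi(panel, "x", "y", window_bp = 5000, slide_bp = 5000,
                    min_sites = 100)
  expect_true(all(wp$insufficient))
})

test_that("block bootstrap: constant statistic, reproducibility, undefined resamples", {
  cfg <- sim_config(genome_bp = 1e6, n_chromosomes = 2, seed = 8)
  panel <- simulate_dataset(cfg)$panel
  const <- block_bootstrap(function(p) 7, panel, block_bp = 1e5,
                           n_boot = 20, seed = 1)
  expect_equal(const$lo, 7)
  expect_equal(const$hi, 7)
  b1 <- block_bootstrap(function(p) pairwise_pi(p, "REC1", "DON1")$pi,
                        panel, block_bp = 1e5, n_boot = 30, seed = 5)
  b2 <- block_bootstrap(function(p) pairwise_pi(p, "REC1", "DON1")$pi,
                        panel, block_bp = 1e5, n_boot = 30, seed = 5)
  expect_identical(b1$boot, b2$boot)
  expect_lt(b1$lo, b1$point)
  expect_gt(b1$hi, b1$point)
})

test_that("bootstrap intervals cover the truth at close to nominal rate", {
  # 200 light panels; 95% interval for pairwise pi should cover the
  # configured value in roughly 95% of them
  covered <- vapply(1:200, function(r) {
    cfg <- sim_config(seed = 7000 + r)
    pan <- simulate_unlinked_loci(cfg, n_loci = 60, samples_per_pop = 1,
                                  locus_bp = 2e3)
    bb <- block_bootstrap(function(p) pairwise_pi(p, "P1_1", "P2_1")$pi,
                          pan, block_bp = 2e3, n_boot = 100, seed = r)
    bb$lo <= cfg$pi_between && cfg$pi_between <= bb$hi
  }, logical(1))
  expect_gte(mean(covered), 0.88)
})

test_that("polarized AFS matches hand tallies and excludes unusable sites", {
  sites <- data.frame(chrom = "chr1", pos = 0:5, ref = "A", alt = "T,G")
  #            in1 in2 in3 out
  g <- rbind(c(1L, 1L, 0L, 0L),   # derived count 2
             c(0L, 0L, 0L, 1L),   # ancestral T: all three ingroup derived
             c(1L, NA, 0L, 0L),   # incomplete ingroup -> excluded
             c(0L, 0L, 0L, NA),   # missing outgroup -> excluded
             c(2L, 1L, 0L, 0L),   # three alleles -> excluded
             c(0L, 0L, 0L, 0L))   # monomorphic: derived count 0
  panel <- genotype_panel(sites, g, c("i1", "i2", "i3", "o"))
  afs <- polarized_afs(panel, c("i1", "i2", "i3"), "o")
  expect_equal(unname(afs$counts), c(0L, 1L, 1L))
  expect_equal(afs$n_sites_used, 3)

  mono <- genotype_panel(sites[1:2, ], matrix(0L, 2, 4),
                         c("i1", "i2", "i3", "o"))
  expect_equal(sum(polarized_afs(mono, c("i1", "i2", "i3"), "o")$counts), 0)
  empty <- genotype_panel(sites[1, ], matrix(NA_integer_, 1, 4),
                          c("i1", "i2", "i3", "o"))
  expect_error(polarized_afs(empty, c("i1", "i2", "i3"), "o"), "no usable")
})

test_that("neutral-equilibrium AFS follows the 1/i expectation", {
  cfg <- sim_config(seed = 31, pi_within = 0.004, pi_between = 0.04)
  pan <- simulate_unlinked_loci(cfg, n_loci = 400, samples_per_pop = c(4, 1),
                                locus_bp = 5e3)
  afs <- polarized_afs(pan, paste0("P1_", 1:4), "P2_1")
  seg <- afs$counts[1:3]  # polymorphic classes for n = 4
  props <- seg / sum(seg)
  expected <- (1 / 1:3) / sum(1 / 1:3)
  # sites within a locus share one genealogy, so the sampling unit is the
  # locus: cluster-robust SE, not per-site binomial SE
  g <- pan$geno[, paste0("P1_", 1:4)]
  dc <- rowSums(g == 1L)
  sel <- dc >= 1 & dc <= 3
  locus <- paste(pan$sites$chrom, pan$sites$pos %/% 5000)[sel]
  for (i in 1:3) {
    k_l <- tapply(dc[sel] == i, locus, sum)
    n_l <- tapply(sel[sel], locus, length)
    se_i <- sqrt(sum((k_l - expected[i] * n_l)^2)) / sum(n_l)
    expect_lt(abs(props[[i]] - expected[i]), 4 * se_i)
  }
})

test_that("variant partitioning assigns each site to one category", {
  sites <- data.frame(chrom = "chr1", pos = 0:4, ref = "A", alt = "T")
  #           a1  a2  b1  b2  out
  g <- rbind(c(0L, 1L, 0L, 1L, 0L),  # shared polymorphism
             c(0L, 1L, 1L, 1L, 1L),  # private to A
             c(0L, 0L, 0L, 1L, 0L),  # private to B
             c(1L, 1L, 0L, 0L, 0L),  # fixed diff, derived in A
             c(0L, 0L, 1L, 1L, 0L))  # fixed diff, derived in B
  panel <- genotype_panel(sites, g, c("a1", "a2", "b1", "b2", "o"))
  pv <- partition_variants(panel, c("a1", "a2"), c("b1", "b2"), "o")
  expect_equal(pv$shared, 1L)
  expect_equal(pv$private_a, 1L)
  expect_equal(pv$private_b, 1L)
  expect_equal(pv$fixed_diff, 2L)
  expect_equal(pv$fixed_derived_in_a, 1L)
  expect_equal(pv$fixed_derived_in_b, 1L)
  # groups with identical content: no fixed differences
  g2 <- g
  g2[, 3:4] <- g[, 1:2]
  dup <- genotype_panel(sites, g2, c("a1", "a2", "b1", "b2", "o"))
  expect_equal(partition_variants(dup, c("a1", "a2"), c("b1", "b2"))$fixed_diff, 0L)
  expect_error(partition_variants(panel, c("a1"), c("a1")), "disjoint")
})
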