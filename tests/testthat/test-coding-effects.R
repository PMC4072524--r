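# Fixture: simulated dataset with planted gene models and stop codons.
stop_dataset <- function(stops = NULL, seed = 2) {
  cfg <- sim_config(n_recipient = 1, n_donor = 1, genome_bp = 2e4,
                    n_chromosomes = 1, map_length_morgans = 0.01,
                    pi_within = 0, pi_between = 0, alpha = 0, v = 1,
                    seed = seed)
  ds <- simulate_dataset(cfg)
  plant_gene_models_and_stops(ds, stops = stops)
}

test_that("no planted stops means no called stops", {
  ds <- stop_dataset()
  ev <- find_premature_stops(ds$panel, "REC1", ds$genes, ds$reference)
  expect_equal(nrow(ev), 0)
})

test_that("planted mid-gene stops are found; rule-violating plants are not", {
  # genes have 100 codons: codon 50 is mid-gene, codon 96 is in the last
  # 5% (96/100 > 0.95), codon 95 is exactly at the boundary and admissible
  stops <- data.frame(gene_id = c("g1", "g2", "g3"),
                      codon_index = c(50L, 96L, 95L),
                      sample = "ADM1")
  ds <- stop_dataset(stops)
  ev <- find_premature_stops(ds$panel, "ADM1", ds$genes, ds$reference)
  expect_setequal(paste(ev$gene_id, ev$codon_index),
                  c("g1 50", "g3 95"))
  expect_true(all(ev$codon == "TAA"))
  # the planted record agrees
  expect_equal(ds$planted$codon_fraction[1], 0.5)
  # a different sample carries none of them
  expect_equal(nrow(find_premature_stops(ds$panel, "DON1", ds$genes,
                                         ds$reference)), 0)
})

test_that("codons with incomplete data are excluded", {
  stops <- data.frame(gene_id = "g1", codon_index = 50L, sample = "ADM1")
  ds <- stop_dataset(stops)
  # knock out one base of the planted codon for ADM1
  gi <- ds$genes[ds$genes$gene_id == "g1", ]
  sp <- selfmix:::spliced_coding(gi, ds$reference[[gi$chrom[1]]])
  gpos <- sp$pos[(50 - 1) * 3 + 1]
  ds$panel <- selfmix:::add_site_allele(ds$panel, gi$chrom[1], gpos,
                                        "A", "T", "ADM1")
  hit <- which(ds$panel$sites$chrom == gi$chrom[1] &
                 ds$panel$sites$pos == gpos)
  ds$panel$geno[hit, "ADM1"] <- NA_integer_
  ev <- find_premature_stops(ds$panel, "ADM1", ds$genes, ds$reference)
  expect_false(any(ev$gene_id == "g1" & ev$codon_index == 50))
})

test_that("genes with under 25% available codons contribute nothing", {
  stops <- data.frame(gene_id = "g1", codon_index = 50L, sample = "ADM1")
  ds <- stop_dataset(stops)
  gi <- ds$genes[ds$genes$gene_id == "g1", ]
  sp <- selfmix:::spliced_coding(gi, ds$reference[[gi$chrom[1]]])
  # mask 90% of the gene's codons for ADM1, keeping codons 46..55 (and
  # the planted stop at 50) fully available
  for (gpos in sp$pos[c(1:135, 166:300)]) {
    ds$panel <- selfmix:::add_site_allele(ds$panel, gi$chrom[1], gpos,
                                          "A", "A", "ADM1")
    hit <- which(ds$panel$sites$chrom == gi$chrom[1] &
                   ds$panel$sites$pos == gpos)
    ds$panel$geno[hit, "ADM1"] <- NA_integer_
  }
  ev <- find_premature_stops(ds$panel, "ADM1", ds$genes, ds$reference)
  expect_false(any(ev$gene_id == "g1"))
  # relaxing the availability rule can only add events (monotonicity)
  ev_relaxed <- find_premature_stops(ds$panel, "ADM1", ds$genes,
                                     ds$reference, min_gene_fraction = 0)
  expect_true(all(paste(ev$gene_id, ev$codon_index) %in%
                    paste(ev_relaxed$gene_id, ev_relaxed$codon_index)))
  expect_true(any(ev_relaxed$gene_id == "g1" & ev_relaxed$codon_index == 50))
})

test_that("relaxing the 3'-end rule only adds events", {
  stops <- data.frame(gene_id = c("g1", "g2"), codon_index = c(50L, 96L),
                      sample = "ADM1")
  ds <- stop_dataset(stops)
  strict <- find_premature_stops(ds$panel, "ADM1", ds$genes, ds$reference)
  relaxed <- find_premature_stops(ds$panel, "ADM1", ds$genes, ds$reference,
                                  last_fraction = 0)
  expect_true(all(paste(strict$gene_id, strict$codon_index) %in%
                    paste(relaxed$gene_id, relaxed$codon_index)))
  expect_gt(nrow(relaxed), nrow(strict))
})

test_that("stop planting validates its inputs", {
  expect_error(stop_dataset(data.frame(gene_id = "g1", codon_index = 200L,
                                       sample = "ADM1")),
               "outside")
  expect_error(stop_dataset(data.frame(gene_id = "nope", codon_index = 5L,
                                       sample = "ADM1")),
               "unknown gene")
})

test_that("stop sharing summary counts carriers per codon", {
  ev <- data.frame(gene_id = c("g1", "g1", "g2", "g1"),
                   codon_index = c(5L, 5L, 9L, 7L),
                   sample = c("s1", "s2", "s1", "s2"))
  ss <- stop_sharing_summary(ev)
  expect_equal(ss$per_sample[["s1"]], 2L)
  expect_equal(ss$per_sample[["s2"]], 2L)
  # g1:5 carried by both samples; g2:9 and g1:7 by one each
  expect_equal(unname(ss$sharing), c(2L, 1L))
  empty <- stop_sharing_summary(list(
    find_premature_stops(stop_dataset()$panel, "REC1",
                         stop_dataset()$genes, stop_dataset()$reference)))
  expect_equal(length(empty$per_sample), 0)
})

test_that("pn_ps pools pairwise diversity by degeneracy class", {
  # toy: 2 samples, 12 coding sites of alternating class, hand-computed
  sites <- data.frame(chrom = "chrT", pos = 0:11, ref = "A", alt = "T")
  g <- matrix(0L, 12, 2)
  deg <- rep(c("0", "4"), 6)
  g[c(1, 3), 2] <- 1L   # two 0-fold differences (positions 0 and 2)
  g[c(2, 4, 6), 2] <- 1L  # three 4-fold differences
  panel <- genotype_panel(sites, g, c("a", "b"), degeneracy = deg)
  est <- pn_ps(panel, c("a", "b"), block_bp = 4, n_boot = 20, seed = 1)
  expect_equal(est$pi_N, 2 / 6)
  expect_equal(est$pi_S, 3 / 6)
  expect_equal(est$ratio, (2 / 6) / (3 / 6))
  expect_false(est$undefined)
  # no 4-fold variation: flagged undefined, not zero
  g0 <- g; g0[c(2, 4, 6), 2] <- 0L
  p0 <- genotype_panel(sites, g0, c("a", "b"), degeneracy = deg)
  expect_true(pn_ps(p0, c("a", "b"), n_boot = 5)$undefined)
  # no 0-fold variation: ratio 0
  gN <- g; gN[c(1, 3), 2] <- 0L
  pN <- genotype_panel(sites, gN, c("a", "b"), degeneracy = deg)
  expect_equal(pn_ps(pN, c("a", "b"), block_bp = 4, n_boot = 20,
                     seed = 1)$ratio, 0)
})

test_that("equal per-class rates give a ratio near one", {
  # simulated panel, classes assigned alternately so both classes see the
  # same mutational process
  cfg <- sim_config(genome_bp = 4e5, n_chromosomes = 2, seed = 14)
  ds <- simulate_dataset(cfg)
  panel <- ds$panel
  panel$degeneracy <- rep(c("0", "4"), length.out = nrow(panel$sites))
  panel$callable <- "panel"   # class masks need per-site denominators
  panel$chrom_lengths <- NULL
  est <- pn_ps(panel, c("REC1", "DON1", "DON2"), block_bp = 5e4,
               n_boot = 60, seed = 2)
  expect_gt(est$ratio, 0.9)
  expect_lt(est$ratio, 1.1)
  expect_true(est$ci[1] <= 1 && 1 <= est$ci[2])
})
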