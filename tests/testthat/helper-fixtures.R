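# In-code fixtures shared across test files.

# A small hand-designed panel with depths, a heterozygote, and a
# triallelic site, used for the filter-cascade and hand-count checks.
# Expected outcome (worked by hand from the depth arithmetic):
#   - s1 at site 1 (depth 9) fails the min-depth cutoff;
#   - s2 depths are (15,15,16,15,14,60): mean 22.5, sd 18.38, so only
#     |60 - 22.5| = 37.5 exceeds 2 sd = 36.76 -> s2 censored at site 6;
#   - site 3 carries alleles {0,1,2} -> dropped as multiallelic.
toy_filter_panel <- function() {
  sites <- data.frame(
    chrom = "chr1",
    pos = c(10L, 20L, 30L, 40L, 50L, 60L),
    ref = c("A", "C", "G", "T", "A", "C"),
    alt = c("T", "G", "A,C", "", "G", "T"))
  geno <- rbind(
    c(0L, 1L, 0L),
    c(1L, 1L, 1L),
    c(0L, 1L, 2L),
    c(0L, 0L, 0L),
    c(selfmix:::encode_het(0L, 1L), 0L, 1L),
    c(1L, 0L, 0L))
  depth <- cbind(c(9L, 15L, 14L, 15L, 16L, 15L),
                 c(15L, 15L, 16L, 15L, 14L, 60L),
                 c(15L, 15L, 15L, 15L, 15L, 15L))
  genotype_panel(sites, geno, c("s1", "s2", "s3"), depth = depth)
}

# Three-sample toy panel with staggered missingness for hand-counted
# diversity checks (callable = panel).
toy_missing_panel <- function() {
  sites <- data.frame(chrom = "chr1", pos = c(0L, 5L, 10L, 15L, 20L, 25L),
                      ref = "A", alt = "T")
  geno <- rbind(
    c(0L, 1L, 0L),
    c(1L, NA, 1L),
    c(0L, 0L, NA),
    c(1L, 0L, 1L),
    c(NA, 1L, 1L),
    c(0L, 0L, 0L))
  genotype_panel(sites, geno, c("a", "b", "c"))
}

# One-gene reference fixture: a plus-strand gene of n_codons on a random
# stop-free background, returning list(genes, reference).
toy_gene <- function(n_codons = 20, strand = "+", seed = 3) {
  nts <- c("A", "C", "G", "T")
  all_cod <- apply(expand.grid(nts, nts, nts), 1, paste, collapse = "")
  ok_cod <- setdiff(all_cod, c("TAA", "TAG", "TGA"))
  set.seed(seed)
  cds <- c("ATG", sample(ok_cod, n_codons - 2, replace = TRUE), "TGA")
  cds_b <- strsplit(paste(cds, collapse = ""), "")[[1]]
  flank <- 30L
  L <- flank * 2L + length(cds_b)
  s <- sample(nts, L, replace = TRUE)
  if (strand == "-") {
    s[(flank + 1):(flank + length(cds_b))] <- rev(chartr("ACGT", "TGCA", cds_b))
  } else {
    s[(flank + 1):(flank + length(cds_b))] <- cds_b
  }
  genes <- gene_models(data.frame(gene_id = "g1", chrom = "chrT",
                                  strand = strand, start = flank,
                                  end = flank + length(cds_b), frame = 0L))
  list(genes = genes, reference = c(chrT = paste(s, collapse = "")),
       cds = cds)
}

# Independent degeneracy oracle built on Biostrings' genetic code,
# enumerating the three substitutions directly.
oracle_degeneracy <- function(codon, pos) {
  code <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  aa <- code[[codon]]
  alts <- setdiff(nts, substr(codon, pos, pos))
  nsyn <- sum(vapply(alts, function(a) {
    m <- codon
    substr(m, pos, pos) <- a
    code[[m]] == aa
  }, logical(1)))
  c("0", "2", "3", "4")[nsyn + 1]
}

# Brute-force two-state HMM posterior by explicit enumeration of all
# state paths (oracle for forward_backward on short chains).
enumerate_posteriors <- function(emis, trans, init) {
  T_ <- nrow(emis)
  paths <- as.matrix(expand.grid(rep(list(1:2), T_)))
  pr <- apply(paths, 1, function(st) {
    p <- init[st[1]] * emis[1, st[1]]
    if (T_ > 1) for (t in 2:T_) p <- p * trans[st[t - 1], st[t]] * emis[t, st[t]]
    p
  })
  post <- sapply(seq_len(T_), function(t)
    sum(pr[paths[, t] == 2]) / sum(pr))
  list(post_donor = post, loglik = log(sum(pr)))
}
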