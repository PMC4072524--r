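#' Site and genotype filters
#'
#' Applies the paranoid-alignment filter cascade used for inbred-line
#' resequencing panels, in this order:
#'
#' 1. calls with depth below `min_depth` reads are set missing;
#' 2. calls whose depth is more than `depth_sd` standard deviations from
#'    that sample's mean depth are set missing (a guard against collapsed
#'    paralogs); the mean and SD are computed per sample over calls that
#'    survive the minimum-depth cutoff, so the cascade is idempotent;
#' 3. sites with more than two distinct alleles among the retained calls
#'    are dropped entirely.
#'
#' Sites left without any alternate-bearing call are retained (they are
#' legitimate invariant callable sites and enter diversity denominators).
#'
#' @param panel a [genotype_panel()] with depths.
#' @param min_depth minimum reads per call (default 10).
#' @param depth_sd two-sided depth censoring threshold in per-sample
#'   standard deviations (default 2).
#' @return The filtered panel.  A summary of the number of calls and sites
#'   removed by each rule is attached as `attr(, "filter_log")`.
#' @export
apply_site_filters <- function(panel, min_depth = 10, depth_sd = 2) {
  if (n_sites(panel) == 0) stop("empty panel")
  if (is.null(panel$depth)) stop("panel has no depth information")
  g <- panel$geno
  d <- panel$depth

  low <- !is.na(g) & (is.na(d) | d < min_depth)
  g[low] <- NA_integer_

  # per-sample depth moments over calls passing the min-depth cutoff;
  # based on depths only, so re-application reproduces the same censoring
  censored <- matrix(FALSE, nrow(g), ncol(g))
  for (j in seq_len(ncol(g))) {
    keep <- !is.na(d[, j]) & d[, j] >= min_depth
    if (!any(keep)) next
    mu <- mean(d[keep, j])
    s <- sd(d[keep, j])
    if (is.na(s) || s == 0) next
    censored[, j] <- keep & abs(d[, j] - mu) > depth_sd * s
  }
  g[censored & !is.na(g)] <- NA_integer_
  n_censored <- sum(censored & !low)

  # allele count among retained calls (het calls contribute both alleles)
  n_alleles <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    gi <- gi[!is.na(gi)]
    if (!length(gi)) next
    al <- gi[gi >= 0L]
    if (any(gi < 0L)) {
      ab <- decode_het(gi[gi < 0L])
      al <- c(al, ab)
    }
    n_alleles[i] <- length(unique(al))
  }
  keep_site <- n_alleles <= 2L

  out <- subset_panel(
    structure(list(sites = panel$sites, geno = g, samples = panel$samples,
                   depth = d, degeneracy = panel$degeneracy,
                   callable = panel$callable,
                   chrom_lengths = panel$chrom_lengths),
              class = "genotype_panel"),
    which(keep_site))
  attr(out, "filter_log") <- list(
    n_calls_low_depth = sum(low),
    n_calls_depth_censored = n_censored,
    n_sites_multiallelic_dropped = sum(!keep_site))
  out
}

#' Resolve residual heterozygous calls
#'
#' Inbred lines occasionally retain heterozygous diploid calls; each such
#' call is replaced by one of its two alleles chosen uniformly at random.
#' Deterministic under `seed`; the caller's RNG state is untouched.
#'
#' @param panel a [genotype_panel()].
#' @param seed integer seed.
#' @return Panel with all calls haploid.
#' @export
resolve_heterozygotes <- function(panel, seed) {
  g <- panel$geno
  hetm <- which(is_het(g))
  if (length(hetm)) {
    ab <- decode_het(g[hetm])
    pick <- with_seed(seed, runif(length(hetm)) < 0.5)
    g[hetm] <- ifelse(pick, ab[, "a"], ab[, "b"])
  }
  out <- panel
  out$geno <- g
  out
}
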