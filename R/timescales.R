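#' Mutation-rate parameters
#'
#' @param mu mutations per bp per generation (default 1.5e-8).
#' @param generation_time years per generation (default 1, an annual).
#' @return list of class `rate_params`.
#' @export
rate_params <- function(mu = 1.5e-8, generation_time = 1) {
  stopifnot(mu > 0, generation_time > 0)
  structure(list(mu = mu, generation_time = generation_time),
            class = "rate_params")
}

#' Split time from a diversity difference
#'
#' Under neutrality, pairwise divergence between two populations is the
#' ancestral diversity plus `2 * mu * tau`, so the split time is
#' `tau = (pi_between - pi_ancestral) / (2 * mu)` generations.  Ancestral
#' diversity is usually proxied by present-day diversity within one
#' population.
#'
#' @param pi_between pairwise divergence between the populations (fraction
#'   per site).
#' @param pi_ancestral ancestral (proxy) diversity (fraction per site).
#' @param rates a [rate_params()].
#' @param pi_between_ci,pi_ancestral_ci optional length-2 bootstrap bounds
#'   on the two pi inputs; when both are given they are pushed through the
#'   formula to bracket tau (low divergence with high ancestral diversity
#'   gives the lower bound).
#' @return list of class `split_estimate` with `tau_generations`,
#'   `tau_years`, and optional `tau_years_ci`.
#' @export
split_time <- function(pi_between, pi_ancestral, rates = rate_params(),
                       pi_between_ci = NULL, pi_ancestral_ci = NULL) {
  if (pi_between < pi_ancestral)
    stop("pi_between < pi_ancestral implies a negative split time")
  tau <- (pi_between - pi_ancestral) / (2 * rates$mu)
  out <- list(tau_generations = tau,
              tau_years = tau * rates$generation_time)
  if (!is.null(pi_between_ci) && !is.null(pi_ancestral_ci)) {
    lo <- (min(pi_between_ci) - max(pi_ancestral_ci)) / (2 * rates$mu)
    hi <- (max(pi_between_ci) - min(pi_ancestral_ci)) / (2 * rates$mu)
    out$tau_generations_ci <- c(lo, hi)
    out$tau_years_ci <- c(lo, hi) * rates$generation_time
  }
  structure(out, class = "split_estimate")
}

#' Coalescent scale of a diversity level
#'
#' Returns `pi / (2 * mu)`.  Interpreted as an effective number of
#' chromosomes when `pi` is diversity within a population (haploid
#' pairwise coalescence at rate `1/Ne*` gives `E[pi] = 2 * Ne* * mu`), or
#' as a divergence time in generations when `pi` measures divergence
#' between a pair of sequences.
#'
#' @param pi pairwise diversity (fraction per site), `>= 0`.
#' @param rates a [rate_params()].
#' @return `pi / (2 * mu)` (chromosomes or generations, caller's choice).
#' @export
pi_to_scale <- function(pi, rates = rate_params()) {
  stopifnot(all(pi >= 0))
  pi / (2 * rates$mu)
}

#' Probability of no coalescence by generation t
#'
#' Under a constant effective number of chromosomes `N`, a pair of lineages
#' fails to find a common ancestor by generation `t` with probability
#' `exp(-t / N)`.
#'
#' @param t time in generations (`>= 0`).
#' @param N effective number of chromosomes (`> 0`).
#' @return probability.
#' @export
noncoalescence <- function(t, N) {
  stopifnot(all(t >= 0), all(N > 0))
  exp(-t / N)
}

#' @rdname noncoalescence
#' @param p target non-coalescence probability, strictly in (0, 1).
#' @return `solve_N`: the `N` such that `noncoalescence(t, N) == p`,
#'   i.e. `t / log(1/p)`.
#' @export
solve_N <- function(t, p) {
  if (any(p <= 0 | p >= 1)) stop("p must be strictly inside (0, 1)")
  t / log(1 / p)
}

#' Selfing rate from effective-size and LD-decay ratios
#'
#' In a predominant selfer the population-scaled recombination to mutation
#' ratio is reduced by a factor `1 - F` relative to an outcrossing
#' population (Nordborg's effective-recombination argument).  Comparing a
#' selfer to its outcrossing relative, the ratio of their effective-size
#' reductions to their LD-decay-scale reductions estimates `1 - F`; under
#' a constant selfing rate `s`, `F = s / (2 - s)`, i.e. `s = 2F / (1 + F)`.
#'
#' @param ne_ratio fold-reduction in effective population size
#'   (outcrosser / selfer), `> 0`.
#' @param ld_ratio fold-change in the physical scale of LD decay
#'   (selfer / outcrosser), `>= ne_ratio`.
#' @return list of class `selfing_estimate`: `one_minus_F`, `F`, `s`.
#' @export
selfing_rate_from_ratios <- function(ne_ratio, ld_ratio) {
  if (!(ld_ratio >= ne_ratio && ne_ratio > 0))
    stop("need ld_ratio >= ne_ratio > 0")
  one_minus_F <- ne_ratio / ld_ratio
  Fc <- 1 - one_minus_F
  if (Fc < 0 || Fc > 1) stop("inferred F outside [0, 1]")
  structure(list(one_minus_F = one_minus_F, F = Fc, s = 2 * Fc / (1 + Fc)),
            class = "selfing_estimate")
}

#' @rdname selfing_rate_from_ratios
#' @param s selfing rate in `[0, 1)`.
#' @return `selfing_to_F`: the equilibrium inbreeding coefficient
#'   `F = s / (2 - s)`.
#' @export
selfing_to_F <- function(s) {
  stopifnot(all(s >= 0 & s < 1))
  s / (2 - s)
}

#' Linkage-disequilibrium decay profile
#'
#' Mean `r^2` between pairs of biallelic polymorphic sites as a function of
#' physical distance, and the distance at which the profile has dropped
#' halfway from its short-range maximum towards its long-range minimum.
#' The maximum is the mean of the shortest-distance bin and the asymptotic
#' minimum the mean over the last 10 percent of bins.
#'
#' @param panel a [genotype_panel()].
#' @param samples samples over which to compute haplotype `r^2`
#'   (at least 2).
#' @param max_dist maximum pair distance in bp.
#' @param bins number of distance bins.
#' @param max_pairs cap on the number of site pairs (pairs are subsampled
#'   deterministically above it).
#' @param seed seed for the pair subsample.
#' @return list of class `ld_profile`: data.frame `profile`
#'   (`dist`, `mean_r2`, `n_pairs`) and `half_decay_bp`.
#' @export
ld_profile <- function(panel, samples, max_dist = 5e4, bins = 50,
                       max_pairs = 2e5, seed = 1) {
  ii <- sample_index(panel, samples)
  if (length(ii) < 2) stop("need at least two samples")
  g <- panel$geno[, ii, drop = FALSE]
  poly <- vapply(seq_len(nrow(g)), function(i) {
    x <- g[i, ]; x <- x[!is.na(x)]
    length(unique(x)) == 2L
  }, logical(1))
  if (!any(poly)) stop("no biallelic polymorphic sites among the samples")
  keep <- which(poly)
  pos <- panel$sites$pos[keep]
  chrom <- panel$sites$chrom[keep]
  g <- g[keep, , drop = FALSE]
  # minor-allele indicator per site
  x01 <- t(vapply(seq_len(nrow(g)), function(i) {
    xi <- g[i, ]
    as.numeric(xi == max(xi, na.rm = TRUE))
  }, numeric(ncol(g))))

  ord <- order(chrom, pos)
  pos <- pos[ord]; chrom <- chrom[ord]; x01 <- x01[ord, , drop = FALSE]
  pr_i <- integer(0); pr_j <- integer(0)
  for (ch in unique(chrom)) {
    w <- which(chrom == ch)
    p <- pos[w]
    hi <- findInterval(p + max_dist, p)
    for (k in seq_along(w)) {
      if (hi[k] > k)
        { pr_i <- c(pr_i, rep(w[k], hi[k] - k)); pr_j <- c(pr_j, w[(k + 1):hi[k]]) }
    }
  }
  if (!length(pr_i)) stop("no site pairs within max_dist")
  if (length(pr_i) > max_pairs) {
    sel <- with_seed(seed, sample.int(length(pr_i), max_pairs))
    pr_i <- pr_i[sel]; pr_j <- pr_j[sel]
  }
  r2 <- vapply(seq_along(pr_i), function(k) {
    xi <- x01[pr_i[k], ]; xj <- x01[pr_j[k], ]
    ok <- !is.na(xi) & !is.na(xj)
    if (sum(ok) < 2) return(NA_real_)
    v <- suppressWarnings(stats::cor(xi[ok], xj[ok]))
    if (is.na(v)) NA_real_ else v^2
  }, numeric(1))
  d <- pos[pr_j] - pos[pr_i]
  br <- seq(0, max_dist, length.out = bins + 1)
  bin <- cut(d, br, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(r2) & !is.na(bin)
  mean_r2 <- tapply(r2[ok], factor(bin[ok], levels = seq_len(bins)), mean)
  n_pairs <- tapply(r2[ok], factor(bin[ok], levels = seq_len(bins)), length)
  mid <- (br[-1] + br[-length(br)]) / 2
  prof <- data.frame(dist = mid, mean_r2 = as.numeric(mean_r2),
                     n_pairs = as.integer(ifelse(is.na(n_pairs), 0, n_pairs)))
  obs <- prof[!is.na(prof$mean_r2), , drop = FALSE]
  half_decay <- NA_real_
  if (nrow(obs) >= 3) {
    top <- obs$mean_r2[1]
    floor_bins <- max(1, ceiling(nrow(obs) * 0.1))
    bottom <- mean(tail(obs$mean_r2, floor_bins))
    target <- (top + bottom) / 2
    below <- which(obs$mean_r2 <= target)
    if (length(below)) half_decay <- obs$dist[min(below)]
  }
  structure(list(profile = prof, half_decay_bp = half_decay),
            class = "ld_profile")
}
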