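#' Simulation configuration
#'
#' Parameters for the synthetic-data generators.  Defaults describe the
#' study system the package targets: a 14-chromosome, 260 Mb genome with a
#' 14.7 Morgan map, mutation rate 1.5e-8 per bp per generation, conspecific
#' diversity 0.3 percent and heterospecific divergence 4 percent, and an
#' admixture pulse of proportion 0.15 placed 150 generations ago.
#'
#' @param n_recipient pure recipient-taxon reference samples.
#' @param n_donor donor-taxon panel samples.
#' @param genome_bp total genome length (bp).
#' @param n_chromosomes chromosome count (equal lengths).
#' @param map_length_morgans total map length (Morgans), uniform in bp.
#' @param mu mutation rate per bp per generation.
#' @param pi_within expected conspecific pairwise diversity (per site).
#' @param pi_between expected heterospecific divergence (per site).
#' @param alpha admixture proportion in `[0, 1]`.
#' @param v generations since the admixture pulse.
#' @param pulse_times optional vector of pulse ages (generations) for
#'   multi-pulse scenarios; `alpha` is then split evenly across pulses
#'   unless `pulse_alphas` is given.
#' @param pulse_alphas optional per-pulse admixture proportions.
#' @param seed integer seed; identical configs reproduce identical data.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_recipient = 2, n_donor = 4,
                       genome_bp = 2.6e8, n_chromosomes = 14,
                       map_length_morgans = 14.7, mu = 1.5e-8,
                       pi_within = 0.003, pi_between = 0.04,
                       alpha = 0.15, v = 150,
                       pulse_times = NULL, pulse_alphas = NULL, seed = 1) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (!(pi_between >= pi_within && pi_within >= 0))
    stop("need pi_between >= pi_within >= 0")
  if (genome_bp <= 0 || n_chromosomes <= 0 || map_length_morgans <= 0)
    stop("genome_bp, n_chromosomes and map_length_morgans must be positive")
  if (mu <= 0) stop("mu must be positive")
  if (v < 0) stop("v must be non-negative")
  if (!is.null(pulse_alphas) && length(pulse_alphas) != length(pulse_times))
    stop("pulse_alphas must match pulse_times")
  structure(list(n_recipient = n_recipient, n_donor = n_donor,
                 genome_bp = genome_bp, n_chromosomes = n_chromosomes,
                 map_length_morgans = map_length_morgans, mu = mu,
                 pi_within = pi_within, pi_between = pi_between,
                 alpha = alpha, v = v, pulse_times = pulse_times,
                 pulse_alphas = pulse_alphas, seed = as.integer(seed)),
            class = "sim_config")
}

# One neutral Kingman genealogy for a two-population split, with optional
# stepwise bottleneck in either population and an optional one-off
# migration pulse, plus infinite-sites mutations.  Sizes are in effective
# chromosomes, times in generations before present.  Returns a 0/1 matrix
# (mutations x samples); samples 1..n1 are population 1.
coalescent_locus <- function(n1, n2, N1, N2, N_anc, tau,
                             bottleneck = NULL, pulse = NULL, theta_locus = 0) {
  n <- n1 + n2
  lineages <- lapply(seq_len(n), function(i) i)     # leaf sets
  popof <- c(rep(1L, n1), rep(2L, n2))
  birth <- rep(0, n)
  alive <- rep(TRUE, n)
  muts <- list()
  t <- 0

  drop_mutations <- function(idx, t_end) {
    for (i in idx) {
      nm <- rpois(1, theta_locus / 2 * (t_end - birth[i]))
      if (nm > 0) muts[[length(muts) + 1L]] <<- list(leaves = lineages[[i]], n = nm)
    }
  }

  pop_size <- function(pop, t) {
    if (!is.null(bottleneck) && bottleneck$pop == pop &&
        t >= bottleneck$start && t < bottleneck$end) return(bottleneck$N)
    if (t >= tau) return(N_anc)
    if (pop == 1L) N1 else N2
  }
  # times at which rates or structure change
  checkpoints <- sort(unique(c(tau,
                               if (!is.null(bottleneck)) c(bottleneck$start, bottleneck$end),
                               if (!is.null(pulse)) pulse$time)))
  checkpoints <- checkpoints[checkpoints > 0]
  ci <- 1L

  repeat {
    act <- which(alive)
    if (length(act) <= 1L) break
    k1 <- sum(popof[act] == 1L)
    k2 <- sum(popof[act] == 2L)
    if (t >= tau) { k1 <- k1 + k2; k2 <- 0L }  # merged
    rate <- 0
    if (k1 >= 2) rate <- rate + choose(k1, 2) / pop_size(1L, t)
    if (k2 >= 2) rate <- rate + choose(k2, 2) / pop_size(2L, t)
    nxt <- if (ci <= length(checkpoints)) checkpoints[ci] else Inf
    dt <- if (rate > 0) rexp(1, rate) else Inf
    if (t + dt >= nxt) {
      t <- nxt
      ci <- ci + 1L
      if (!is.null(pulse) && t == pulse$time) {
        movers <- act[popof[act] == pulse$from]
        mv <- movers[runif(length(movers)) < pulse$prob]
        popof[mv] <- pulse$to
      }
      next
    }
    t <- t + dt
    # choose the population of the coalescing pair
    r1 <- if (k1 >= 2) choose(k1, 2) / pop_size(1L, t) else 0
    pop <- if (runif(1) < r1 / rate) 1L else 2L
    cand <- if (t >= tau) act else act[popof[act] == pop]
    pair <- sample(cand, 2)
    drop_mutations(pair, t)
    alive[pair] <- FALSE
    new <- length(lineages) + 1L
    lineages[[new]] <- sort(c(lineages[[pair[1]]], lineages[[pair[2]]]))
    popof <- c(popof, if (t >= tau) 1L else pop)
    birth <- c(birth, t)
    alive <- c(alive, TRUE)
  }

  if (!length(muts)) return(matrix(0L, 0, n))
  rows <- lapply(muts, function(m) {
    out <- matrix(0L, m$n, n)
    out[, m$leaves] <- 1L
    out
  })
  do.call(rbind, rows)
}

#' Simulate unlinked loci under a two-population split
#'
#' Per-locus neutral coalescent genealogies for samples from two
#' populations that split `tau` generations ago, with an optional stepwise
#' bottleneck and an optional migration pulse; infinite-sites mutations
#' are dropped at rate `mu` per bp.  Loci are statistically independent
#' and are laid out round-robin across `config$n_chromosomes` chromosomes
#' (non-overlapping `locus_bp` slots) so that chromosome-blocked methods
#' (jackknife, bootstrap) can be exercised.
#'
#' Population sizes default to the diversity levels in `config`:
#' `N = pi_within / (2 mu)` chromosomes for both daughters and the
#' ancestor, and `tau = (pi_between - pi_within) / (2 mu)`, so that
#' `E[pi_between] = pi_anc + 2 mu tau = pi_between`.
#'
#' @param config a [sim_config()]; `seed` drives the whole simulation.
#' @param n_loci number of independent loci (> 0).
#' @param samples_per_pop haploid samples per population (scalar, or a
#'   length-2 vector for asymmetric sampling).
#' @param locus_bp locus length in bp.
#' @param demography optional overrides: list with any of `N1`, `N2`,
#'   `N_anc` (chromosomes), `tau` (generations), `bottleneck =
#'   list(pop, start, end, N)`, `pulse = list(time, prob, from, to)`.
#' @return A genome-callable [genotype_panel()]; sample names are
#'   `P1_1..` and `P2_1..`.
#' @export
simulate_unlinked_loci <- function(config, n_loci, samples_per_pop,
                                   locus_bp = 1e4, demography = list()) {
  stopifnot(inherits(config, "sim_config"))
  if (n_loci <= 0) stop("n_loci must be positive")
  N_def <- config$pi_within / (2 * config$mu)
  tau_def <- (config$pi_between - config$pi_within) / (2 * config$mu)
  N1 <- demography$N1 %||% N_def
  N2 <- demography$N2 %||% N_def
  N_anc <- demography$N_anc %||% N_def
  tau <- demography$tau %||% tau_def
  if (N1 <= 0 || N2 <= 0 || N_anc <= 0 || tau < 0)
    stop("invalid demography: sizes must be positive and times non-negative")
  bn <- demography$bottleneck
  if (!is.null(bn) && (bn$N <= 0 || bn$start < 0 || bn$end <= bn$start))
    stop("invalid demography: malformed bottleneck")
  theta_locus <- 2 * config$mu * locus_bp  # so E[pairwise diff] = 2 N mu L
  if (length(samples_per_pop) == 1) samples_per_pop <- rep(samples_per_pop, 2)
  n1 <- samples_per_pop[1]; n2 <- samples_per_pop[2]
  samples <- c(paste0("P1_", seq_len(n1)), paste0("P2_", seq_len(n2)))
  n_chrom <- config$n_chromosomes

  res <- with_seed(config$seed, {
    lapply(seq_len(n_loci), function(l) {
      gm <- coalescent_locus(n1, n2, N1, N2, N_anc, tau,
                             bottleneck = bn, pulse = demography$pulse,
                             theta_locus = theta_locus)
      chrom <- paste0("chr", 1 + (l - 1) %% n_chrom)
      slot <- (l - 1) %/% n_chrom
      if (nrow(gm) == 0) return(NULL)
      pos <- slot * locus_bp + sort(sample.int(locus_bp, nrow(gm),
                                               replace = FALSE)) - 1L
      data.frame(chrom = chrom, pos = pos, gm, stringsAsFactors = FALSE)
    })
  })
  res <- res[!vapply(res, is.null, logical(1))]
  # callable length per chromosome covers only the locus slots actually
  # simulated (the last round-robin pass may be partial)
  loci_on_chrom <- tabulate(1 + (seq_len(n_loci) - 1) %% n_chrom, n_chrom)
  chrom_lengths <- setNames(loci_on_chrom * locus_bp,
                            paste0("chr", seq_len(n_chrom)))
  chrom_lengths <- chrom_lengths[chrom_lengths > 0]
  if (!length(res)) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0))
    return(genotype_panel(sites, matrix(0L, 0, n1 + n2), samples,
                          callable = "genome", chrom_lengths = chrom_lengths))
  }
  all <- do.call(rbind, res)
  sites <- data.frame(chrom = all$chrom, pos = all$pos,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  geno <- as.matrix(all[, -(1:2), drop = FALSE])
  # collisions from independent mutations at one position: keep the first
  dup <- duplicated(paste(sites$chrom, sites$pos))
  genotype_panel(sites[!dup, , drop = FALSE], geno[!dup, , drop = FALSE],
                 samples, callable = "genome", chrom_lengths = chrom_lengths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
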