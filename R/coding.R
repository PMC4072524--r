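#' Premature stop codons in one sample
#'
#' Translates each gene in the sample's genotype background and reports
#' mutant stop codons (TAA/TAG/TGA on the coding strand) subject to three
#' conjunctive admissibility rules:
#'
#' 1. all three nucleotide sites of the codon have data in the sample;
#' 2. at least `min_gene_fraction` (default 25 percent) of the gene's
#'    codons have complete data in the sample;
#' 3. the codon does not fall in the last 5 percent of codons at the 3'
#'    end of the gene.
#'
#' Codons that are stops in the reference annotation itself are never
#' reported (they are not mutant).  A codon carrying two substitutions
#' that jointly produce a stop counts once.
#'
#' @param panel a [genotype_panel()].  For panel-callable data a coding
#'   position absent from the site list counts as missing; for
#'   genome-callable simulator output it counts as a reference call.
#' @param sample sample name.
#' @param genes a [gene_models()] object.
#' @param reference named character vector of chromosome sequences.
#' @param min_gene_fraction rule-2 cutoff.
#' @param last_fraction rule-3 cutoff (default 0.05).
#' @return data.frame of class `stop_events`: `gene_id`, `sample`,
#'   `codon_index` (1-based), `codon_fraction`, `codon`, `n_codons`.
#' @export
find_premature_stops <- function(panel, sample, genes, reference,
                                 min_gene_fraction = 0.25,
                                 last_fraction = 0.05) {
  j <- sample_index(panel, sample)
  reference <- unlist(reference)
  res <- list()
  for (gid in unique(genes$gene_id)) {
    gi <- genes[genes$gene_id == gid, , drop = FALSE]
    ch <- gi$chrom[1]
    sp <- spliced_coding(gi, reference[[ch]])
    if (length(sp$seq) %% 3L != 0L) stop("frame inconsistency in gene ", gid)
    on_ch <- panel$sites$chrom == ch
    m <- match(sp$pos, ifelse(on_ch, panel$sites$pos, NA_integer_))
    call <- rep(NA_integer_, length(sp$pos))
    call[!is.na(m)] <- panel$geno[m[!is.na(m)], j]
    call[is_het(call)] <- NA_integer_  # unresolved hets carry no haploid base
    if (panel$callable == "genome") call[is.na(m)] <- 0L

    base <- sp$seq                       # coding-strand reference base
    base[is.na(call)] <- NA_character_
    nonref <- which(!is.na(call) & call > 0L)
    if (length(nonref)) {
      alts <- strsplit(panel$sites$alt[m[nonref]], ",")
      ab <- mapply(function(a, k) if (k <= length(a)) a[k] else NA_character_,
                   alts, call[nonref])
      if (gi$strand[1] == "-") ab <- chartr("ACGTacgt", "TGCAtgca", ab)
      base[nonref] <- toupper(ab)
    }
    n_cod <- length(base) %/% 3L
    codm <- matrix(base, nrow = 3)
    avail <- colSums(is.na(codm)) == 0L
    if (mean(avail) < min_gene_fraction) next
    cods <- apply(codm, 2, function(x)
      if (anyNA(x)) NA_character_ else paste(x, collapse = ""))
    refm <- matrix(sp$seq, nrow = 3)
    ref_cods <- apply(refm, 2, paste, collapse = "")
    idx <- which(avail & cods %in% STOP_CODONS & !(ref_cods %in% STOP_CODONS))
    idx <- idx[idx / n_cod <= 1 - last_fraction]
    if (length(idx))
      res[[gid]] <- data.frame(gene_id = gid, sample = sample,
                               codon_index = idx,
                               codon_fraction = idx / n_cod,
                               codon = cods[idx], n_codons = n_cod,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), sample = character(0),
                      codon_index = integer(0), codon_fraction = numeric(0),
                      codon = character(0), n_codons = integer(0))
  rownames(out) <- NULL
  class(out) <- c("stop_events", "data.frame")
  out
}

#' Summarise premature stops across samples
#'
#' Per-sample event counts and the sharing spectrum: how many distinct
#' stop codons (gene, codon index) are seen in exactly 1, 2, ... of the
#' samples.  An excess of high-frequency premature stops in the selfing
#' taxon is a signature of relaxed purifying selection.
#'
#' @param events list of [find_premature_stops()] tables (one per
#'   sample), or a single row-bound table.
#' @return list with `per_sample` (named counts) and `sharing` (named
#'   histogram over the number of carrying samples).
#' @export
stop_sharing_summary <- function(events) {
  ev <- if (is.data.frame(events)) events else do.call(rbind, events)
  if (!nrow(ev))
    return(list(per_sample = integer(0), sharing = integer(0)))
  per_sample <- table(ev$sample)
  key <- paste(ev$gene_id, ev$codon_index)
  carriers <- tapply(ev$sample, key, function(s) length(unique(s)))
  n_max <- length(unique(ev$sample))
  sharing <- tabulate(carriers, nbins = n_max)
  list(per_sample = c(per_sample),
       sharing = setNames(sharing, seq_len(n_max)))
}

#' Ratio of nonsynonymous to synonymous diversity
#'
#' Mean pairwise diversity per zerofold-degenerate site over mean pairwise
#' diversity per fourfold-degenerate site across all pairs of the given
#' samples, with a block-bootstrap confidence interval for the ratio.
#' Pairs are pooled (summed mismatches over summed informative sites) so
#' sparse windows do not destabilise the ratio.
#'
#' @param panel a degeneracy-annotated [genotype_panel()].
#' @param samples sample names (>= 2).
#' @param block_bp,n_boot,seed,conf bootstrap settings
#'   (see [block_bootstrap()]).
#' @return list of class `pnps_estimate`: `pi_N`, `pi_S`, `ratio`,
#'   `ci` (length 2), `undefined` (`TRUE` when `pi_S` is 0 -- the ratio
#'   is then flagged, not reported as a number).
#' @export
pn_ps <- function(panel, samples, block_bp = 1e5, n_boot = 200, seed = 1,
                  conf = 0.95) {
  if (length(samples) < 2) stop("need at least two samples")
  pool_pi <- function(p, class) {
    pairs <- utils::combn(samples, 2)
    tot_k <- 0; tot_n <- 0
    for (k in seq_len(ncol(pairs))) {
      r <- pairwise_pi(p, pairs[1, k], pairs[2, k], site_class = class)
      tot_k <- tot_k + r$n_diff; tot_n <- tot_n + r$n_sites
    }
    if (tot_n == 0) NA_real_ else tot_k / tot_n
  }
  pi_N <- pool_pi(panel, "0")
  pi_S <- pool_pi(panel, "4")
  if (is.na(pi_S) || pi_S == 0)
    return(structure(list(pi_N = pi_N, pi_S = pi_S, ratio = NA_real_,
                          ci = c(NA_real_, NA_real_), undefined = TRUE),
                     class = "pnps_estimate"))
  bb <- block_bootstrap(function(p) {
    s <- pool_pi(p, "4")
    if (is.na(s) || s == 0) NA_real_ else pool_pi(p, "0") / s
  }, panel, block_bp = block_bp, n_boot = n_boot, seed = seed, conf = conf)
  structure(list(pi_N = pi_N, pi_S = pi_S, ratio = pi_N / pi_S,
                 ci = c(bb$lo, bb$hi), undefined = FALSE),
            class = "pnps_estimate")
}
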