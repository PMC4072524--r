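#' Pairwise nucleotide diversity
#'
#' Mean pairwise sequence difference between two samples.  The denominator
#' counts only sites at which both samples have a (filtered) call and which
#' belong to `site_class`; the numerator counts mismatches among those.
#' For genome-callable simulator panels the denominator is the callable
#' length in bp (every position is a site under the infinite-sites model).
#'
#' @param panel a [genotype_panel()].
#' @param a,b sample names.
#' @param site_class optional set of degeneracy classes (e.g. `"4"` for
#'   synonymous pi); `NULL` uses every site.
#' @param chrom,start,end optional region restriction (0-based half-open).
#' @return list with `n_sites`, `n_diff`, `pi` (`NA` and `undefined = TRUE`
#'   when no informative site exists -- an undefined ratio, not a zero).
#' @export
pairwise_pi <- function(panel, a, b, site_class = NULL,
                        chrom = NULL, start = NULL, end = NULL) {
  ia <- sample_index(panel, a); ib <- sample_index(panel, b)
  mask <- site_class_mask(panel, site_class)
  if (!is.null(chrom)) {
    mask <- mask & panel$sites$chrom == chrom
    if (!is.null(start)) mask <- mask & panel$sites$pos >= start
    if (!is.null(end)) mask <- mask & panel$sites$pos < end
  }
  ga <- panel$geno[, ia]; gb <- panel$geno[, ib]
  called <- !is.na(ga) & !is.na(gb) & mask
  k <- sum(called & ga != gb, na.rm = TRUE)
  if (panel$callable == "genome") {
    if (!is.null(site_class))
      stop("site_class is not defined for genome-callable panels")
    n <- if (is.null(chrom)) sum(panel$chrom_lengths) else {
      L <- panel$chrom_lengths[[chrom]]
      s <- if (is.null(start)) 0 else start
      e <- if (is.null(end)) L else min(end, L)
      e - s
    }
  } else {
    n <- sum(called)
  }
  list(n_sites = as.numeric(n), n_diff = as.numeric(k),
       pi = if (n > 0) k / n else NA_real_, undefined = n == 0)
}

# Window grid for one chromosome: full windows anchored at 0, plus one
# final partial window when the remainder is at least half a window.
window_starts <- function(L, window_bp, slide_bp) {
  starts <- seq(0, max(0, L - window_bp), by = slide_bp)
  if (L < window_bp) starts <- numeric(0)
  nxt <- if (length(starts)) starts[length(starts)] + slide_bp else 0
  if (nxt < L && (L - nxt) >= window_bp / 2) starts <- c(starts, nxt)
  starts
}

#' Sliding-window pairwise diversity
#'
#' Windowed version of [pairwise_pi()] (default: overlapping 5 kb windows
#' with a 1 kb slide).  Windows with fewer informative sites than
#' `min_sites` are flagged `insufficient` and should be excluded from
#' summaries and histograms.
#'
#' @inheritParams pairwise_pi
#' @param window_bp,slide_bp window length and slide in bp.
#' @param min_sites minimum informative sites per window.
#' @return data.frame, one row per window: `chrom`, `start`, `end`,
#'   `n_sites`, `n_diff`, `pi`, `insufficient`.
#' @export
windowed_pi <- function(panel, a, b, site_class = NULL,
                        window_bp = 5000, slide_bp = 1000, min_sites = 100) {
  if (window_bp < slide_bp) stop("window_bp must be >= slide_bp")
  ia <- sample_index(panel, a); ib <- sample_index(panel, b)
  mask <- site_class_mask(panel, site_class)
  if (panel$callable == "genome" && !is.null(site_class))
    stop("site_class is not defined for genome-callable panels")
  ga <- panel$geno[, ia]; gb <- panel$geno[, ib]
  called <- !is.na(ga) & !is.na(gb) & mask
  diff <- called & ga != gb
  lens <- panel_chrom_lengths(panel)
  out <- lapply(names(lens), function(ch) {
    L <- lens[[ch]]
    starts <- window_starts(L, window_bp, slide_bp)
    if (!length(starts)) return(NULL)
    ends <- pmin(starts + window_bp, L)
    on_ch <- panel$sites$chrom == ch
    p_called <- sort(panel$sites$pos[on_ch & called])
    p_diff <- sort(panel$sites$pos[on_ch & diff])
    n_called <- findInterval(ends - 1, p_called) - findInterval(starts - 1, p_called)
    n_diff <- findInterval(ends - 1, p_diff) - findInterval(starts - 1, p_diff)
    n_sites <- if (panel$callable == "genome") ends - starts else n_called
    data.frame(chrom = ch, start = starts, end = ends,
               n_sites = n_sites, n_diff = n_diff,
               pi = ifelse(n_sites > 0, n_diff / n_sites, NA_real_),
               insufficient = n_sites < min_sites,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Block bootstrap over genomic windows
#'
#' Confidence intervals for genome-wide statistics that acknowledge the
#' non-independence of linked variants: the genome is partitioned into
#' `block_bp` blocks (default 100 kb), blocks are resampled with
#' replacement, and the statistic is recomputed on each resample.  Each
#' resampled block becomes its own pseudo-chromosome so that window
#' arithmetic and callable lengths stay coherent.
#'
#' @param statistic function taking a [genotype_panel()] and returning a
#'   numeric scalar (or vector).
#' @param panel a [genotype_panel()].
#' @param block_bp block length in bp.
#' @param n_boot number of bootstrap resamples (>= 2).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95, i.e. 2.5/97.5 percentiles).
#' @return list with `point`, `lo`, `hi`, the bootstrap draws in `boot`,
#'   and `n_redrawn`, the number of resamples redrawn because the statistic
#'   was undefined on them.
#' @export
block_bootstrap <- function(statistic, panel, block_bp = 1e5, n_boot = 200,
                            seed = 1, conf = 0.95) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  lens <- panel_chrom_lengths(panel)
  blocks <- do.call(rbind, lapply(names(lens), function(ch) {
    starts <- seq(0, lens[[ch]] - 1, by = block_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + block_bp, lens[[ch]]),
               stringsAsFactors = FALSE)
  }))
  B <- nrow(blocks)
  site_block <- match(paste(panel$sites$chrom, panel$sites$pos %/% block_bp),
                      paste(blocks$chrom, blocks$start %/% block_bp))
  idx_by_block <- split(seq_len(n_sites(panel)), factor(site_block, levels = seq_len(B)))

  resample_panel <- function(chosen) {
    idx <- unlist(idx_by_block[chosen], use.names = FALSE)
    rep_id <- rep(seq_along(chosen), times = lengths(idx_by_block[chosen]))
    sub <- subset_panel(panel, idx)
    sub$sites$pos <- sub$sites$pos - blocks$start[chosen][rep_id]
    sub$sites$chrom <- paste0("B", rep_id)
    newlens <- setNames(blocks$end[chosen] - blocks$start[chosen],
                        paste0("B", seq_along(chosen)))
    sub$chrom_lengths <- if (panel$callable == "genome") newlens else NULL
    # resampling can duplicate a block; positions then collide across
    # pseudo-chromosome labels only, which stay distinct
    sub
  }

  point <- statistic(panel)
  boot <- matrix(NA_real_, n_boot, length(point))
  n_redrawn <- 0L
  with_seed(seed, {
    b <- 1L
    guard <- 0L
    while (b <= n_boot && guard < 10L * n_boot + 100L) {
      guard <- guard + 1L
      chosen <- sample.int(B, B, replace = TRUE)
      val <- tryCatch(statistic(resample_panel(chosen)),
                      error = function(e) NA_real_)
      if (length(val) == length(point) && !anyNA(val)) {
        boot[b, ] <- val
        b <- b + 1L
      } else {
        n_redrawn <- n_redrawn + 1L
      }
    }
    if (b <= n_boot) stop("block_bootstrap: statistic undefined on too many resamples")
  })
  alpha <- (1 - conf) / 2
  list(point = point,
       lo = apply(boot, 2, quantile, probs = alpha, names = FALSE),
       hi = apply(boot, 2, quantile, probs = 1 - alpha, names = FALSE),
       boot = boot, n_redrawn = n_redrawn)
}

#' Polarized allele-frequency spectrum
#'
#' Derived-allele counts over the ingroup, with ancestral state assigned by
#' an outgroup sample.  Sites where the outgroup is missing, or where the
#' outgroup carries a third allele not seen in the ingroup comparison, are
#' excluded; only sites with complete ingroup data are tallied.
#'
#' @param panel a [genotype_panel()].
#' @param ingroup character vector of ingroup sample names.
#' @param outgroup single outgroup sample name.
#' @param site_class optional degeneracy class set.
#' @return list with `counts` (named histogram over derived-allele counts
#'   `1..n_ingroup`) and `n_sites_used`.
#' @export
polarized_afs <- function(panel, ingroup, outgroup, site_class = NULL) {
  ii <- sample_index(panel, ingroup)
  io <- sample_index(panel, outgroup)
  mask <- site_class_mask(panel, site_class)
  gin <- panel$geno[, ii, drop = FALSE]
  go <- panel$geno[, io]
  complete <- rowSums(is.na(gin)) == 0L & !is.na(go) & mask
  if (!any(complete)) stop("no usable sites for the polarized AFS")
  gin <- gin[complete, , drop = FALSE]
  go <- go[complete]
  # drop sites where {outgroup, ingroup} carry more than two alleles
  nal <- vapply(seq_len(nrow(gin)),
                function(i) length(unique(c(gin[i, ], go[i]))), integer(1))
  ok <- nal <= 2L
  gin <- gin[ok, , drop = FALSE]
  go <- go[ok]
  derived <- rowSums(gin != go)
  n <- length(ingroup)
  counts <- tabulate(derived, nbins = n)
  list(counts = setNames(counts, seq_len(n)), n_sites_used = length(go))
}

#' Partition variants between two groups
#'
#' Assigns every polymorphic site to exactly one category: shared
#' polymorphism, private to group A, private to group B, or a fixed
#' difference.  Fixed differences are polarized by the outgroup where its
#' allele matches one side (the other side then carries the derived state).
#'
#' @param panel a [genotype_panel()].
#' @param group_a,group_b disjoint character vectors of sample names.
#' @param outgroup optional outgroup sample name for polarization.
#' @return list of counts: `shared`, `private_a`, `private_b`,
#'   `fixed_diff`, and for polarized fixed differences
#'   `fixed_derived_in_a`, `fixed_derived_in_b`, `fixed_unpolarized`.
#' @export
partition_variants <- function(panel, group_a, group_b, outgroup = NULL) {
  if (length(intersect(group_a, group_b)))
    stop("group_a and group_b must be disjoint")
  ia <- sample_index(panel, group_a)
  ib <- sample_index(panel, group_b)
  io <- if (!is.null(outgroup)) sample_index(panel, outgroup)
  ga <- panel$geno[, ia, drop = FALSE]
  gb <- panel$geno[, ib, drop = FALSE]
  counts <- c(shared = 0L, private_a = 0L, private_b = 0L, fixed_diff = 0L,
              fixed_derived_in_a = 0L, fixed_derived_in_b = 0L,
              fixed_unpolarized = 0L)
  for (i in seq_len(nrow(ga))) {
    aa <- unique(ga[i, !is.na(ga[i, ])])
    bb <- unique(gb[i, !is.na(gb[i, ])])
    if (!length(aa) || !length(bb)) next
    pa <- length(aa) > 1L; pb <- length(bb) > 1L
    if (pa && pb) counts["shared"] <- counts["shared"] + 1L
    else if (pa) counts["private_a"] <- counts["private_a"] + 1L
    else if (pb) counts["private_b"] <- counts["private_b"] + 1L
    else if (aa != bb) {
      counts["fixed_diff"] <- counts["fixed_diff"] + 1L
      if (!is.null(io) && !is.na(panel$geno[i, io])) {
        anc <- panel$geno[i, io]
        if (anc == bb) counts["fixed_derived_in_a"] <- counts["fixed_derived_in_a"] + 1L
        else if (anc == aa) counts["fixed_derived_in_b"] <- counts["fixed_derived_in_b"] + 1L
        else counts["fixed_unpolarized"] <- counts["fixed_unpolarized"] + 1L
      } else if (!is.null(io)) {
        counts["fixed_unpolarized"] <- counts["fixed_unpolarized"] + 1L
      }
    }
  }
  as.list(counts)
}
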