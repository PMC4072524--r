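#' Scan for single-outlier divergent regions in the donor-taxon panel
#'
#' In a highly selfing taxon most of the genome is near-identical across
#' samples; long regions where exactly one sample is sharply diverged from
#' all others carry either deep ancestral variation or material
#' introgressed from the outcrossing relative.  Windows in which one
#' sample exceeds `pi_threshold` pairwise divergence against every other
#' sample, while the others stay mutually below it, are merged into
#' regions; regions shorter than `region_bp` are dropped.
#'
#' @param panel a [genotype_panel()].
#' @param samples donor-taxon sample names (>= 3).
#' @param window_bp scan window (non-overlapping grid).
#' @param pi_threshold pairwise divergence defining "differs" (default 1
#'   percent).
#' @param region_bp minimum merged region length (default 20 kb).
#' @param min_sites minimum informative sites per window per pair; windows
#'   failing it for any pair are not classified.
#' @return data.frame of class `outlier_regions`: `chrom`, `start`,
#'   `end`, `length_bp`, `outlier`, `n_windows`.
#' @export
find_outlier_regions <- function(panel, samples, window_bp = 5000,
                                 pi_threshold = 0.01, region_bp = 2e4,
                                 min_sites = 100) {
  if (length(samples) < 3) stop("need at least 3 donor-taxon samples")
  pairs <- utils::combn(samples, 2)
  wp <- lapply(seq_len(ncol(pairs)), function(k)
    windowed_pi(panel, pairs[1, k], pairs[2, k],
                window_bp = window_bp, slide_bp = window_bp,
                min_sites = min_sites))
  nw <- nrow(wp[[1]])
  usable <- Reduce(`&`, lapply(wp, function(w) !w$insufficient))
  above <- vapply(wp, function(w) w$pi > pi_threshold, logical(nw))
  # outlier identity per window: the unique sample in every exceeding pair
  outlier <- rep(NA_character_, nw)
  for (i in which(usable)) {
    ex <- above[i, ]
    if (!any(ex)) next
    for (s in samples) {
      in_pair <- pairs[1, ] == s | pairs[2, ] == s
      if (all(ex[in_pair]) && !any(ex[!in_pair])) {
        outlier[i] <- s
        break
      }
    }
  }
  grid <- wp[[1]][c("chrom", "start", "end")]
  grid$outlier <- outlier
  out <- lapply(split(grid, grid$chrom), function(gr) {
    gr <- gr[order(gr$start), , drop = FALSE]
    key <- ifelse(is.na(gr$outlier), "<none>", gr$outlier)
    r <- rle(key)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    keep <- which(r$values != "<none>")
    if (!length(keep)) return(NULL)
    data.frame(chrom = gr$chrom[1],
               start = gr$start[starts_i[keep]],
               end = gr$end[ends_i[keep]],
               outlier = r$values[keep],
               n_windows = r$lengths[keep],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), outlier = character(0),
                      n_windows = integer(0))
  res$length_bp <- res$end - res$start
  res <- res[res$length_bp >= region_bp, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("outlier_regions", "data.frame")
  res
}

#' Test whether outlier regions trace to a candidate source population
#'
#' Under incomplete lineage sorting the outlier haplotype is closer to any
#' given relative's sample than the non-outliers are with probability 1/2;
#' under introgression from (a population close to) the candidate source
#' that probability exceeds 1/2.  For each region the outlier's divergence
#' to the source is compared with the non-outliers' divergence (their mean
#' by default, or every one of them under `comparison = "strict"`); ties
#' and regions without informative sites are dropped, and the k-of-n
#' successes are referred to an exact one-sided binomial tail at 1/2.
#'
#' @param regions an [find_outlier_regions()] table.
#' @param source candidate source sample name.
#' @param panel a [genotype_panel()].
#' @param samples the donor-taxon samples used in the scan.
#' @param comparison `"mean"` or `"strict"`.
#' @return list of class `outlier_test`: `k`, `n`, `p_value`.
#' @export
outlier_source_test <- function(regions, source, panel, samples,
                                comparison = c("mean", "strict")) {
  comparison <- match.arg(comparison)
  if (!nrow(regions)) stop("no outlier regions to test")
  closer <- rep(NA, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    out_s <- regions$outlier[i]
    others <- setdiff(samples, out_s)
    po <- pairwise_pi(panel, out_s, source, chrom = regions$chrom[i],
                      start = regions$start[i], end = regions$end[i])
    if (po$undefined) next
    pn <- vapply(others, function(s) {
      p <- pairwise_pi(panel, s, source, chrom = regions$chrom[i],
                       start = regions$start[i], end = regions$end[i])
      if (p$undefined) NA_real_ else p$pi
    }, numeric(1))
    if (anyNA(pn)) next
    ref <- if (comparison == "mean") mean(pn) else min(pn)
    if (po$pi == ref) next  # tie: dropped from n
    closer[i] <- po$pi < ref
  }
  k <- sum(closer, na.rm = TRUE)
  n <- sum(!is.na(closer))
  if (n == 0) stop("no informative outlier regions")
  structure(list(k = k, n = n,
                 p_value = binom_tail_geq(k, n, 0.5)),
            class = "outlier_test")
}

# Exact one-sided binomial tail P(X >= k), X ~ Binomial(n, p).
binom_tail_geq <- function(k, n, p) {
  pbinom(k - 1, n, p, lower.tail = FALSE)
}
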