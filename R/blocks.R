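#' Call admixture blocks from a posterior track
#'
#' Maximal runs of consecutive windows whose donor-ancestry posterior
#' exceeds `threshold` (default 0.95) are merged into blocks; block
#' coordinates are the union of the window spans.
#'
#' @param track a [forward_backward()] posterior track.
#' @param threshold posterior cutoff.
#' @return data.frame of class `ancestry_blocks`: `chrom`, `start`,
#'   `end`, `length_bp`, `n_windows`, `mean_posterior`.
#' @export
call_blocks <- function(track, threshold = 0.95) {
  window_bp <- attr(track, "window_bp")
  out <- lapply(split(track, track$chrom), function(tr) {
    tr <- tr[order(tr$start), , drop = FALSE]
    hi <- tr$post_donor > threshold
    if (!any(hi)) return(NULL)
    r <- rle(hi)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    keep <- which(r$values)
    data.frame(chrom = tr$chrom[1],
               start = tr$start[starts_i[keep]],
               end = tr$end[ends_i[keep]],
               n_windows = r$lengths[keep],
               mean_posterior = vapply(keep, function(j)
                 mean(tr$post_donor[starts_i[j]:ends_i[j]]), numeric(1)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      mean_posterior = numeric(0))
  res$length_bp <- res$end - res$start
  rownames(res) <- NULL
  attr(res, "window_bp") <- window_bp
  class(res) <- c("ancestry_blocks", "data.frame")
  res
}

#' Heal nearby blocks into longer blocks
#'
#' Ancestry callers occasionally break a contiguous admixture tract; this
#' merges successive blocks on the same chromosome whose gap is at most
#' `gap_bp` (transitively).  By default the healed length spans the merged
#' extent including the gaps ("one longer block"); `length_mode = "sum"`
#' instead sums the member lengths.
#'
#' @param blocks an [call_blocks()] table.
#' @param gap_bp maximum gap to bridge (0 returns the input).
#' @param length_mode `"extent"` or `"sum"`.
#' @return A healed `ancestry_blocks` table.
#' @export
heal_blocks <- function(blocks, gap_bp = 0, length_mode = c("extent", "sum")) {
  length_mode <- match.arg(length_mode)
  if (gap_bp <= 0 || nrow(blocks) == 0) return(blocks)
  out <- lapply(split(blocks, blocks$chrom), function(bl) {
    bl <- bl[order(bl$start), , drop = FALSE]
    gap <- c(Inf, bl$start[-1] - bl$end[-nrow(bl)])
    grp <- cumsum(gap > gap_bp)
    data.frame(chrom = bl$chrom[1],
               start = tapply(bl$start, grp, min),
               end = tapply(bl$end, grp, max),
               n_windows = as.integer(tapply(bl$n_windows, grp, sum)),
               mean_posterior = as.numeric(
                 tapply(bl$mean_posterior * bl$n_windows, grp, sum) /
                   tapply(bl$n_windows, grp, sum)),
               length_sum = as.numeric(tapply(bl$length_bp, grp, sum)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$length_bp <- if (length_mode == "extent") res$end - res$start
                   else res$length_sum
  res$length_sum <- NULL
  rownames(res) <- NULL
  attr(res, "window_bp") <- attr(blocks, "window_bp")
  class(res) <- c("ancestry_blocks", "data.frame")
  res
}

#' Convert physical block length to map length
#'
#' Linear conversion assuming a uniform genome-wide recombination rate:
#' `cM = length_bp * map_length_cm / genome_bp` (defaults: a 1,470 cM map
#' over a 2.6e8 bp genome).
#'
#' @param length_bp block length(s) in bp.
#' @param map_length_cm total map length in cM.
#' @param genome_bp total genome size in bp.
#' @return length(s) in cM.
#' @export
block_length_cm <- function(length_bp, map_length_cm = 1470,
                            genome_bp = 2.6e8) {
  stopifnot(map_length_cm > 0, genome_bp > 0)
  length_bp * map_length_cm / genome_bp
}

#' Mean block length in Morgans, corrected for window quantization
#'
#' A tract caller working on a fixed window grid reports the union of all
#' windows overlapping a tract, which overshoots the true tract length by
#' about one window (half a window at each end).  For tracts much longer
#' than the window the overshoot is negligible, but when the mean tract
#' spans only tens of windows it biases the tract-length clock downward;
#' subtracting one window (floored at half a window) removes most of the
#' bias.
#'
#' @param blocks an [call_blocks()] table.
#' @param morgans_per_bp uniform map density (total Morgans / genome bp),
#'   or `NULL` to return bp instead of Morgans.
#' @param quantization_bp window size to subtract (default: the calling
#'   window recorded on `blocks`; use 0 to disable the correction).
#' @return mean corrected block length (Morgans, or bp if
#'   `morgans_per_bp` is `NULL`).
#' @export
block_mean_length <- function(blocks, morgans_per_bp = NULL,
                              quantization_bp = attr(blocks, "window_bp")) {
  if (nrow(blocks) == 0) stop("no blocks")
  if (is.null(quantization_bp)) quantization_bp <- 0
  len <- pmax(blocks$length_bp - quantization_bp, quantization_bp / 2)
  if (is.null(morgans_per_bp)) mean(len) else mean(len * morgans_per_bp)
}

#' Generations since an admixture pulse
#'
#' Under a single pulse, admixture tract lengths are exponential with a
#' mean (in Morgans) equal to the reciprocal of the age of the pulse in
#' generations: `T = 1 / mean_length_morgans`.
#'
#' @param mean_length_morgans mean tract length in Morgans (> 0).
#' @return generations since the pulse.
#' @export
generations_since_pulse <- function(mean_length_morgans) {
  if (any(mean_length_morgans <= 0)) stop("mean length must be positive")
  1 / mean_length_morgans
}

#' Bootstrap test of the single-pulse (exponential) block-length model
#'
#' Recombination thins tracts as a Poisson process, so a single pulse
#' predicts exponential tract lengths whose variance equals the squared
#' mean.  Blocks are resampled with replacement `n_boot` times; the
#' reported one-sided p-value is the proportion of resamples in which the
#' squared mean exceeds the variance.  Small p indicates overdispersion
#' (variance persistently above the squared mean), as expected under
#' ongoing or multi-pulse gene flow.
#'
#' @param lengths block lengths (Morgan scale recommended; any linear
#'   scale works since the statistic compares mean^2 with the variance).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return list: `p_value`, `mean`, `sd`, `n_blocks`.
#' @export
pulse_dispersion_test <- function(lengths, n_boot = 1000, seed = 1) {
  if (length(lengths) < 2) stop("need at least two blocks")
  stat <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      x <- sample(lengths, replace = TRUE)
      mean(x)^2 > var(x)
    }, logical(1))
  })
  list(p_value = mean(stat), mean = mean(lengths), sd = sd(lengths),
       n_blocks = length(lengths))
}

#' Expected chunk count of a present-day genome, v generations back
#'
#' Looking `v` generations into the past, a genome is broken into
#' `X = v * L + C` chunks: one per recombination event (map length `L`
#' Morgans per generation) plus one per chromosome (`C`).  These chunks
#' are spread over `2^v` genealogical ancestors, so the expected number of
#' segments inherited from any one ancestor is `X / 2^v`, reported in
#' log2 space (`log2(X) - v`) because `2^v` overflows doubles for
#' realistic `v`.
#'
#' @param v generations (>= 0).
#' @param L map length in Morgans.
#' @param C chromosome count.
#' @return list of class `chunk_model`: `v`, `L`, `C`, `X`,
#'   `log2_segments_per_ancestor`.
#' @export
genome_chunks <- function(v, L = 14.7, C = 14) {
  if (v < 0) stop("v must be non-negative")
  X <- v * L + C
  structure(list(v = v, L = L, C = C, X = X,
                 log2_segments_per_ancestor = log2(X) - v),
            class = "chunk_model")
}

#' Summarise blocks in the style of an admixture-history table
#'
#' One row per healing rule: block count, total length, mean and SD length
#' in cM, the implied generations since admixture, the dispersion-test
#' p-value, and the log2 probability scale of per-ancestor inheritance.
#'
#' @param blocks an [call_blocks()] table.
#' @param gaps_bp healing gaps to tabulate.
#' @param map_length_cm,genome_bp linear map conversion.
#' @param n_boot,seed dispersion-test settings.
#' @return data.frame, one row per healing gap.
#' @export
block_summary <- function(blocks, gaps_bp = c(0, 2e4, 5e4, 1e5),
                          map_length_cm = 1470, genome_bp = 2.6e8,
                          n_boot = 1000, seed = 1) {
  rows <- lapply(gaps_bp, function(g) {
    bl <- heal_blocks(blocks, g)
    if (nrow(bl) < 2)
      return(data.frame(heal_gap_bp = g, n_blocks = nrow(bl),
                        total_kb = sum(bl$length_bp) / 1e3,
                        mean_cm = NA, sd_cm = NA, T_generations = NA,
                        p_exp = NA, log2_per_ancestor = NA))
    cm <- block_length_cm(bl$length_bp, map_length_cm, genome_bp)
    Tg <- generations_since_pulse(mean(cm) / 100)
    disp <- pulse_dispersion_test(cm / 100, n_boot = n_boot, seed = seed)
    ch <- genome_chunks(Tg, L = map_length_cm / 100, C = 14)
    data.frame(heal_gap_bp = g, n_blocks = nrow(bl),
               total_kb = sum(bl$length_bp) / 1e3,
               mean_cm = mean(cm), sd_cm = sd(cm), T_generations = Tg,
               p_exp = disp$p_value,
               log2_per_ancestor = ch$log2_segments_per_ancestor)
  })
  do.call(rbind, rows)
}
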