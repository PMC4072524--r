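#' Windowed local recombination rates from a genetic map
#'
#' The raw rate of a window is the interpolated cM distance across it over
#' its length; the smoothed rate is the mean raw rate over all windows
#' intersecting the surrounding `smooth_bp` span (edge windows use the
#' neighbours that exist).  Windows outside the map's marker coverage are
#' excluded.
#'
#' @param map a [genetic_map()].
#' @param window_bp window length (default 100 kb).
#' @param smooth_bp smoothing span centred on the window (default 500 kb).
#' @return data.frame of class `recomb_windows`: `chrom`, `start`, `end`,
#'   `rate_cm_mb`, `smoothed_cm_mb`.
#' @export
window_recomb_rates <- function(map, window_bp = 1e5, smooth_bp = 5e5) {
  out <- lapply(unique(map$chrom), function(ch) {
    m <- map[map$chrom == ch, , drop = FALSE]
    lo <- min(m$bp); hi <- max(m$bp)
    if (hi - lo < window_bp) return(NULL)
    starts <- seq(ceiling(lo / window_bp) * window_bp, hi - window_bp,
                  by = window_bp)
    if (!length(starts)) return(NULL)
    ends <- starts + window_bp
    cm <- interpolate_cm(map, ch, c(starts, ends))
    ns <- length(starts)
    raw <- (cm[ns + seq_len(ns)] - cm[seq_len(ns)]) / (window_bp / 1e6)
    half <- floor(smooth_bp / window_bp / 2)
    sm <- vapply(seq_len(ns), function(i) {
      j <- max(1, i - half):min(ns, i + half)
      mean(raw[j])
    }, numeric(1))
    data.frame(chrom = ch, start = starts, end = ends,
               rate_cm_mb = raw, smoothed_cm_mb = sm,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("map covers no full window on any chromosome")
  rownames(res) <- NULL
  class(res) <- c("recomb_windows", "data.frame")
  res
}

#' Correlation between windowed divergence and recombination rate
#'
#' Joins windowed diversity/divergence statistics to windowed
#' recombination rates by coordinates and reports Spearman's rank
#' correlation.  Windows with fewer than `min_comparisons` informative
#' pairwise comparisons, or without a recombination estimate, are
#' excluded.
#'
#' @param window_stats a [windowed_pi()] table on the same window grid as
#'   `rates` (same `window_bp`, slide equal to the window).
#' @param rates an [window_recomb_rates()] table.
#' @param min_comparisons minimum `n_sites` per window (default 100).
#' @param use_smoothed correlate against the smoothed rate (default TRUE).
#' @return list of class `correlation_result`: `rho`, `p_value`, `n`.
#' @export
divergence_recomb_correlation <- function(window_stats, rates,
                                          min_comparisons = 100,
                                          use_smoothed = TRUE) {
  j <- join_windows(window_stats, rates, min_comparisons)
  if (nrow(j) < 10) stop("fewer than 10 joined windows")
  rate <- if (use_smoothed) j$smoothed_cm_mb else j$rate_cm_mb
  ct <- suppressWarnings(cor.test(j$pi, rate, method = "spearman",
                                  exact = FALSE))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(j)),
            class = "correlation_result")
}

join_windows <- function(window_stats, rates, min_comparisons) {
  ws <- window_stats[!is.na(window_stats$pi) &
                       window_stats$n_sites >= min_comparisons, , drop = FALSE]
  key_w <- paste(ws$chrom, ws$start)
  key_r <- paste(rates$chrom, rates$start)
  m <- match(key_w, key_r)
  cbind(ws[!is.na(m), , drop = FALSE],
        rates[m[!is.na(m)], c("rate_cm_mb", "smoothed_cm_mb"), drop = FALSE])
}

#' Covariate-controlled rank correlation
#'
#' Checks that a divergence-recombination correlation is not driven by a
#' confounder (outgroup divergence as a mutation-rate proxy, or mean
#' sequencing depth): both variables are rank-transformed, rank-regressed
#' on the covariate's ranks, and the Spearman correlation is recomputed on
#' the residuals; a stratified version (correlation within covariate
#' quartiles, sample-size-weighted) is reported alongside.  A constant
#' covariate falls back to the plain correlation with a note.
#'
#' @param window_stats,rates as in [divergence_recomb_correlation()].
#' @param covariates data.frame of per-window covariates with `chrom` and
#'   `start` columns plus one column per covariate.
#' @param min_comparisons minimum informative comparisons per window.
#' @param use_smoothed correlate against the smoothed rate.
#' @return named list (one entry per covariate) of lists:
#'   `residualized` and `stratified` `correlation_result`s, and `note`.
#' @export
covariate_check <- function(window_stats, rates, covariates,
                            min_comparisons = 100, use_smoothed = TRUE) {
  j <- join_windows(window_stats, rates, min_comparisons)
  if (nrow(j) < 10) stop("fewer than 10 joined windows")
  key_j <- paste(j$chrom, j$start)
  key_c <- paste(covariates$chrom, covariates$start)
  m <- match(key_j, key_c)
  j <- j[!is.na(m), , drop = FALSE]
  cov_df <- covariates[m[!is.na(m)], , drop = FALSE]
  rate <- if (use_smoothed) j$smoothed_cm_mb else j$rate_cm_mb
  cov_names <- setdiff(names(covariates), c("chrom", "start", "end"))
  out <- lapply(cov_names, function(cn) {
    cv <- cov_df[[cn]]
    ok <- !is.na(cv)
    x <- j$pi[ok]; y <- rate[ok]; cv <- cv[ok]
    if (length(unique(cv)) < 2) {
      ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
      return(list(residualized = structure(
        list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x)),
        class = "correlation_result"),
        stratified = NULL,
        note = "constant covariate; plain correlation reported"))
    }
    rx <- rank(x); ry <- rank(y); rc <- rank(cv)
    ex <- residuals(lm(rx ~ rc))
    ey <- residuals(lm(ry ~ rc))
    ct <- suppressWarnings(cor.test(ex, ey, method = "spearman", exact = FALSE))
    res <- structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                          n = length(ex)), class = "correlation_result")
    qs <- cut(cv, breaks = quantile(cv, probs = seq(0, 1, 0.25)),
              include.lowest = TRUE, labels = FALSE)
    per <- lapply(sort(unique(qs)), function(q) {
      xi <- x[qs == q]; yi <- y[qs == q]
      if (length(xi) < 5) return(NULL)
      cti <- suppressWarnings(cor.test(xi, yi, method = "spearman",
                                       exact = FALSE))
      list(rho = unname(cti$estimate), n = length(xi))
    })
    per <- per[!vapply(per, is.null, logical(1))]
    wsum <- sum(vapply(per, `[[`, numeric(1), "n"))
    rho_strat <- sum(vapply(per, function(p) p$rho * p$n, numeric(1))) / wsum
    strat <- structure(list(rho = rho_strat, p_value = NA_real_, n = wsum),
                       class = "correlation_result")
    list(residualized = res, stratified = strat, note = NULL)
  })
  names(out) <- cov_names
  out
}
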