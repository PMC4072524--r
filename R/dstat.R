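#' Four-population D statistic
#'
#' Frequency-based D over aligned biallelic sites for populations Y
#' (sympatric recipient), Z (allopatric recipient close to Y), W (donor
#' taxon) and X (distant allopatric recipient):
#' `D = sum_i (y_i - z_i)(w_i - x_i) / sum_i (y_i + z_i - 2 y_i z_i)(w_i + x_i - 2 w_i x_i)`.
#' Excess derived-allele sharing between Y and W gives D > 0.  Sites with
#' any undefined frequency are skipped.
#'
#' @param y,z,w,x per-site sample allele frequencies (equal length, same
#'   allele orientation per site; orientation itself cancels).
#' @return list of class `dstat_result`: `D`, `n_sites_used`, plus the
#'   per-site `numerator`/`denominator` terms for block jackknifing.
#'   `D` is `NA` with `undefined = TRUE` when the denominator sums to 0.
#' @export
d_statistic <- function(y, z, w, x) {
  stopifnot(length(y) == length(z), length(y) == length(w),
            length(y) == length(x))
  ok <- !(is.na(y) | is.na(z) | is.na(w) | is.na(x))
  num <- (y - z) * (w - x)
  den <- (y + z - 2 * y * z) * (w + x - 2 * w * x)
  num[!ok] <- NA; den[!ok] <- NA
  sden <- sum(den, na.rm = TRUE)
  structure(list(D = if (sden != 0) sum(num, na.rm = TRUE) / sden else NA_real_,
                 undefined = sden == 0,
                 n_sites_used = sum(ok),
                 numerator = num, denominator = den),
            class = "dstat_result")
}

#' Delete-one-chromosome block jackknife for a ratio statistic
#'
#' Linked sites violate the independence behind naive standard errors, so
#' significance is evaluated by deleting one whole chromosome at a time
#' and recomputing the ratio.  Blocks of unequal size are handled with the
#' weighted jackknife (Busing et al. 1999): with `g` blocks, block sizes
#' `m_j`, total `n`, full estimate `theta`, and leave-one-out estimates
#' `theta_{-j}`,
#' `theta_J = g theta - sum_j (1 - m_j/n) theta_{-j}` and
#' `var = (1/g) sum_j (ps_j - theta_J)^2 / (h_j - 1)` with `h_j = n/m_j`
#' and pseudovalues `ps_j = h_j theta - (h_j - 1) theta_{-j}`.
#'
#' @param numerator,denominator per-site terms (e.g. from
#'   [d_statistic()]); `NA` terms are dropped.
#' @param chrom per-site chromosome labels (>= 3 distinct).
#' @return list of class `dstat_result`: `D`, `se`, `Z`,
#'   `leave_one_out` (named per-chromosome estimates), `n_blocks`.
#' @export
block_jackknife <- function(numerator, denominator, chrom) {
  ok <- !(is.na(numerator) | is.na(denominator))
  numerator <- numerator[ok]; denominator <- denominator[ok]
  chrom <- as.character(chrom)[ok]
  blocks <- unique(chrom)
  g <- length(blocks)
  if (g < 3) stop("block jackknife needs at least 3 chromosomes")
  sn <- sum(numerator); sd_ <- sum(denominator)
  if (sd_ == 0) stop("denominator sums to zero")
  theta <- sn / sd_
  m <- as.numeric(table(chrom)[blocks])
  n <- sum(m)
  loo <- vapply(blocks, function(b) {
    inb <- chrom == b
    (sn - sum(numerator[inb])) / (sd_ - sum(denominator[inb]))
  }, numeric(1))
  h <- n / m
  theta_j <- g * theta - sum((1 - m / n) * loo)
  ps <- h * theta - (h - 1) * loo
  v <- sum((ps - theta_j)^2 / (h - 1)) / g
  se <- sqrt(v)
  structure(list(D = theta, se = se,
                 Z = if (se > 0) theta / se else Inf * sign(theta),
                 leave_one_out = loo, n_blocks = g),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D = %.4f", x$D))
  if (!is.null(x$se)) cat(sprintf("  SE = %.4f  Z = %.2f", x$se, x$Z))
  cat("\n")
  invisible(x)
}

# Per-site sample allele frequencies of the alternate allele over a set of
# samples (NA when no sample has a call).
panel_freqs <- function(panel, samples) {
  g <- panel$geno[, sample_index(panel, samples), drop = FALSE]
  called <- rowSums(!is.na(g))
  alt <- rowSums(g == 1L, na.rm = TRUE)
  ifelse(called > 0, alt / called, NA_real_)
}

#' Four-population D test from a genotype panel
#'
#' Computes sample allele frequencies per population, the D statistic,
#' and its delete-one-chromosome jackknife standard error.
#'
#' @param panel a biallelic [genotype_panel()].
#' @param Y,Z,W,X character vectors of sample names per population.
#' @return A `dstat_result` with jackknife `se` and `Z`.
#' @export
d_test <- function(panel, Y, Z, W, X) {
  y <- panel_freqs(panel, Y); z <- panel_freqs(panel, Z)
  w <- panel_freqs(panel, W); x <- panel_freqs(panel, X)
  d <- d_statistic(y, z, w, x)
  block_jackknife(d$numerator, d$denominator, panel$sites$chrom)
}
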