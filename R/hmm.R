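#' Windowed minimum-divergence emissions
#'
#' For a focal sample, computes in non-overlapping windows (default 1 kb)
#' the number of informative sites and the mismatch count against each
#' donor-panel sample, keeping the donor with the smallest mismatch
#' proportion -- the windowed minimum pairwise divergence to the donor
#' panel that the ancestry HMM takes as its observation.
#'
#' @param panel a [genotype_panel()].
#' @param focal focal sample name.
#' @param donors character vector of donor-panel sample names (>= 1).
#' @param window_bp window length (non-overlapping grid anchored at 0).
#' @param site_class optional degeneracy class restriction (panel-callable
#'   panels only).
#' @return data.frame of class `emission_windows`: `chrom`, `start`,
#'   `end`, `n_sites`, `k_min`, `closest`, `missing` (no co-called site;
#'   such windows are flagged, never treated as zero divergence).
#' @export
compute_emission_windows <- function(panel, focal, donors, window_bp = 1000,
                                     site_class = NULL) {
  if (length(donors) < 1) stop("need at least one donor")
  ifo <- sample_index(panel, focal)
  ido <- sample_index(panel, donors)
  mask <- site_class_mask(panel, site_class)
  if (panel$callable == "genome" && !is.null(site_class))
    stop("site_class is not defined for genome-callable panels")
  lens <- panel_chrom_lengths(panel)
  gfo <- panel$geno[, ifo]
  chrom <- panel$sites$chrom
  win_of <- panel$sites$pos %/% window_bp + 1L
  idx_by_chrom <- split(seq_len(n_sites(panel)), chrom)
  called_l <- vector("list", length(donors))
  diff_l <- vector("list", length(donors))
  for (d in seq_along(donors)) {
    gd <- panel$geno[, ido[d]]
    called_l[[d]] <- mask & !is.na(gfo) & !is.na(gd)
    diff_l[[d]] <- called_l[[d]] & gfo != gd
  }

  out <- lapply(names(lens), function(ch) {
    L <- lens[[ch]]
    nw <- ceiling(L / window_bp)
    starts <- (seq_len(nw) - 1L) * window_bp
    ends <- pmin(starts + window_bp, L)
    idx <- idx_by_chrom[[ch]]
    wi <- win_of[idx]
    k <- matrix(0L, nw, length(donors))
    n <- matrix(0L, nw, length(donors))
    for (d in seq_along(donors)) {
      k[, d] <- tabulate(wi[diff_l[[d]][idx]], nbins = nw)
      n[, d] <- if (panel$callable == "genome") ends - starts
                else tabulate(wi[called_l[[d]][idx]], nbins = nw)
    }
    p <- ifelse(n > 0, k / n, Inf)
    best <- max.col(-p, ties.method = "first")
    pick <- cbind(seq_len(nw), best)
    miss <- rowSums(n > 0) == 0L
    data.frame(chrom = ch, start = starts, end = ends,
               n_sites = ifelse(miss, 0L, n[pick]),
               k_min = ifelse(miss, NA_integer_, k[pick]),
               closest = ifelse(miss, NA_character_, donors[best]),
               missing = miss, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "window_bp") <- window_bp
  class(res) <- c("emission_windows", "data.frame")
  res
}

# Adjust a vector of per-window minimum divergences taken over m_ref
# comparisons so that it emulates minima over m comparisons: each draw
# takes the minimum of a random number of resampled values with expected
# total comparisons m.  No-op when m <= m_ref.
adjust_min_of_m <- function(p, m_ref, m, n_draws, seed) {
  if (is.null(m) || is.null(m_ref) || m <= m_ref) return(p)
  extra_prob <- (m - m_ref) / m_ref
  with_seed(seed, {
    base <- sample(p, n_draws, replace = TRUE)
    extra <- sample(p, n_draws, replace = TRUE)
    take_extra <- runif(n_draws) < extra_prob
    ifelse(take_extra, pmin(base, extra), base)
  })
}

#' Build the two-state emission model
#'
#' The emission probability of an observed (mismatches `k`, informative
#' sites `n`) pair under each ancestry state is a binomial mixture over a
#' weighted histogram of per-site mismatch probabilities taken from
#' genome-wide reference distributions: windows between donor-taxon
#' samples and their closest donor (the donor-ancestry state) and windows
#' between recipient-taxon samples and their closest donor (the
#' recipient-ancestry state).  The histogram construction absorbs the
#' genome-wide heterogeneity in informative-site density; the binomial
#' absorbs the per-window site count.  When the reference minima were
#' taken over fewer donor comparisons than the focal sample's `m`, the
#' reference distribution is resampled to min-of-`m` draws.
#'
#' @param donor_ref,recipient_ref [compute_emission_windows()] tables
#'   providing the reference distributions for the two states.
#' @param m number of donor comparisons the focal minima are taken over.
#' @param m_ref_donor,m_ref_recipient comparisons behind each reference
#'   distribution (defaults: `m`, i.e. no adjustment).
#' @param n_bins histogram bins (default 50).
#' @param pseudocount added to every bin to avoid zero likelihoods.
#' @param resample_draws draws for the min-of-m resampling.
#' @param seed seed for the resampling.
#' @return list of class `emission_model`: `mids`, `w_recipient`,
#'   `w_donor` (weights summing to 1 per state).
#' @export
build_emission_model <- function(donor_ref, recipient_ref, m = NULL,
                                 m_ref_donor = m, m_ref_recipient = m,
                                 n_bins = 50, pseudocount = 0.5,
                                 resample_draws = 10000, seed = 1) {
  pd <- with(donor_ref[!donor_ref$missing & donor_ref$n_sites > 0, ],
             k_min / n_sites)
  pr <- with(recipient_ref[!recipient_ref$missing & recipient_ref$n_sites > 0, ],
             k_min / n_sites)
  if (!length(pd) || !length(pr))
    stop("empty reference distribution for the emission model")
  pd <- adjust_min_of_m(pd, m_ref_donor, m, resample_draws, derive_seed(seed, 11L))
  pr <- adjust_min_of_m(pr, m_ref_recipient, m, resample_draws, derive_seed(seed, 12L))
  top <- max(pd, pr, 1e-6) * (1 + 1e-9)
  breaks <- seq(0, top, length.out = n_bins + 1)
  wts <- function(p) {
    h <- tabulate(findInterval(p, breaks, rightmost.closed = TRUE),
                  nbins = n_bins) + pseudocount
    h / sum(h)
  }
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 w_donor = wts(pd), w_recipient = wts(pr), m = m),
            class = "emission_model")
}

# T x 2 matrix of emission likelihoods (col 1 recipient, col 2 donor);
# missing windows emit likelihood 1 in both states.
emission_matrix <- function(windows, model) {
  T_ <- nrow(windows)
  E <- matrix(1, T_, 2)
  obs <- which(!windows$missing & windows$n_sites > 0)
  if (!length(obs)) return(E)
  k <- windows$k_min[obs]; n <- windows$n_sites[obs]
  B <- length(model$mids)
  lik <- matrix(0, length(obs), B)
  for (b in seq_len(B)) lik[, b] <- dbinom(k, n, model$mids[b])
  E[obs, 1] <- as.numeric(lik %*% model$w_recipient)
  E[obs, 2] <- as.numeric(lik %*% model$w_donor)
  E
}

#' HMM parameters
#'
#' `alpha` is the admixture proportion; `r` the per-window recombination
#' probability times generations since admixture.  Transitions between the
#' recipient (state 1) and donor (state 2) ancestry states are
#' `t[1,1] = (1-r) + r(1-alpha)`, `t[1,2] = r alpha`,
#' `t[2,1] = r(1-alpha)`, `t[2,2] = (1-r) + r alpha`; the stationary
#' distribution is `(1-alpha, alpha)`, also used as the initial
#' distribution.
#'
#' @param alpha,r both in `[0, 1]`.
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(alpha, r) {
  if (alpha < 0 || alpha > 1 || r < 0 || r > 1)
    stop("alpha and r must lie in [0, 1]")
  structure(list(alpha = alpha, r = r), class = "hmm_params")
}

#' @rdname hmm_params
#' @return `transition_matrix`: the 2 x 2 row-stochastic matrix above.
#' @export
transition_matrix <- function(alpha, r) {
  if (alpha < 0 || alpha > 1 || r < 0 || r > 1)
    stop("alpha and r must lie in [0, 1]")
  matrix(c((1 - r) + r * (1 - alpha), r * alpha,
           r * (1 - alpha), (1 - r) + r * alpha),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("recipient", "donor"), c("recipient", "donor")))
}

#' Forward-backward posterior decoding
#'
#' Runs the scaled forward-backward recursions over each chromosome as an
#' independent chain and returns the per-window posterior probability of
#' donor ancestry together with the total log-likelihood.  Missing
#' windows emit likelihood 1 in both states while the transition step
#' still advances one window, preserving genome geometry under the
#' constant-per-window recombination assumption.
#'
#' @param windows an [compute_emission_windows()] table.
#' @param model an [build_emission_model()] model.
#' @param params an [hmm_params()].
#' @return data.frame of class `posterior_track` (`chrom`, `start`, `end`,
#'   `post_donor`) with attributes `loglik` and `window_bp`.
#' @export
forward_backward <- function(windows, model, params) {
  trans <- transition_matrix(params$alpha, params$r)
  init <- c(1 - params$alpha, params$alpha)
  loglik <- 0
  out <- lapply(split(seq_len(nrow(windows)), windows$chrom), function(idx) {
    w <- windows[idx, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    if (all(w$missing))
      warning("chromosome ", w$chrom[1],
              " has no informative window; posteriors are the stationary distribution")
    E <- emission_matrix(w, model)
    fb <- fb_chain(E, trans, init)
    loglik <<- loglik + fb$loglik
    data.frame(chrom = w$chrom, start = w$start, end = w$end,
               post_donor = fb$posterior[, 2], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "loglik") <- loglik
  attr(res, "window_bp") <- attr(windows, "window_bp")
  class(res) <- c("posterior_track", "data.frame")
  res
}

#' Fit the ancestry HMM by maximum likelihood
#'
#' Maximises the forward log-likelihood over `(alpha, r)` with Nelder-Mead
#' on the logit scale (so the search is unconstrained), restarting from a
#' spread of initial points and keeping the best optimum.  The fitted
#' log-likelihood never falls below the initial one.
#'
#' @param windows an [compute_emission_windows()] table.
#' @param model an [build_emission_model()] model.
#' @param init an [hmm_params()] starting point.
#' @param n_restarts number of spread restarts in addition to `init`.
#' @param reltol convergence tolerance on the log-likelihood.
#' @return list: `params` (fitted [hmm_params()]), `loglik`,
#'   `init_loglik`, `converged`, and `track`, the posterior decoding at
#'   the optimum.
#' @export
fit_hmm <- function(windows, model, init = hmm_params(0.1, 0.1),
                    n_restarts = 5, reltol = 1e-8) {
  chains <- lapply(split(seq_len(nrow(windows)), windows$chrom), function(idx) {
    w <- windows[idx, , drop = FALSE]
    emission_matrix(w[order(w$start), , drop = FALSE], model)
  })
  negll <- function(par) {
    alpha <- inv_logit(par[1]); r <- inv_logit(par[2])
    trans <- transition_matrix(alpha, r)
    init_d <- c(1 - alpha, alpha)
    -sum(vapply(chains, forward_loglik, numeric(1),
                trans = trans, init = init_d))
  }
  starts <- list(c(logit(init$alpha), logit(init$r)))
  spread <- list(c(0.02, 0.02), c(0.1, 0.3), c(0.3, 0.05),
                 c(0.5, 0.5), c(0.05, 0.8))
  for (s in spread[seq_len(min(n_restarts, length(spread)))])
    starts <- c(starts, list(logit(s)))
  best <- NULL
  converged <- FALSE
  for (st in starts) {
    fit <- optim(st, negll, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = 500))
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- fit$convergence == 0
    }
  }
  init_loglik <- -negll(starts[[1]])
  loglik <- -best$value
  if (loglik < init_loglik) {  # optimizer contract: never worse than init
    best$par <- starts[[1]]
    loglik <- init_loglik
  }
  params <- hmm_params(inv_logit(best$par[1]), inv_logit(best$par[2]))
  list(params = params, loglik = loglik, init_loglik = init_loglik,
       converged = converged,
       track = forward_backward(windows, model, params))
}

#' Genome-wide admixture fraction from a posterior track
#'
#' @param track a [forward_backward()] posterior track.
#' @param mode `"posterior"` for the posterior-weighted mean donor
#'   ancestry, `"threshold"` for the fraction of windows whose donor
#'   posterior exceeds `threshold` (with `threshold = 0.5` this is the
#'   majority vote of the decoded states).
#' @param threshold cutoff for `"threshold"` mode.
#' @return fraction in `[0, 1]`.
#' @export
admixture_fraction <- function(track, mode = c("posterior", "threshold"),
                               threshold = 0.5) {
  mode <- match.arg(mode)
  if (!nrow(track)) stop("empty posterior track")
  if (mode == "posterior") mean(track$post_donor)
  else mean(track$post_donor > threshold)
}
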