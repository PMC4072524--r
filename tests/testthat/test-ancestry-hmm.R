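# Shared small mosaic dataset: study-like separation (pi_between /
# pi_within > 10) on a 6 Mb genome so blocks span many 1 kb windows.
hmm_dataset <- function(seed = 11, genome_bp = 6e6) {
  cfg <- sim_config(genome_bp = genome_bp, n_chromosomes = 4,
                    map_length_morgans = 14.7 * genome_bp / 3e7,
                    seed = seed)
  ds <- simulate_dataset(cfg)
  ew <- compute_emission_windows(ds$panel, "ADM1", ds$roles$donor)
  dref <- do.call(rbind, lapply(ds$roles$donor, function(d)
    compute_emission_windows(ds$panel, d, setdiff(ds$roles$donor, d))))
  rref <- do.call(rbind, lapply(ds$roles$recipient, function(s)
    compute_emission_windows(ds$panel, s, ds$roles$donor)))
  attr(dref, "window_bp") <- 1000
  attr(rref, "window_bp") <- 1000
  model <- build_emission_model(dref, rref, m = 4, m_ref_donor = 3,
                                m_ref_recipient = 4, seed = 1)
  list(ds = ds, ew = ew, model = model)
}

test_that("emission windows record minima and flag empty windows", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 300L, 1500L),
                      ref = "A", alt = "T")
  #          focal d1  d2  d3
  g <- rbind(c(1L, 1L, 0L, 0L),
             c(0L, 1L, 1L, 0L),
             c(1L, 0L, 1L, NA))
  panel <- genotype_panel(sites, g, c("f", "d1", "d2", "d3"))
  ew <- compute_emission_windows(panel, "f", c("d1", "d2", "d3"),
                                 window_bp = 1000)
  # window 1: mismatches f-d1 = 1 (site2), f-d2 = 2, f-d3 = 1 over n = 2
  w1 <- ew[ew$start == 0, ]
  expect_equal(w1$k_min, 1L)
  expect_true(w1$closest %in% c("d1", "d3"))
  # window 2: d3 has no call -> minimum over d1 (k=1), d2 (k=0)
  w2 <- ew[ew$start == 1000, ]
  expect_equal(w2$k_min, 0L)
  expect_equal(w2$closest, "d2")
  # identical focal and donor: k_min = 0
  same <- panel
  same$geno[, "d2"] <- same$geno[, "f"]
  expect_equal(compute_emission_windows(same, "f", "d2")$k_min[1], 0L)
  # a window with no co-called site is missing, not zero
  gap <- genotype_panel(sites, rbind(c(1L, NA), c(0L, NA), c(1L, 0L)),
                        c("f", "d1"))
  ewg <- compute_emission_windows(gap, "f", "d1", window_bp = 1000)
  expect_true(ewg$missing[1])
  expect_false(ewg$missing[2])
})

test_that("emission likelihoods normalise and separate the states", {
  fx <- hmm_dataset()
  model <- fx$model
  # sum over all k of P(k | n, state) is 1 for both states
  n <- 200
  E <- selfmix:::emission_matrix(
    data.frame(missing = FALSE, n_sites = n, k_min = 0:n), model)
  expect_equal(colSums(E), c(1, 1), tolerance = 1e-9)
  # a window at the donor-state mode beats the recipient state and
  # vice versa
  don_mode <- round(2 * 0.003 * 1000)
  rec_mode <- round((0.04 + 2 * 0.003) * 1000)
  Em <- selfmix:::emission_matrix(
    data.frame(missing = FALSE, n_sites = 1000,
               k_min = c(don_mode, rec_mode)), model)
  expect_gt(Em[1, 2], Em[1, 1])
  expect_gt(Em[2, 1], Em[2, 2])
})

test_that("emission-only classification exceeds 90% on pure windows", {
  fx <- hmm_dataset()
  ds <- fx$ds
  # donor-vs-donor windows are donor-state draws; recipient-vs-donor
  # windows are recipient-state draws
  dref <- compute_emission_windows(ds$panel, "DON1", c("DON2", "DON3", "DON4"))
  rref <- compute_emission_windows(ds$panel, "REC1", ds$roles$donor)
  lik_d <- selfmix:::emission_matrix(dref, fx$model)
  lik_r <- selfmix:::emission_matrix(rref, fx$model)
  expect_gt(mean(lik_d[, 2] > lik_d[, 1]), 0.9)
  expect_gt(mean(lik_r[, 1] > lik_r[, 2]), 0.9)
})

test_that("transition matrix has the stated entries and stationary law", {
  for (alpha in c(0.05, 0.3, 0.8)) for (r in c(0.01, 0.4, 1)) {
    tm <- transition_matrix(alpha, r)
    expect_equal(unname(rowSums(tm)), c(1, 1))
    expect_equal(tm[1, 2], r * alpha)
    expect_equal(tm[2, 1], r * (1 - alpha))
    # stationary distribution (1-alpha, alpha)
    expect_equal(as.numeric(c(1 - alpha, alpha) %*% tm),
                 c(1 - alpha, alpha))
  }
  expect_equal(unname(transition_matrix(0.3, 0)), diag(2))
  expect_error(transition_matrix(-0.1, 0.5), "0, 1")
  expect_error(hmm_params(0.5, 1.2), "0, 1")
})

test_that("forward-backward equals brute-force path enumeration", {
  set.seed(8)
  for (T_ in c(1, 2, 6, 10)) {
    emis <- matrix(runif(2 * T_, 0.05, 1), T_, 2)
    params <- hmm_params(0.2, 0.3)
    trans <- transition_matrix(0.2, 0.3)
    init <- c(0.8, 0.2)
    fb <- selfmix:::fb_chain(emis, trans, init)
    oracle <- enumerate_posteriors(emis, trans, init)
    expect_equal(fb$posterior[, 2], oracle$post_donor, tolerance = 1e-10)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
    # forward and backward recursions agree on the total likelihood
    expect_equal(selfmix:::forward_loglik(emis, trans, init),
                 selfmix:::backward_loglik(emis, trans, init),
                 tolerance = 1e-10)
    # posteriors sum to one and are invariant to per-window rescaling
    expect_equal(rowSums(fb$posterior), rep(1, T_))
    scaled <- emis * runif(T_, 0.5, 200)
    fb2 <- selfmix:::fb_chain(scaled, trans, init)
    expect_equal(fb2$posterior, fb$posterior, tolerance = 1e-12)
  }
})

test_that("single-window posterior is init times emission, normalised", {
  emis <- matrix(c(0.2, 0.6), 1, 2)
  fb <- selfmix:::fb_chain(emis, transition_matrix(0.3, 0.5), c(0.7, 0.3))
  expect_equal(fb$posterior[1, ],
               c(0.7 * 0.2, 0.3 * 0.6) / (0.7 * 0.2 + 0.3 * 0.6))
})

test_that("decoding on a simulated mosaic is over 95% accurate", {
  fx <- hmm_dataset()
  fit <- fit_hmm(fx$ew, fx$model)
  tr <- fx$ds$truth$ADM1
  track <- fit$track
  acc <- unlist(lapply(split(track, track$chrom), function(w) {
    s <- tr[tr$chrom == w$chrom[1], ]
    true_donor <- s$ancestry[findInterval(w$start + 500, s$start)] == "donor"
    (w$post_donor > 0.5) == true_donor
  }))
  expect_gt(mean(acc), 0.95)
  # fitted parameters recover the pulse
  expect_lt(abs(fit$params$alpha - 0.15), 0.05)
  expect_gte(fit$loglik, fit$init_loglik)
})

test_that("admixture fraction behaves at the boundaries", {
  fx <- hmm_dataset()
  fit <- fit_hmm(fx$ew, fx$model)
  tr_frac <- with(fx$ds$truth$ADM1,
                  sum((end - start)[ancestry == "donor"]) / sum(end - start))
  expect_lt(abs(admixture_fraction(fit$track) - tr_frac), 0.02)
  # threshold mode at 0.5 equals the majority vote of decoded states
  expect_equal(admixture_fraction(fit$track, "threshold", 0.5),
               mean(fit$track$post_donor > 0.5))
  zero <- fit$track
  zero$post_donor <- 0
  expect_equal(admixture_fraction(zero), 0)
})

test_that("alpha collapses when no window looks donor-like", {
  fx <- hmm_dataset(seed = 21, genome_bp = 2e6)
  ds <- fx$ds
  # a pure recipient sample as the focal: no donor ancestry to find
  ew <- compute_emission_windows(ds$panel, "REC2", ds$roles$donor)
  fit <- fit_hmm(ew, fx$model)
  expect_lte(fit$params$alpha, 0.01)
})
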