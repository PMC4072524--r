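#' Run the full analysis pipeline
#'
#' Orchestrates the stages end-to-end with one global seed: (optional)
#' simulation -> filtering -> heterozygote resolution -> windowed
#' diversity -> timescale estimators -> ancestry HMM -> block extraction
#' and dating -> four-population D test -> outlier scan -> recombination
#' correlation.  Every stage writes its tables to the run directory; a
#' machine-readable `summary.json` collects the headline numbers together
#' with the configuration hash, and `run_log.txt` echoes parameters and
#' stage timings.  A stage failure halts the run with an error naming the
#' stage; outputs of earlier stages are retained.
#'
#' @param config list with fields:
#'   * `seed` (integer), `out_dir` (created if needed);
#'   * either `simulate` (a [sim_config()], plus optional `n_admixed`) or
#'     `input` (list with `vcf` and optional `genes`, `map`, `reference`);
#'   * `roles`: list with `focal` (admixed recipient), `donors`,
#'     `recipients` (pure recipient references); optional `outgroup` and
#'     `dstat` (list Y/Z/W/X);
#'   * optional `params`: `hmm_window_bp` (1000), `block_threshold`
#'     (0.95), `heal_gap_bp` (0), `min_sites` (100), `recomb_window_bp`
#'     (1e5), `min_comparisons` (100).
#' @return The run directory path, invisibly; the parsed summary is
#'   attached as `attr(, "summary")`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  summary <- list(config_hash = rlang::hash(cfg), seed = cfg$seed)
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  cat("selfmix pipeline\n", file = log_path)
  logline("R %s; selfmix %s", getRversion(),
          as.character(utils::packageVersion("selfmix")))
  logline("seed: %d; config hash: %s", cfg$seed, summary$config_hash)

  stage <- function(name, expr) {
    logline("stage %s: start %s", name, format(Sys.time(), "%H:%M:%OS1"))
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- data ---------------------------------------------------------
  dataset <- NULL
  panel <- stage("input", {
    if (!is.null(cfg$simulate)) {
      dataset <- simulate_dataset(cfg$simulate, cfg$n_admixed %||% 1)
      if (is.null(cfg$roles))
        cfg$roles <- list(focal = dataset$roles$admixed[1],
                          donors = dataset$roles$donor,
                          recipients = dataset$roles$recipient)
      dataset$panel
    } else {
      read_genotype_vcf(cfg$input$vcf)
    }
  })
  map <- if (!is.null(dataset)) dataset$map
         else if (!is.null(cfg$input$map)) read_genetic_map(cfg$input$map)
  missing_roles <- setdiff(unlist(cfg$roles), panel$samples)
  if (length(missing_roles))
    stop("config references sample(s) absent from the panel: ",
         paste(missing_roles, collapse = ", "))
  p <- cfg$params

  panel <- stage("filter", {
    if (!is.null(panel$depth))
      panel <- apply_site_filters(panel, p$min_depth %||% 10,
                                  p$depth_sd %||% 2)
    resolve_heterozygotes(panel, derive_seed(cfg$seed, 21L))
  })

  # --- diversity ----------------------------------------------------
  focal <- cfg$roles$focal
  donors <- cfg$roles$donors
  stage("diversity", {
    wp <- windowed_pi(panel, focal, donors[1],
                      window_bp = p$window_bp %||% 5000,
                      slide_bp = p$slide_bp %||% 1000,
                      min_sites = p$min_sites %||% 100)
    write.table(wp, file.path(cfg$out_dir, "windowed_pi.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    gw <- pairwise_pi(panel, focal, donors[1])
    summary$pi_focal_donor <- gw$pi
  })

  # --- timescales ---------------------------------------------------
  stage("timescales", {
    rec <- cfg$roles$recipients
    if (length(rec) >= 2) {
      pi_anc <- pairwise_pi(panel, rec[1], rec[2])$pi
      pi_bet <- pairwise_pi(panel, rec[1], donors[1])$pi
      if (!is.na(pi_anc) && !is.na(pi_bet) && pi_bet >= pi_anc) {
        st <- split_time(pi_bet, pi_anc,
                         rate_params(mu = cfg$mu %||% 1.5e-8))
        summary$split_time_generations <- st$tau_generations
      }
    }
  })

  # --- ancestry HMM -------------------------------------------------
  track <- stage("hmm", {
    wbp <- p$hmm_window_bp %||% 1000
    ew <- compute_emission_windows(panel, focal, donors, window_bp = wbp)
    donor_ref <- do.call(rbind, lapply(donors, function(d)
      compute_emission_windows(panel, d, setdiff(donors, d), window_bp = wbp)))
    attr(donor_ref, "window_bp") <- wbp
    rec_ref <- do.call(rbind, lapply(cfg$roles$recipients, function(s)
      compute_emission_windows(panel, s, donors, window_bp = wbp)))
    attr(rec_ref, "window_bp") <- wbp
    model <- build_emission_model(donor_ref, rec_ref,
                                  m = length(donors),
                                  m_ref_donor = length(donors) - 1L,
                                  m_ref_recipient = length(donors),
                                  seed = derive_seed(cfg$seed, 22L))
    fit <- fit_hmm(ew, model)
    summary$alpha_hat <- fit$params$alpha
    summary$r_hat <- fit$params$r
    summary$hmm_loglik <- fit$loglik
    summary$ancestry_fraction <- admixture_fraction(fit$track)
    write.table(fit$track, file.path(cfg$out_dir, "posterior_track.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fit$track
  })

  # --- blocks -------------------------------------------------------
  stage("blocks", {
    bl <- call_blocks(track, p$block_threshold %||% 0.95)
    bl <- heal_blocks(bl, p$heal_gap_bp %||% 0)
    bed <- bl[c("chrom", "start", "end")]
    write.table(bed, file.path(cfg$out_dir, "ancestry_blocks.bed"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    summary$n_blocks <- nrow(bl)
    if (nrow(bl) >= 2 && !is.null(map)) {
      wbp <- attr(bl, "window_bp") %||% 0
      morg <- vapply(seq_len(nrow(bl)), function(i) {
        cm <- interpolate_cm(map, bl$chrom[i], c(bl$start[i], bl$end[i]))
        # window-quantization correction, scaled through the local map
        shrink <- max(bl$length_bp[i] - wbp, wbp / 2) / bl$length_bp[i]
        (cm[2] - cm[1]) / 100 * shrink
      }, numeric(1))
      morg <- morg[morg > 0]
      if (length(morg) >= 2) {
        summary$T_generations <- generations_since_pulse(mean(morg))
        summary$dispersion_p <- pulse_dispersion_test(
          morg, seed = derive_seed(cfg$seed, 23L))$p_value
      }
    }
  })

  # --- D test -------------------------------------------------------
  if (!is.null(cfg$roles$dstat)) {
    stage("dstat", {
      ds <- cfg$roles$dstat
      d <- d_test(panel, ds$Y, ds$Z, ds$W, ds$X)
      summary$D <- d$D; summary$D_se <- d$se; summary$D_Z <- d$Z
    })
  }

  # --- outlier scan -------------------------------------------------
  if (length(donors) >= 3) {
    stage("outliers", {
      reg <- find_outlier_regions(panel, donors,
                                  window_bp = p$outlier_window_bp %||% 5000,
                                  pi_threshold = p$pi_threshold %||% 0.01,
                                  region_bp = p$region_bp %||% 2e4,
                                  min_sites = p$outlier_min_sites %||% 100)
      write.table(reg, file.path(cfg$out_dir, "outlier_regions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$n_outlier_regions <- nrow(reg)
    })
  }

  # --- recombination scan -------------------------------------------
  if (!is.null(map)) {
    stage("recomb", {
      rw <- tryCatch(window_recomb_rates(map,
                                         window_bp = p$recomb_window_bp %||% 1e5),
                     error = function(e) NULL)
      if (!is.null(rw)) {
        ws <- windowed_pi(panel, focal, donors[1],
                          window_bp = p$recomb_window_bp %||% 1e5,
                          slide_bp = p$recomb_window_bp %||% 1e5,
                          min_sites = p$min_comparisons %||% 100)
        cr <- tryCatch(divergence_recomb_correlation(
          ws, rw, min_comparisons = p$min_comparisons %||% 100),
          error = function(e) NULL)
        if (!is.null(cr)) {
          summary$recomb_rho <- cr$rho
          summary$recomb_p <- cr$p_value
        }
        write.table(rw, file.path(cfg$out_dir, "recomb_windows.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logline("done %s", format(Sys.time(), "%H:%M:%OS1"))
  out <- cfg$out_dir
  attr(out, "summary") <- summary
  invisible(out)
}

validate_run_config <- function(config) {
  if (is.null(config$seed)) stop("config$seed is required")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (is.null(config$simulate) && is.null(config$input$vcf))
    stop("config needs either $simulate or $input$vcf")
  if (is.null(config$simulate) && is.null(config$roles))
    stop("config$roles is required for file input")
  config$seed <- as.integer(config$seed)
  if (is.null(config$params)) config$params <- list()
  config
}
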