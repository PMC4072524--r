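# Chromosome layout implied by a sim_config: equal-length chromosomes and
# a uniform genetic map (Morgans linear in bp).
chrom_layout <- function(config) {
  len <- floor(config$genome_bp / config$n_chromosomes)
  lens <- setNames(rep(len, config$n_chromosomes),
                   paste0("chr", seq_len(config$n_chromosomes)))
  list(lengths = lens,
       morgans_per_bp = config$map_length_morgans / (len * config$n_chromosomes))
}

# Sites are handled internally as numeric keys
# (chromosome_index - 1) * chrom_len + pos, globally sorted, which keeps
# the large simulated panels cheap to merge and tabulate.

# Poisson-placed derived positions at `rate` per bp, as sorted keys.
scatter_keys <- function(lens, rate) {
  L <- lens[[1]]
  out <- lapply(seq_along(lens), function(i) {
    n <- rpois(1, rate * L)
    (i - 1) * L + sort.int(unique(floor(runif(n, 0, L))))
  })
  unlist(out, use.names = FALSE)
}

# The donor taxon's consensus divergence from the recipient consensus,
# deterministic given the config seed (shared by every sample generator).
donor_consensus <- function(config) {
  lay <- chrom_layout(config)
  with_seed(derive_seed(config$seed, 1L),
            scatter_keys(lay$lengths, config$pi_between))
}

pulse_table <- function(config) {
  if (is.null(config$pulse_times))
    return(data.frame(v = config$v, alpha = config$alpha))
  k <- length(config$pulse_times)
  al <- config$pulse_alphas %||% rep(config$alpha / k, k)
  data.frame(v = config$pulse_times, alpha = al)
}

#' Simulate one admixed mosaic genome
#'
#' Recombination breakpoints are placed as a Poisson process with rate `v`
#' per Morgan along the (uniform) map, chromosome ends always break, and
#' each resulting segment is independently of donor ancestry with
#' probability `alpha` -- the Markovian mosaic implied by single-pulse
#' admixture `v` generations ago, with no back-coalescence of segments.
#' Donor segments carry the donor-consensus variants (divergence
#' `pi_between` from the recipient consensus); the whole genome also
#' carries sample-private variants at rate `pi_within`.
#'
#' Truth segments are returned at breakpoint resolution: individual
#' inter-breakpoint segments (exponential with mean `1/v` Morgans under a
#' single pulse), which tile each chromosome.  Adjacent segments of equal
#' ancestry merge into the maximal runs an ancestry caller can see; use
#' [merge_ancestry_runs()] for that view.
#'
#' @param config a [sim_config()].
#' @param sample_index index of the admixed sample (determines its private
#'   random substream).
#' @return list with `derived` (data.frame `chrom`, `pos` of derived
#'   alleles), `truth` (data.frame `chrom`, `start`, `end`, `ancestry`
#'   in `{"recipient", "donor"}`, 0-based half-open).
#' @export
simulate_admixed_genome <- function(config, sample_index = 1) {
  stopifnot(inherits(config, "sim_config"))
  cons <- donor_consensus(config)
  res <- mosaic_sample(config, cons, sample_index)
  lay <- chrom_layout(config)
  L <- lay$lengths[[1]]
  ci <- floor(res$derived / L) + 1L
  res$derived <- data.frame(chrom = names(lay$lengths)[ci],
                            pos = as.integer(res$derived - (ci - 1) * L),
                            stringsAsFactors = FALSE)
  res
}

mosaic_sample <- function(config, cons, sample_index) {
  lay <- chrom_layout(config)
  pulses <- pulse_table(config)
  L <- lay$lengths[[1]]
  with_seed(derive_seed(config$seed, 100L + sample_index), {
    truth <- list(); derived <- list()
    for (i in seq_along(lay$lengths)) {
      ch <- names(lay$lengths)[i]
      off <- (i - 1) * L
      morgans <- L * lay$morgans_per_bp
      # overlay of pulses: union of breakpoints; donor if any pulse says so
      donor_iv <- list()
      all_bp <- numeric(0)
      for (p in seq_len(nrow(pulses))) {
        n_bp <- rpois(1, pulses$v[p] * morgans)
        bp <- sort(floor(runif(n_bp, 0, L)))
        bounds <- unique(c(0, bp, L))
        is_donor <- runif(length(bounds) - 1) < pulses$alpha[p]
        donor_iv[[p]] <- cbind(bounds[-length(bounds)][is_donor],
                               bounds[-1][is_donor])
        all_bp <- c(all_bp, bp)
      }
      bounds <- unique(sort(c(0, all_bp, L)))
      starts <- bounds[-length(bounds)]; ends <- bounds[-1]
      anc <- rep("recipient", length(starts))
      for (p in seq_along(donor_iv)) {
        iv <- donor_iv[[p]]
        if (nrow(iv) == 0) next
        j <- findInterval(starts, iv[, 1])
        hit <- j >= 1 & starts < iv[pmax(j, 1), 2]
        anc[hit] <- "donor"
      }
      truth[[i]] <- data.frame(chrom = ch, start = starts, end = ends,
                               ancestry = anc, stringsAsFactors = FALSE)
      # donor-consensus variants on donor segments
      donor_mask <- anc == "donor"
      lo <- findInterval(off - 0.5, cons) + 1L
      hi <- findInterval(off + L - 0.5, cons)
      cp <- if (hi >= lo) cons[lo:hi] - off else numeric(0)
      seg_of <- findInterval(cp, starts)
      on_donor <- cp[donor_mask[seg_of]]
      priv_n <- rpois(1, config$pi_within * L)
      priv <- sort.int(unique(floor(runif(priv_n, 0, L))))
      keys <- off + sort.int(unique(c(on_donor, priv)))
      derived[[i]] <- keys
    }
    list(derived = unlist(derived, use.names = FALSE),
         truth = do.call(rbind, truth))
  })
}

#' Merge truth segments into maximal same-ancestry runs
#'
#' @param truth a truth data.frame from [simulate_admixed_genome()].
#' @return data.frame of the same shape with adjacent equal-ancestry
#'   segments merged.
#' @export
merge_ancestry_runs <- function(truth) {
  out <- lapply(split(truth, truth$chrom), function(tr) {
    tr <- tr[order(tr$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, tr$ancestry[-1] != tr$ancestry[-nrow(tr)]))
    data.frame(chrom = tr$chrom[1],
               start = tapply(tr$start, grp, min),
               end = tapply(tr$end, grp, max),
               ancestry = tapply(tr$ancestry, grp, `[`, 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Derived-site keys for a pure donor (consensus + private) or pure
# recipient (private only) sample.
pure_sample <- function(config, cons, kind, index) {
  lay <- chrom_layout(config)
  with_seed(derive_seed(config$seed,
                        if (kind == "donor") 200L + index else 300L + index), {
    priv <- scatter_keys(lay$lengths, config$pi_within)
    if (kind == "donor") sort.int(unique(c(cons, priv))) else priv
  })
}

#' Simulate a full dataset with known ancestry truth
#'
#' Builds a genome-callable [genotype_panel()] containing pure recipient
#' reference samples (`REC*`), a donor panel (`DON*`) that shares the
#' donor-consensus divergence from the recipient consensus plus private
#' variation, and one or more admixed recipient samples (`ADM*`) whose
#' genomes are donor/recipient mosaics with recorded truth segments.  A
#' uniform genetic map over the configured chromosomes is attached.
#'
#' @param config a [sim_config()].
#' @param n_admixed number of admixed focal samples.
#' @return list of class `sim_dataset`: `panel`, `truth` (list per admixed
#'   sample), `map`, `config`, `roles` (named list of sample names),
#'   `genes` (filled by [plant_gene_models_and_stops()]).
#' @export
simulate_dataset <- function(config, n_admixed = 1) {
  stopifnot(inherits(config, "sim_config"))
  lay <- chrom_layout(config)
  cons <- donor_consensus(config)
  rec <- lapply(seq_len(config$n_recipient),
                function(i) pure_sample(config, cons, "recipient", i))
  don <- lapply(seq_len(config$n_donor),
                function(i) pure_sample(config, cons, "donor", i))
  adm <- lapply(seq_len(n_admixed), function(i) mosaic_sample(config, cons, i))
  samples <- c(paste0("REC", seq_len(config$n_recipient)),
               paste0("DON", seq_len(config$n_donor)),
               paste0("ADM", seq_len(n_admixed)))
  derived <- c(rec, don, lapply(adm, `[[`, "derived"))

  L <- lay$lengths[[1]]
  keys <- sort.int(unique(unlist(derived, use.names = FALSE)))
  geno <- matrix(0L, length(keys), length(samples))
  for (j in seq_along(derived))
    geno[findInterval(derived[[j]], keys), j] <- 1L
  ci <- floor(keys / L) + 1L
  sites <- data.frame(chrom = names(lay$lengths)[ci],
                      pos = as.integer(keys - (ci - 1) * L),
                      ref = rep("A", length(keys)),
                      alt = rep("T", length(keys)),
                      stringsAsFactors = FALSE)
  # keys are sorted by construction; bypass the constructor's re-sort
  panel <- structure(list(sites = sites, geno = geno, samples = samples,
                          depth = NULL, degeneracy = NULL,
                          callable = "genome", chrom_lengths = lay$lengths),
                     class = "genotype_panel")
  colnames(panel$geno) <- samples
  map <- genetic_map(do.call(rbind, lapply(names(lay$lengths), function(ch) {
    L <- lay$lengths[[ch]]
    data.frame(chrom = ch, bp = c(0, L),
               cm = c(0, L * lay$morgans_per_bp * 100))
  })))
  truth <- lapply(adm, `[[`, "truth")
  names(truth) <- paste0("ADM", seq_len(n_admixed))
  structure(list(panel = panel, truth = truth, map = map, config = config,
                 genes = NULL, reference = NULL,
                 roles = list(recipient = paste0("REC", seq_len(config$n_recipient)),
                              donor = paste0("DON", seq_len(config$n_donor)),
                              admixed = paste0("ADM", seq_len(n_admixed)))),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", n_sites(x$panel), "segregating sites;",
      length(x$roles$recipient), "recipient,",
      length(x$roles$donor), "donor,",
      length(x$roles$admixed), "admixed sample(s)\n")
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the panel as VCF, each admixed sample's truth segments as BED
#' (0-based half-open), the genetic map and (if present) gene models as
#' TSV.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotype_vcf(dataset$panel, file.path(dir, "panel.vcf.gz"))
  for (nm in names(dataset$truth)) {
    tr <- dataset$truth[[nm]]
    write.table(tr[c("chrom", "start", "end", "ancestry")],
                file.path(dir, paste0("truth_", nm, ".bed")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  write_genetic_map(dataset$map, file.path(dir, "map.tsv"))
  if (!is.null(dataset$genes))
    write_gene_models(dataset$genes, file.path(dir, "genes.tsv"))
  invisible(dir)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Plant gene models and premature stop codons
#'
#' Adds coding annotation to a simulated dataset: a reference sequence is
#' generated over each chromosome (only feasible for fixture-scale
#' genomes), gene models with stop-free random codons are written into it,
#' and requested codons are mutated to premature stops in chosen samples
#' by adding the corresponding derived alleles to the panel.  The record
#' of planted events is returned for exact-recovery checks against the
#' stop-codon caller.
#'
#' @param dataset a [simulate_dataset()] result with a small genome
#'   (reference strings are materialised in memory).
#' @param stops data.frame with columns `gene_id`, `codon_index`
#'   (1-based), `sample`; may have zero rows.
#' @param genes optional [gene_models()]; by default five 100-codon
#'   single-interval genes are laid out on the first chromosome, one of
#'   them on the minus strand.
#' @param codon stop codon to plant (default `"TAA"`).
#' @return The dataset with `genes`, `reference` and `planted` filled.
#' @export
plant_gene_models_and_stops <- function(dataset, stops = NULL, genes = NULL,
                                        codon = "TAA") {
  stopifnot(inherits(dataset, "sim_dataset"))
  config <- dataset$config
  lay <- chrom_layout(config)
  if (any(lay$lengths > 5e6))
    stop("gene planting is for fixture-scale genomes (chromosomes <= 5 Mb)")
  if (!codon %in% STOP_CODONS) stop("codon must be a stop codon")
  if (is.null(genes)) {
    ch <- names(lay$lengths)[1]
    n_codons <- 100L
    glen <- 3L * n_codons
    starts <- seq(1000L, by = glen + 1000L, length.out = 5L)
    if (max(starts) + glen > lay$lengths[[ch]])
      stop("first chromosome too short for default gene layout")
    genes <- gene_models(data.frame(
      gene_id = paste0("g", 1:5), chrom = ch,
      strand = c("+", "+", "-", "+", "+"),
      start = starts, end = starts + glen, frame = 0L))
  }
  reference <- with_seed(derive_seed(config$seed, 7L), {
    ref <- lapply(lay$lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
    names(ref) <- names(lay$lengths)
    ref
  })
  # overwrite gene bodies with stop-free codons (coding strand), ending in
  # a genuine terminal stop so the annotation is frame-consistent
  non_stop <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                        c("A","C","G","T")), 1, paste, collapse = ""),
                      STOP_CODONS)
  reference <- with_seed(derive_seed(config$seed, 8L), {
    for (gid in unique(genes$gene_id)) {
      gi <- genes[genes$gene_id == gid, , drop = FALSE]
      len <- sum(gi$end - gi$start)
      n_cod <- len %/% 3L
      cds <- c("ATG", sample(non_stop, n_cod - 2L, replace = TRUE), "TGA")
      cds_bases <- strsplit(paste(cds, collapse = ""), "")[[1]]
      ch <- gi$chrom[1]
      pos <- unlist(lapply(seq_len(nrow(gi)),
                           function(r) seq.int(gi$start[r], gi$end[r] - 1L)))
      if (gi$strand[1] == "-") cds_bases <- rev_complement(cds_bases)
      s <- strsplit(reference[[ch]], "")[[1]]
      s[pos + 1L] <- cds_bases
      reference[[ch]] <- paste(s, collapse = "")
    }
    reference
  })
  planted <- NULL
  panel <- dataset$panel
  if (!is.null(stops) && nrow(stops)) {
    for (r in seq_len(nrow(stops))) {
      gid <- stops$gene_id[r]
      gi <- genes[genes$gene_id == gid, , drop = FALSE]
      if (!nrow(gi)) stop("stop requested in unknown gene ", gid)
      sp <- spliced_coding(gi, reference[[gi$chrom[1]]])
      n_cod <- length(sp$seq) %/% 3L
      ci <- as.integer(stops$codon_index[r])
      if (ci < 1L || ci > n_cod)
        stop("codon index outside frame-consistent coding region of ", gid)
      idx <- (ci - 1L) * 3L + 1:3
      ref_cod <- paste(sp$seq[idx], collapse = "")
      target <- strsplit(codon, "")[[1]]
      for (p in 1:3) {
        if (sp$seq[idx[p]] == target[p]) next
        gpos <- sp$pos[idx[p]]
        ref_base <- substr(reference[[gi$chrom[1]]], gpos + 1L, gpos + 1L)
        alt_base <- if (gi$strand[1] == "-")
          chartr("ACGT", "TGCA", target[p]) else target[p]
        panel <- add_site_allele(panel, gi$chrom[1], gpos, ref_base,
                                 alt_base, stops$sample[r])
      }
      planted <- rbind(planted, data.frame(
        gene_id = gid, codon_index = ci,
        codon_fraction = ci / n_cod, sample = stops$sample[r],
        ref_codon = ref_cod, new_codon = codon, stringsAsFactors = FALSE))
    }
  }
  dataset$genes <- genes
  dataset$reference <- reference
  dataset$panel <- panel
  dataset$planted <- planted
  dataset
}

# Give `sample` the alternate allele at (chrom, pos), creating the site if
# it is not yet in the panel.
add_site_allele <- function(panel, chrom, pos, ref, alt, sample) {
  j <- sample_index(panel, sample)
  hit <- which(panel$sites$chrom == chrom & panel$sites$pos == pos)
  if (length(hit)) {
    panel$sites$ref[hit] <- ref
    panel$sites$alt[hit] <- alt
    panel$geno[hit, j] <- 1L
    return(panel)
  }
  new_site <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  new_row <- matrix(0L, 1, length(panel$samples))
  new_row[1, j] <- 1L
  if (!is.null(panel$depth)) {
    dnew <- rbind(panel$depth, matrix(NA_integer_, 1, length(panel$samples)))
  } else dnew <- NULL
  genotype_panel(rbind(panel$sites, new_site), rbind(panel$geno, new_row),
                 panel$samples, depth = dnew,
                 degeneracy = if (!is.null(panel$degeneracy))
                   c(panel$degeneracy, NA_character_),
                 callable = panel$callable,
                 chrom_lengths = panel$chrom_lengths)
}
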