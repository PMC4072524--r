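#' Haploid genotype panel
#'
#' The central container: per-site calls for a set of (effectively haploid,
#' fully inbred) samples, with optional per-call sequencing depth and
#' per-site codon-degeneracy class.
#'
#' Coordinates are 0-based half-open throughout the package; VCF input and
#' output convert from and to the 1-based VCF convention.
#'
#' Calls are stored as integer allele indices: `0` is the reference allele,
#' `k >= 1` the k-th alternate, `NA` missing.  Residual heterozygous diploid
#' calls (e.g. `0/1` from a variant caller run on an inbred line) are kept
#' as an encoded pair until [resolve_heterozygotes()] replaces them by a
#' random allele.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt` (comma-separated alternate alleles, `""` if none).
#' @param geno integer matrix, `nrow(sites)` x `length(samples)`.
#' @param samples character vector of sample names (column order of `geno`).
#' @param depth optional integer matrix of per-call read depths, same shape
#'   as `geno`.
#' @param degeneracy optional character vector per site, one of
#'   `"0"`, `"2"`, `"3"`, `"4"`, `"noncoding"`.
#' @param callable `"panel"` if only the listed sites carry data (real
#'   resequencing panels, where invariant callable sites are part of the
#'   site list), or `"genome"` for simulator output under the infinite-sites
#'   model, where every position is callable and absence from the site list
#'   means identity with the reference.
#' @param chrom_lengths optional named vector of chromosome lengths in bp;
#'   required for `callable = "genome"`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sites, geno, samples, depth = NULL,
                           degeneracy = NULL,
                           callable = c("panel", "genome"),
                           chrom_lengths = NULL) {
  callable <- match.arg(callable)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(sites))
    stop("geno must have one row per site")
  if (ncol(geno) != length(samples))
    stop("geno must have one column per sample")
  colnames(geno) <- samples
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    stopifnot(all(dim(depth) == dim(geno)))
    colnames(depth) <- samples
  }
  if (!is.null(degeneracy)) {
    stopifnot(length(degeneracy) == nrow(sites))
    degeneracy <- as.character(degeneracy)
  }
  if (callable == "genome" && is.null(chrom_lengths))
    stop("chrom_lengths is required when callable = \"genome\"")
  # strictly increasing positions within chromosome
  ci <- match(sites$chrom, unique(sites$chrom))
  o <- order(ci, sites$pos, method = "radix")
  if (is.unsorted(o)) {
    sites <- sites[o, , drop = FALSE]
    geno <- geno[o, , drop = FALSE]
    if (!is.null(depth)) depth <- depth[o, , drop = FALSE]
    if (!is.null(degeneracy)) degeneracy <- degeneracy[o]
    ci <- ci[o]
  }
  n <- nrow(sites)
  if (n > 1 && any(ci[-1] == ci[-n] & sites$pos[-1] == sites$pos[-n]))
    stop("duplicate site positions within a chromosome")
  rownames(sites) <- NULL
  structure(list(sites = sites, geno = geno, samples = samples,
                 depth = depth, degeneracy = degeneracy,
                 callable = callable, chrom_lengths = chrom_lengths),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d sites x %d samples (%s-callable)\n",
              nrow(x$sites), length(x$samples), x$callable))
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  cat("chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$geno)

n_sites <- function(panel) nrow(panel$sites)

# Subset a panel to a row index (rows may repeat, e.g. in a block
# bootstrap resample).
subset_panel <- function(panel, idx) {
  structure(list(sites = panel$sites[idx, , drop = FALSE],
                 geno = panel$geno[idx, , drop = FALSE],
                 samples = panel$samples,
                 depth = if (!is.null(panel$depth)) panel$depth[idx, , drop = FALSE],
                 degeneracy = if (!is.null(panel$degeneracy)) panel$degeneracy[idx],
                 callable = panel$callable,
                 chrom_lengths = panel$chrom_lengths),
            class = "genotype_panel")
}

sample_index <- function(panel, sample) {
  i <- match(sample, panel$samples)
  if (anyNA(i))
    stop("sample(s) not in panel: ",
         paste(sample[is.na(i)], collapse = ", "))
  i
}

# Logical mask of sites belonging to a degeneracy class set (NULL = all).
site_class_mask <- function(panel, site_class) {
  if (is.null(site_class)) return(rep(TRUE, n_sites(panel)))
  if (is.null(panel$degeneracy))
    stop("panel has no degeneracy annotation; run annotate_degeneracy() first")
  panel$degeneracy %in% as.character(site_class)
}

# Heterozygote encoding: a diploid call a/b (a < b, allele indices 0..3)
# is stored as -(4*a + b) - 1L so it cannot collide with haploid codes.
encode_het <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  as.integer(-(4L * lo + hi) - 1L)
}
decode_het <- function(code) {
  v <- -(code + 1L)
  cbind(a = v %/% 4L, b = v %% 4L)
}
is_het <- function(geno) !is.na(geno) & geno < 0L

#' Read a genotype panel from VCF
#'
#' Reads haploid (`GT` like `0`, `1`) or diploid (`0/0`, `0|1`, ...) calls,
#' homozygous diploid calls being collapsed to haploid allele indices and
#' heterozygous calls kept encoded for [resolve_heterozygotes()].  Per-call
#' `DP` is read when present.  Positions are converted to 0-based.
#'
#' @param path VCF file (plain or bgzipped).
#' @return A [genotype_panel()].
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  samples <- colnames(gt_raw)
  gt_first <- sub("[/|].*$", "", gt_raw)
  gt_second <- sub("^[^/|]*[/|]", "", gt_raw)
  a <- suppressWarnings(as.integer(gt_first))
  b <- suppressWarnings(as.integer(gt_second))
  hap <- !grepl("[/|]", gt_raw)
  geno <- ifelse(hap, a, ifelse(a == b, a, encode_het(a, b)))
  geno <- matrix(as.integer(geno), nrow = nrow(gt_raw),
                 dimnames = dimnames(gt_raw))
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]) - 1L,
                      ref = fix[, "REF"],
                      alt = ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]),
                      stringsAsFactors = FALSE)
  if (!is.null(dp)) {
    dp <- matrix(as.integer(dp), nrow = nrow(dp), dimnames = dimnames(dp))
  }
  genotype_panel(sites, geno, samples, depth = dp)
}

#' Write a genotype panel to VCF
#'
#' One haploid genotype column per sample (`GT`, plus `DP` when depths are
#' present).  Encoded heterozygotes are written back as diploid `a/b` calls,
#' so a panel round-trips losslessly.
#'
#' @param panel a [genotype_panel()].
#' @param path output path; vcfR appends `.gz` handling automatically
#'   (the file is written bgzipped when the name ends in `.gz`).
#' @export
write_genotype_vcf <- function(panel, path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("writing VCF requires the vcfR package")
  n <- n_sites(panel)
  gt_chr <- matrix("", n, length(panel$samples),
                   dimnames = list(NULL, panel$samples))
  g <- panel$geno
  hetm <- is_het(g)
  gt_chr[] <- ifelse(is.na(g), ".", as.character(g))
  if (any(hetm)) {
    ab <- decode_het(g[hetm])
    gt_chr[hetm] <- paste0(ab[, "a"], "/", ab[, "b"])
  }
  fmt <- "GT"
  if (!is.null(panel$depth)) {
    fmt <- "GT:DP"
    dp_chr <- ifelse(is.na(panel$depth), ".", as.character(panel$depth))
    gt_chr[] <- paste0(gt_chr, ":", dp_chr)
  }
  gt <- cbind(FORMAT = rep(fmt, n), gt_chr)
  fix <- cbind(CHROM = panel$sites$chrom,
               POS = as.character(panel$sites$pos + 1L),
               ID = rep(NA_character_, n),
               REF = panel$sites$ref,
               ALT = ifelse(panel$sites$alt == "", NA_character_,
                            panel$sites$alt),
               QUAL = rep(NA_character_, n),
               FILTER = rep("PASS", n),
               INFO = rep(NA_character_, n))
  meta <- c("##fileformat=VCFv4.2",
            "##source=selfmix",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Gene models (coding intervals)
#'
#' A flat, GFF-like table of coding intervals: one row per interval with
#' columns `gene_id`, `chrom`, `strand` (`"+"`/`"-"`), `start`, `end`
#' (0-based half-open) and `frame` (codon offset of the gene's first
#' interval, almost always 0).  Intervals of a gene must be non-overlapping
#' and are used in 5'-to-3' order; the summed interval length must be a
#' multiple of 3.
#'
#' @param df data.frame with the columns above (`frame` optional).
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(df) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(df)))
  if (is.null(df$frame)) df$frame <- 0L
  if (any(df$end <= df$start)) stop("gene intervals must have start < end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  len <- tapply(df$end - df$start, df$gene_id, sum)
  bad <- names(len)[len %% 3L != 0L]
  if (length(bad))
    stop("coding length not divisible by 3 for gene(s): ",
         paste(bad, collapse = ", "))
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("gene_models", "data.frame"))
}

#' @rdname gene_models
#' @param path TSV file path.
#' @export
read_gene_models <- function(path) {
  gene_models(read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE))
}

#' @rdname gene_models
#' @param genes a `gene_models` object.
#' @export
write_gene_models <- function(genes, path) {
  write.table(as.data.frame(genes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Genetic map
#'
#' Per-chromosome ordered markers linking physical (bp) and genetic (cM)
#' positions.  cM must be non-decreasing in bp within a chromosome.
#'
#' @param df data.frame with columns `chrom`, `bp` (0-based), `cm`.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(df) {
  stopifnot(all(c("chrom", "bp", "cm") %in% names(df)))
  df <- df[order(df$chrom, df$bp), , drop = FALSE]
  bad <- unlist(tapply(df$cm, df$chrom, function(x) any(diff(x) < 0)))
  if (any(bad))
    stop("cM must be non-decreasing in bp on chromosome(s): ",
         paste(names(bad)[bad], collapse = ", "))
  rownames(df) <- NULL
  structure(df, class = c("genetic_map", "data.frame"))
}

#' @rdname genetic_map
#' @param path TSV file path.
#' @export
read_genetic_map <- function(path) {
  genetic_map(read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE))
}

#' @rdname genetic_map
#' @param map a `genetic_map` object.
#' @export
write_genetic_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Interpolate genetic-map position
#'
#' Piecewise-linear interpolation of the cM position of arbitrary bp
#' coordinates between flanking markers.  Positions outside the marker
#' range are clamped to the terminal marker's cM (no extrapolation, which
#' could produce negative local rates).
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome id (scalar).
#' @param bp vector of physical positions.
#' @return Numeric vector of cM positions.
#' @export
interpolate_cm <- function(map, chrom, bp) {
  m <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0) stop("chromosome not in map: ", chrom)
  if (nrow(m) == 1) return(rep(m$cm, length(bp)))
  approx(m$bp, m$cm, xout = bp, rule = 2, ties = "ordered")$y
}

#' Chromosome lengths known to a panel
#'
#' For genome-callable (simulated) panels this is the configured length;
#' otherwise the last site position + 1 per chromosome.
#' @param panel a [genotype_panel()].
#' @return Named numeric vector of lengths in bp.
#' @export
panel_chrom_lengths <- function(panel) {
  if (!is.null(panel$chrom_lengths)) return(panel$chrom_lengths)
  len <- tapply(panel$sites$pos, panel$sites$chrom, max) + 1
  setNames(as.numeric(len), names(len))
}
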