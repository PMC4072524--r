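#' Codon degeneracy classification
#'
#' Labels every coding site with its degeneracy class under the standard
#' genetic code: zerofold (`"0"`, no synonymous substitution), twofold
#' (`"2"`, one of the three alternative nucleotides is synonymous),
#' threefold (`"3"`) or fourfold (`"4"`, all substitutions synonymous).
#' Classification is strand-aware and uses the reference codon: when the
#' degeneracy of a site depends on another polymorphic position in the same
#' codon, the reference codon decides.
#'
#' @param genes a [gene_models()] object.
#' @param reference named character vector of chromosome sequences
#'   (names matching `genes$chrom`), or a list of single strings.
#' @return data.frame with columns `chrom`, `pos` (0-based), `gene_id`,
#'   `degeneracy`.  Sites covered by several genes keep the first gene's
#'   class.
#' @export
classify_degeneracy <- function(genes, reference) {
  reference <- unlist(reference)
  out <- vector("list", length(unique(genes$gene_id)))
  ids <- unique(genes$gene_id)
  for (k in seq_along(ids)) {
    gid <- ids[k]
    gi <- genes[genes$gene_id == gid, , drop = FALSE]
    chrom <- gi$chrom[1]
    if (!chrom %in% names(reference))
      stop("no reference sequence for chromosome ", chrom)
    sp <- spliced_coding(gi, reference[[chrom]])
    cds <- sp$seq
    if (length(cds) %% 3L != 0L)
      stop("frame inconsistency in gene ", gid)
    codons <- matrix(cds, nrow = 3)
    deg <- apply(codons, 2, function(cod) degeneracy_of_codon(paste(cod, collapse = "")))
    out[[k]] <- data.frame(chrom = chrom, pos = sp$pos, gene_id = gid,
                           degeneracy = as.character(deg),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[!duplicated(res[c("chrom", "pos")]), , drop = FALSE]
}

# Splice the coding sequence of one gene (rows of a gene_models table for a
# single gene_id) out of a chromosome string.  Returns the coding-strand
# bases in translation order together with their genomic positions.
spliced_coding <- function(gi, chromseq) {
  gi <- gi[order(gi$start), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(gi)),
                       function(r) seq.int(gi$start[r], gi$end[r] - 1L)))
  bases <- strsplit(chromseq, "")[[1]][pos + 1L]
  strand <- gi$strand[1]
  if (strand == "-") {
    pos <- rev(pos)
    bases <- rev_complement(bases)
  }
  frame <- gi$frame[1] %% 3L
  if (frame > 0L) {
    pos <- pos[-seq_len(frame)]
    bases <- bases[-seq_len(frame)]
  }
  list(pos = pos, seq = toupper(bases))
}

rev_complement <- function(bases) {
  rev(chartr("ACGTacgt", "TGCAtgca", bases))
}

translate_codon <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

# Degeneracy classes ("0"/"2"/"3"/"4") of the three positions of a codon.
degeneracy_of_codon <- function(codon) {
  .degeneracy_table()[[toupper(codon)]]
}

.deg_cache <- new.env(parent = emptyenv())

.degeneracy_table <- function() {
  if (!is.null(.deg_cache$tab)) return(.deg_cache$tab)
  nts <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(nts, nts, nts, stringsAsFactors = FALSE),
                  1, paste, collapse = "")
  tab <- lapply(codons, function(cod) {
    aa <- translate_codon(cod)
    vapply(1:3, function(p) {
      alts <- setdiff(nts, substr(cod, p, p))
      nsyn <- sum(vapply(alts, function(a) {
        mut <- cod
        substr(mut, p, p) <- a
        translate_codon(mut) == aa
      }, logical(1)))
      c("0", "2", "3", "4")[nsyn + 1L]
    }, character(1))
  })
  names(tab) <- codons
  .deg_cache$tab <- tab
  tab
}

#' Annotate a panel with degeneracy classes
#'
#' Convenience wrapper around [classify_degeneracy()]: every panel site
#' inside a coding interval receives its class, all other sites become
#' `"noncoding"`.
#'
#' @inheritParams classify_degeneracy
#' @param panel a [genotype_panel()].
#' @return The panel with its `degeneracy` field filled.
#' @export
annotate_degeneracy <- function(panel, genes, reference) {
  cls <- classify_degeneracy(genes, reference)
  key <- paste(panel$sites$chrom, panel$sites$pos)
  m <- match(key, paste(cls$chrom, cls$pos))
  deg <- ifelse(is.na(m), "noncoding", cls$degeneracy[m])
  panel$degeneracy <- deg
  panel
}
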