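# Core containers shared by the simulation and IO layers.

#' Construct a genotype dosage matrix
#'
#' Samples x variants dosage matrix (0/1/2 copies of the alternative
#' allele, NA for missing) with per-variant metadata. The minor allele
#' frequency is recomputed from the non-missing dosages.
#'
#' @param dosage Numeric matrix, samples in rows, variants in columns.
#' @param variants Data frame with one row per variant; columns `id`,
#'   `chrom`, `pos` (1-based, VCF convention), `ref`, `alt`. Missing
#'   metadata are filled with defaults.
#' @return An object of class `genotype_matrix`: list with elements
#'   `dosage`, `variants` (including a `maf` column) and `samples`.
#' @export
genotype_matrix <- function(dosage, variants = NULL) {
  dosage <- as.matrix(dosage)
  if (!all(dosage %in% c(0, 1, 2) | is.na(dosage)))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("var%05d", seq_len(ncol(dosage)))
  if (is.null(variants))
    variants <- data.frame(id = colnames(dosage))
  variants$id <- as.character(variants$id)
  if (is.null(variants$chrom)) variants$chrom <- "chr1"
  if (is.null(variants$pos)) variants$pos <- seq_len(ncol(dosage)) * 1000L
  if (is.null(variants$ref)) variants$ref <- "A"
  if (is.null(variants$alt)) variants$alt <- "G"
  af <- colMeans(dosage, na.rm = TRUE) / 2
  variants$maf <- pmin(af, 1 - af)
  variants$maf[!is.finite(variants$maf)] <- NA_real_
  structure(list(dosage = dosage, variants = variants,
                 samples = rownames(dosage)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  MAF range: %.3f - %.3f\n",
              min(x$variants$maf, na.rm = TRUE),
              max(x$variants$maf, na.rm = TRUE)))
  invisible(x)
}

#' Construct an intron cluster count table
#'
#' Junction counts per intron per sample, with introns grouped into
#' clusters sharing splice sites (LeafCutter-style). Row keys follow the
#' `chrom:start:end:cluID` dialect with 0-based half-open coordinates.
#'
#' @param counts Non-negative integer matrix, introns x samples.
#' @param introns Data frame with columns `chrom`, `start`, `end`,
#'   `cluster` (one row per intron, same order as `counts`).
#' @return An object of class `intron_cluster_table`.
#' @export
intron_cluster_table <- function(counts, introns) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE))
    stop("junction counts must be non-negative", call. = FALSE)
  if (nrow(counts) != nrow(introns))
    stop("counts and introns disagree on the number of introns", call. = FALSE)
  introns <- as.data.frame(introns)
  stopifnot(all(c("chrom", "start", "end", "cluster") %in% names(introns)))
  rownames(counts) <- intron_keys(introns)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%04d", seq_len(ncol(counts)))
  structure(list(counts = counts, introns = introns),
            class = "intron_cluster_table")
}

intron_keys <- function(introns) {
  sprintf("%s:%d:%d:%s", introns$chrom, introns$start, introns$end,
          introns$cluster)
}

#' @export
print.intron_cluster_table <- function(x, ...) {
  cat(sprintf("intron_cluster_table: %d introns in %d clusters x %d samples\n",
              nrow(x$counts), length(unique(x$introns$cluster)),
              ncol(x$counts)))
  invisible(x)
}

#' Construct a transcript model
#'
#' Strand-aware exon chain. Exons are stored 0-based half-open and kept
#' sorted 5' to 3' along the transcript (i.e. by decreasing genomic start
#' on the minus strand).
#'
#' @param id Transcript identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data frame of exon `start`, `end`
#'   (0-based half-open).
#' @param biotype `"lncRNA"`, `"protein_coding"`, or another annotation
#'   biotype string.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(id, chrom, strand, exons,
                             biotype = "lncRNA") {
  exons <- as.matrix(as.data.frame(exons)[, 1:2])
  colnames(exons) <- c("start", "end")
  storage.mode(exons) <- "integer"
  if (any(exons[, "start"] >= exons[, "end"]))
    stop(sprintf("transcript %s: exon with start >= end", id), call. = FALSE)
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons[-1, "start"] < exons[-nrow(exons), "end"]))
    stop(sprintf("transcript %s: overlapping exons", id), call. = FALSE)
  if (!strand %in% c("+", "-"))
    stop(sprintf("transcript %s: strand must be '+' or '-'", id), call. = FALSE)
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  structure(
    list(id = as.character(id), chrom = as.character(chrom), strand = strand,
         start = min(exons[, "start"]), end = max(exons[, "end"]),
         exons = exons, biotype = biotype, n_exons = nrow(exons),
         multi_exonic = nrow(exons) >= 2L),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%d-%d [%s], %d exon(s)\n",
              x$id, x$biotype, x$chrom, x$start, x$end, x$strand, x$n_exons))
  invisible(x)
}

# Strand-aware 5' terminus (0-based position of the first transcribed nt).
transcript_tss <- function(tx) {
  if (tx$strand == "+") tx$start else tx$end - 1L
}

# Introns of a transcript in genomic order: gaps between genomically
# sorted exons; 0-based half-open.
transcript_introns <- function(tx) {
  ex <- tx$exons[order(tx$exons[, "start"]), , drop = FALSE]
  n <- nrow(ex)
  if (n < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex[-n, "end"], end = ex[-1, "start"])
}
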