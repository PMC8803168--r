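# Readers and writers for the standard formats the pipeline touches.
# All internal coordinates are 0-based half-open (BED convention); GTF and
# VCF boundaries are converted on the way in and out.

#' Read transcript models from a GTF file
#'
#' Parses exon records (via `rtracklayer`), groups them by transcript,
#' converts the 1-based inclusive GTF coordinates to 0-based half-open,
#' and orders exons 5' to 3' along the transcript strand. Overlapping
#' exons within one transcript are a parse error naming the transcript.
#'
#' @param path Path to a GTF file.
#' @return A named list of [transcript_model()] objects (class
#'   `transcript_set`). Empty input yields an empty set with a warning.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GTF: ", path, call. = FALSE)
    return(structure(list(), class = "transcript_set"))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type == "exon", , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("GTF has no exon records: ", path, call. = FALSE)
    return(structure(list(), class = "transcript_set"))
  }
  biotype_col <- intersect(c("transcript_biotype", "gene_biotype", "biotype",
                             "transcript_type", "gene_type"), names(df))
  txs <- split(df, df$transcript_id)
  out <- lapply(txs, function(d) {
    bt <- if (length(biotype_col)) as.character(d[[biotype_col[1]]][1]) else "lncRNA"
    if (is.na(bt)) bt <- "lncRNA"
    if (bt %in% c("lincRNA", "antisense", "lncRNA", "processed_transcript"))
      bt <- "lncRNA"
    transcript_model(id = d$transcript_id[1],
                     chrom = as.character(d$seqnames[1]),
                     strand = as.character(d$strand[1]),
                     exons = cbind(start = d$start - 1L, end = d$end),
                     biotype = bt)
  })
  structure(out, class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcript(s)\n", length(x)))
  invisible(x)
}

#' Read a BED file of genomic intervals
#'
#' @param path Path to a BED (3-6 column) file.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and, when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start - 1L, end = df$end)
  if (!is.null(df$name)) out$name <- df$name
  if (!is.null(df$score)) out$score <- df$score
  st <- as.character(df$strand)
  if (!all(st == "*")) out$strand <- ifelse(st == "*", ".", st)
  out
}

#' Write intervals to BED
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optional `name`, `score`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(chrom = intervals$chrom,
                   start = intervals$start, end = intervals$end,
                   name = if (is.null(intervals$name)) "." else intervals$name,
                   score = if (is.null(intervals$score)) 0 else intervals$score,
                   strand = if (is.null(intervals$strand)) "." else intervals$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from VCF or TSV
#'
#' VCF input (4.x, GT field) is parsed with `vcfR`; multi-allelic records
#' are skipped with a warning and phased/unphased GT separators are both
#' accepted. The TSV dialect has columns `variant_id`, `chrom`, `pos`,
#' `ref`, `alt` followed by one dosage column per sample (the format
#' [write_genotypes()] emits). Variants with all calls missing are
#' dropped with a warning.
#'
#' @param path Path to a `.vcf` or `.tsv` file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    warning(sum(multi), " multi-allelic record(s) skipped", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  dosage <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(strsplit(g, "[|/]")[[1]] == "1")
  })
  dosage <- t(dosage)  # samples x variants
  all_missing <- colSums(!is.na(dosage)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing variant(s) dropped", call. = FALSE)
    dosage <- dosage[, !all_missing, drop = FALSE]
    fix <- fix[!all_missing, , drop = FALSE]
  }
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                sprintf("%s_%s", fix$CHROM, fix$POS), fix$ID)
  colnames(dosage) <- ids
  genotype_matrix(dosage,
                  data.frame(id = ids, chrom = fix$CHROM,
                             pos = as.integer(fix$POS),
                             ref = fix$REF, alt = fix$ALT))
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(df)))
    stop("genotype TSV must have columns ", paste(meta_cols, collapse = ", "),
         call. = FALSE)
  dosage <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
  colnames(dosage) <- df$variant_id
  all_missing <- colSums(!is.na(dosage)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing variant(s) dropped", call. = FALSE)
    dosage <- dosage[, !all_missing, drop = FALSE]
    df <- df[!all_missing, , drop = FALSE]
  }
  genotype_matrix(dosage,
                  data.frame(id = df$variant_id, chrom = df$chrom,
                             pos = df$pos, ref = df$ref, alt = df$alt))
}

#' Write a genotype matrix to TSV or minimal VCF 4.2
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param format `"tsv"` (dosage matrix with variant metadata columns) or
#'   `"vcf"` (GT-only VCF 4.2; dosage 1 is written as `0/1`).
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(gm, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (format == "tsv") {
    df <- data.frame(variant_id = gm$variants$id, chrom = gm$variants$chrom,
                     pos = gm$variants$pos, ref = gm$variants$ref,
                     alt = gm$variants$alt, check.names = FALSE)
    df <- cbind(df, as.data.frame(t(gm$dosage), check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    gt_code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = ncol(gm$dosage), ncol = nrow(gm$dosage))
    ok <- !is.na(t(gm$dosage))
    gt[ok] <- gt_code[t(gm$dosage)[ok] + 1L]
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", gm$samples), collapse = "\t"))
    body <- apply(cbind(gm$variants$chrom, gm$variants$pos, gm$variants$id,
                        gm$variants$ref, gm$variants$alt, ".", "PASS", ".",
                        "GT", gt), 1L, paste, collapse = "\t")
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Read a LeafCutter-style intron cluster count table
#'
#' Rows are keyed `chrom:start:end:cluID` (0-based half-open intron
#' coordinates), one count column per sample. Malformed row keys raise a
#' parse error with the offending line number.
#'
#' @param path Path to the counts TSV.
#' @return An [intron_cluster_table()].
#' @export
read_intron_clusters <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  keys <- as.character(df[[1]])
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop(sprintf("malformed intron key at line %d: '%s'",
                 bad[1] + 1L, keys[bad[1]]), call. = FALSE)
  introns <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                        start = as.integer(vapply(parts, `[`, "", 2L)),
                        end = as.integer(vapply(parts, `[`, "", 3L)),
                        cluster = vapply(parts, `[`, "", 4L))
  if (anyNA(introns$start) || anyNA(introns$end))
    stop("non-numeric intron coordinates in ", path, call. = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  intron_cluster_table(counts, introns)
}

#' Write an intron cluster count table
#'
#' @param ict An [intron_cluster_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_intron_clusters <- function(ict, path) {
  stopifnot(inherits(ict, "intron_cluster_table"))
  df <- data.frame(intron = rownames(ict$counts),
                   as.data.frame(ict$counts, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a phenotype matrix (traits x samples)
#'
#' TSV with trait ids in the first column and one column per sample. A
#' `# kind: <tag>` comment line records the trait kind (`expression` RPKM,
#' `splicing` PSI, or `chromatin` CPM) and round-trips through the reader.
#'
#' @param path File path.
#' @return `read_phenotypes()`: numeric matrix with attribute `kind`.
#' @export
read_phenotypes <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- NULL
  if (grepl("^# kind:", first)) kind <- trimws(sub("^# kind:", "", first))
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m)))
    stop("duplicate trait ids in ", path, call. = FALSE)
  attr(m, "kind") <- kind
  m
}

#' @rdname read_phenotypes
#' @param mat Numeric matrix, traits in rows, samples in columns.
#' @param kind Optional trait-kind tag stored as a comment line.
#' @export
write_phenotypes <- function(mat, path, kind = attr(mat, "kind")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(kind)) writeLines(paste0("# kind: ", kind), con)
  df <- data.frame(trait = rownames(mat),
                   as.data.frame(mat, check.names = FALSE), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write pairwise-aligned FASTA sequence pairs
#'
#' Pairs are stored as consecutive records named `<name>_a` / `<name>_b`;
#' the two gapped sequences of a pair must have equal length.
#'
#' @param path FASTA file path.
#' @return `read_aligned_fasta()`: named list of `pairwise_alignment`
#'   objects.
#' @export
read_aligned_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) %% 2L != 0L)
    stop("aligned FASTA must contain an even number of records", call. = FALSE)
  idx <- seq(1L, length(ss), by = 2L)
  out <- lapply(idx, function(i)
    pairwise_alignment(as.character(ss[[i]]), as.character(ss[[i + 1L]])))
  names(out) <- sub("_a$", "", names(ss)[idx])
  out
}

#' @rdname read_aligned_fasta
#' @param pairs Named list of `pairwise_alignment` objects (or two-element
#'   lists of equal-length sequences).
#' @export
write_aligned_fasta <- function(pairs, path) {
  if (is.null(names(pairs)))
    names(pairs) <- sprintf("pair%04d", seq_along(pairs))
  seqs <- unlist(lapply(pairs, function(p) c(p$seq1, p$seq2)))
  names(seqs) <- as.vector(rbind(paste0(names(pairs), "_a"),
                                 paste0(names(pairs), "_b")))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
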