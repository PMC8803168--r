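# Transcript classification relative to enhancer/promoter annotations,
# and identification of splice-site-disrupting variants.

#' Classify transcripts by the position of their 5' end
#'
#' A lncRNA whose strand-aware 5' terminus lies within `window` bp of an
#' enhancer is an elncRNA; otherwise, a 5' end within `window` bp of a
#' promoter makes it a plncRNA (lncRNA biotype) or a pcg (protein-coding
#' biotype). Distance is measured to the nearest interval edge and is 0
#' for overlap, so "within 500 bp" is inclusive of the boundary.
#' Enhancer proximity is tested before promoter proximity (dialect
#' choice: the elncRNA set is defined first, so a lncRNA TSS near both
#' annotations is called elncRNA). Enhancers to which no transcript was
#' assigned are returned as the eRNA-enhancer background class.
#' Transcripts on chromosomes absent from both annotation sets are
#' `unclassified` with a warning.
#'
#' @param transcripts A `transcript_set` (see [read_gtf()]) or list of
#'   [transcript_model()] objects.
#' @param enhancers,promoters BED-style data frames (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param window Maximum TSS-to-edge distance in bp (default 500).
#' @return A list of class `transcript_classification`: `transcripts`
#'   (data frame with `id`, `biotype`, `class`, `multi_exonic`) and
#'   `erna_enhancers` (the unassigned enhancers).
#' @export
classify_transcripts <- function(transcripts, enhancers, promoters,
                                 window = 500L) {
  stopifnot_scalar_number(window, "window", lower = 0)
  known_chroms <- unique(c(enhancers$chrom, promoters$chrom))
  enhancer_hit <- rep(FALSE, nrow(enhancers))
  rows <- lapply(transcripts, function(tx) {
    tss <- transcript_tss(tx)
    cls <- "unclassified"
    if (!tx$chrom %in% known_chroms) {
      warning(sprintf("transcript %s on unannotated chromosome %s",
                      tx$id, tx$chrom), call. = FALSE)
    } else {
      e <- which(enhancers$chrom == tx$chrom)
      e_near <- e[point_interval_distance(tss, enhancers$start[e],
                                          enhancers$end[e]) <= window]
      p <- which(promoters$chrom == tx$chrom)
      p_near <- any(point_interval_distance(tss, promoters$start[p],
                                            promoters$end[p]) <= window)
      if (tx$biotype == "lncRNA" && length(e_near)) {
        cls <- "elncRNA"
        enhancer_hit[e_near] <<- TRUE
      } else if (p_near) {
        cls <- if (tx$biotype == "protein_coding") "pcg" else "plncRNA"
      }
    }
    data.frame(id = tx$id, biotype = tx$biotype, class = cls,
               multi_exonic = tx$multi_exonic)
  })
  structure(list(transcripts = do.call(rbind, c(rows, make.row.names = FALSE)),
                 erna_enhancers = enhancers[!enhancer_hit, , drop = FALSE]),
            class = "transcript_classification")
}

#' @export
print.transcript_classification <- function(x, ...) {
  tab <- table(x$transcripts$class)
  cat("transcript_classification:\n")
  for (nm in names(tab)) cat(sprintf("  %-12s %d\n", nm, tab[[nm]]))
  cat(sprintf("  eRNA-enhancers: %d\n", nrow(x$erna_enhancers)))
  invisible(x)
}

#' Find variants disrupting elncRNA splice-site dinucleotides
#'
#' Returns variants whose position overlaps the GT donor dinucleotide
#' (first 2 intronic nt, 5' side of the intron in transcript orientation)
#' or AG acceptor dinucleotide (last 2 intronic nt) of any intron of a
#' multi-exonic transcript, strand-aware: on the minus strand the donor
#' dinucleotide sits at the genomic end of the intron. Variants on
#' contigs carrying no transcript are excluded silently.
#'
#' @param variants Data frame with columns `id`, `chrom`, `pos`
#'   (1-based position, VCF convention).
#' @param transcripts A `transcript_set` or list of [transcript_model()]
#'   objects; only multi-exonic entries are scanned (pass your elncRNA
#'   set).
#' @return Data frame with one row per (variant, transcript, intron) hit:
#'   `variant_id`, `transcript_id`, `site` (`"donor"`/`"acceptor"`),
#'   `intron_index`, `intron_start`, `intron_end`.
#' @export
find_splice_site_variants <- function(variants, transcripts) {
  hits <- list()
  for (tx in transcripts) {
    if (!tx$multi_exonic) next
    introns <- transcript_introns(tx)
    v <- variants[variants$chrom == tx$chrom, , drop = FALSE]
    if (nrow(v) == 0L) next
    pos0 <- v$pos - 1L  # 0-based
    for (i in seq_len(nrow(introns))) {
      s <- introns$start[i]; e <- introns$end[i]
      if (tx$strand == "+") {
        donor <- c(s, s + 1L); acceptor <- c(e - 2L, e - 1L)
      } else {
        donor <- c(e - 2L, e - 1L); acceptor <- c(s, s + 1L)
      }
      for (site in c("donor", "acceptor")) {
        at <- if (site == "donor") donor else acceptor
        hit <- which(pos0 %in% at)
        if (length(hit))
          hits[[length(hits) + 1L]] <- data.frame(
            variant_id = v$id[hit], transcript_id = tx$id, site = site,
            intron_index = i, intron_start = s, intron_end = e)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(variant_id = character(0), transcript_id = character(0),
                      site = character(0), intron_index = integer(0),
                      intron_start = integer(0), intron_end = integer(0)))
  do.call(rbind, c(hits, make.row.names = FALSE))
}
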