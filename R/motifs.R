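# Splice-site-flanking window extraction, hexamer scanning, and
# GC-content profiles.

#' Splicing-associated hexamer motif sets
#'
#' The U1 snRNP recognition set is the canonical {GGTAAG, GGTGAG, GTGAGT}
#' (DNA form). The shipped exonic-splicing-enhancer (ESE) sets are
#' deterministic purine-rich SYNTHETIC stand-ins for the published
#' 238-motif and 54-motif hexamer catalogues, which are external inputs:
#' supply the real lists via `hexamers` to reproduce a published scan.
#'
#' @param name `"U1"`, `"ESE238"` or `"ESE54"`.
#' @param hexamers Optional character vector of 6-mers overriding the
#'   named set (DNA alphabet, length 6 each).
#' @return Object of class `motif_set`: list with `name` and `hexamers`.
#' @export
motif_set <- function(name = c("U1", "ESE238", "ESE54"), hexamers = NULL) {
  name <- match.arg(name)
  if (is.null(hexamers)) {
    if (name == "U1") {
      hexamers <- c("GGTAAG", "GGTGAG", "GTGAGT")
    } else {
      file <- system.file("extdata",
                          sprintf("ese%s_synthetic_hexamers.txt",
                                  sub("ESE", "", name)),
                          package = "elsplice")
      hexamers <- readLines(file)
    }
  }
  hexamers <- toupper(hexamers)
  if (any(nchar(hexamers) != 6L) ||
      any(grepl("[^ACGT]", hexamers)))
    stop("motifs must be 6-mers over the DNA alphabet", call. = FALSE)
  structure(list(name = name, hexamers = unique(hexamers)),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("motif_set %s: %d hexamer(s)\n", x$name, length(x$hexamers)))
  invisible(x)
}

# Extract the transcript-orientation sequence of a genomic window
# [start, end) on the transcript's strand.
window_seq <- function(genome, chrom, start, end, strand) {
  seq <- subseq0(as.character(genome[[chrom]]), start, end)
  if (strand == "-") revcomp(seq) else seq
}

#' Extract splice-site-flanking scan windows
#'
#' ESE windows: for each internal exon longer than `min_exon` nt, the
#' `flank` exonic nucleotides adjacent to each of its two splice sites,
#' with the `mask` nt immediately adjacent to the splice site masked to
#' avoid splice-site-proximal composition bias. U1 windows: for each 5'
#' (donor) splice site, 3 exonic + 6 intronic nt. All sequences are
#' reported in transcript orientation (minus-strand windows are
#' reverse-complemented). Windows wider than their exon are truncated.
#'
#' @param tx A [transcript_model()].
#' @param genome Named list / `DNAStringSet` / character vector mapping
#'   chromosome names to sequences.
#' @param kind `"ESE"` or `"U1"`.
#' @param flank Exonic window width per side for ESE scans (default 50).
#' @param mask Number of splice-site-adjacent nt to mask (default 5).
#' @param min_exon Minimum internal-exon length, exclusive (default 100).
#' @return List of `scan_window` objects: `transcript`, `exon_index`,
#'   `site` (`"donor"`/`"acceptor"`), `seq`, `masked` (logical per nt),
#'   `effective_length` (unmasked nt).
#' @export
extract_windows <- function(tx, genome, kind = c("ESE", "U1"),
                            flank = 50L, mask = 5L, min_exon = 100L) {
  kind <- match.arg(kind)
  # exons in transcript order (constructor guarantees 5'->3')
  ex <- tx$exons
  n <- nrow(ex)
  windows <- list()
  add <- function(seq, masked, site, exon_index) {
    windows[[length(windows) + 1L]] <<- structure(
      list(transcript = tx$id, exon_index = exon_index, site = site,
           seq = seq, masked = masked,
           effective_length = sum(!masked)),
      class = "scan_window")
  }
  if (kind == "ESE") {
    if (n < 3L) return(windows)
    for (i in 2:(n - 1L)) {
      s <- ex[i, "start"]; e <- ex[i, "end"]
      width <- e - s
      if (width <= min_exon) next
      w <- min(flank, width)
      if (tx$strand == "+") {
        up <- window_seq(genome, tx$chrom, s, s + w, "+")     # acceptor side
        dn <- window_seq(genome, tx$chrom, e - w, e, "+")     # donor side
      } else {
        up <- window_seq(genome, tx$chrom, e - w, e, "-")
        dn <- window_seq(genome, tx$chrom, s, s + w, "-")
      }
      m <- min(mask, w)
      mask_up <- c(rep(TRUE, m), rep(FALSE, w - m))  # SS at window start
      mask_dn <- rev(mask_up)                        # SS at window end
      add(up, mask_up, "acceptor", i)
      add(dn, mask_dn, "donor", i)
    }
  } else {
    if (n < 2L) return(windows)
    for (i in 1:(n - 1L)) {
      # donor = 3' boundary of exon i in transcript orientation
      if (tx$strand == "+") {
        e <- ex[i, "end"]
        seq <- window_seq(genome, tx$chrom, e - 3L, e + 6L, "+")
      } else {
        s <- ex[i, "start"]
        seq <- window_seq(genome, tx$chrom, s - 6L, s + 3L, "-")
      }
      add(seq, rep(FALSE, nchar(seq)), "donor", i)
    }
  }
  windows
}

#' Count perfect hexamer matches in a scan window
#'
#' Every offset whose 6-mer equals a motif and overlaps no masked
#' position is counted; overlapping matches all count. `N` bases never
#' match; characters outside `{A,C,G,T,N}` are a data error. Density is
#' matches per unmasked (effective) nucleotide.
#'
#' @param window A `scan_window` from [extract_windows()].
#' @param motifs A [motif_set()].
#' @return List with `count` and `density`.
#' @export
scan_hexamers <- function(window, motifs) {
  stopifnot(inherits(motifs, "motif_set"))
  seq <- toupper(window$seq)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  L <- nchar(seq)
  count <- 0L
  if (L >= 6L) {
    for (off in 1:(L - 5L)) {
      if (any(window$masked[off:(off + 5L)])) next
      if (substr(seq, off, off + 5L) %in% motifs$hexamers)
        count <- count + 1L
    }
  }
  density <- if (window$effective_length > 0)
    count / window$effective_length else 0
  list(count = count, density = density)
}

#' Per-transcript hexamer density
#'
#' Convenience wrapper: extracts all windows of the requested kind for
#' each transcript and aggregates counts over windows; density is total
#' matches per total unmasked nt (additive over windows, invariant to
#' their order).
#'
#' @param transcripts `transcript_set` or list of [transcript_model()]s.
#' @param genome Chromosome sequences (as in [extract_windows()]).
#' @param motifs A [motif_set()].
#' @param kind `"ESE"` or `"U1"`; defaults to `"U1"` for the U1 set and
#'   `"ESE"` otherwise.
#' @param ... Passed to [extract_windows()].
#' @return Data frame: `id`, `n_windows`, `count`, `effective_length`,
#'   `density`.
#' @export
hexamer_density <- function(transcripts, genome, motifs, kind = NULL, ...) {
  if (is.null(kind)) kind <- if (motifs$name == "U1") "U1" else "ESE"
  rows <- lapply(transcripts, function(tx) {
    ws <- extract_windows(tx, genome, kind = kind, ...)
    count <- 0L; eff <- 0L
    for (w in ws) {
      count <- count + scan_hexamers(w, motifs)$count
      eff <- eff + w$effective_length
    }
    data.frame(id = tx$id, n_windows = length(ws), count = count,
               effective_length = eff,
               density = if (eff > 0) count / eff else NA_real_)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' GC-content profile of a multi-exonic transcript
#'
#' GC fraction of the first exon, of the remaining exons (concatenated),
#' of the introns (concatenated), and of flanking intergenic sequence of
#' matching total length after excluding the `gap` nt immediately
#' adjacent to the annotation: each flank mirrors the transcript span
#' length and the two flanks are pooled. Flanks running off the contig
#' are truncated with a warning.
#'
#' @param tx A multi-exonic [transcript_model()].
#' @param genome Chromosome sequences.
#' @param gap Excluded annotation-adjacent margin in nt (default 500).
#' @return Named numeric vector: `first_exon`, `other_exons`, `introns`,
#'   `flank`, each in `[0, 1]`.
#' @export
gc_profile <- function(tx, genome, gap = 500L) {
  if (!tx$multi_exonic)
    stop("gc_profile requires a multi-exonic transcript", call. = FALSE)
  chrom_seq <- as.character(genome[[tx$chrom]])
  clen <- nchar(chrom_seq)
  exon_seq <- function(i) subseq0(chrom_seq, tx$exons[i, "start"],
                                  tx$exons[i, "end"])
  first <- exon_seq(1L)
  others <- paste(vapply(2:tx$n_exons, exon_seq, ""), collapse = "")
  introns <- transcript_introns(tx)
  intr <- paste(vapply(seq_len(nrow(introns)), function(i)
    subseq0(chrom_seq, introns$start[i], introns$end[i]), ""), collapse = "")
  span <- tx$end - tx$start
  left <- c(tx$start - gap - span, tx$start - gap)
  right <- c(tx$end + gap, tx$end + gap + span)
  truncated <- left[1] < 0 || right[2] > clen
  if (truncated)
    warning(sprintf("flank of %s truncated at contig boundary", tx$id),
            call. = FALSE)
  left <- pmin(pmax(left, 0L), clen)
  right <- pmin(pmax(right, 0L), clen)
  flank <- paste0(subseq0(chrom_seq, left[1], left[2]),
                  subseq0(chrom_seq, right[1], right[2]))
  c(first_exon = gc_fraction(first), other_exons = gc_fraction(others),
    introns = gc_fraction(intr), flank = gc_fraction(flank))
}
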