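# Intron-centric splicing quantification: PSI per intron cluster, coSI
# per gene, the log10-modulus fold-difference statistic, and the
# splice-site-variant contrast panels.

#' Group introns into clusters sharing splice sites
#'
#' Connected components under the "shares a donor or acceptor
#' coordinate" relation: two introns on the same chromosome belong to
#' one cluster when they have a common start or a common end (an intron
#' ending where another begins is not linked). Singleton introns form
#' their own cluster.
#'
#' @param introns Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return The input with a `cluster` column (`"clu1"`, `"clu2"`, ... in
#'   order of first appearance).
#' @export
cluster_introns <- function(introns) {
  n <- nrow(introns)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  link_on <- function(key) {
    grp <- split(seq_len(n), key)
    for (g in grp) if (length(g) > 1L)
      for (k in seq_along(g)[-1]) union_(g[1], g[k])
  }
  link_on(paste(introns$chrom, introns$start, sep = ":"))
  link_on(paste(introns$chrom, introns$end, sep = ":"))
  roots <- vapply(seq_len(n), find, 0L)
  ids <- match(roots, unique(roots))
  introns$cluster <- sprintf("clu%d", ids)
  introns
}

#' Percent-spliced-in for one cluster's counts
#'
#' PSI of intron i in a sample is its junction count divided by the
#' cluster's total junction count in that sample; when the cluster total
#' falls below `min_cluster_reads` all PSI values of that sample are
#' missing (low-coverage filter, LeafCutter-style).
#'
#' @param counts Non-negative matrix (introns x samples) or vector (one
#'   sample) of junction counts for a single cluster.
#' @param min_cluster_reads Minimum cluster read total (default 10).
#' @return Matrix (or vector) of PSI values in `[0, 1]` or `NA`.
#' @examples
#' compute_psi(c(30, 10, 10), min_cluster_reads = 10)
#' @export
compute_psi <- function(counts, min_cluster_reads = 10) {
  vec <- is.null(dim(counts))
  m <- if (vec) matrix(counts, ncol = 1) else as.matrix(counts)
  if (any(m < 0, na.rm = TRUE)) stop("negative junction count", call. = FALSE)
  tot <- colSums(m)
  psi <- sweep(m, 2, tot, "/")
  psi[, tot < min_cluster_reads] <- NA_real_
  if (vec) psi[, 1] else psi
}

#' PSI matrix for a whole intron cluster table
#'
#' Applies [compute_psi()] cluster by cluster.
#'
#' @param ict An [intron_cluster_table()].
#' @param min_cluster_reads Minimum cluster read total (default 10).
#' @return Numeric matrix (introns x samples) with the table's row keys.
#' @export
psi_matrix <- function(ict, min_cluster_reads = 10) {
  stopifnot(inherits(ict, "intron_cluster_table"))
  out <- ict$counts * NA_real_
  for (cl in unique(ict$introns$cluster)) {
    idx <- which(ict$introns$cluster == cl)
    out[idx, ] <- compute_psi(ict$counts[idx, , drop = FALSE],
                              min_cluster_reads)
  }
  out
}

#' Completed splicing index (coSI)
#'
#' Per intron, coSI = j / (j + (b5 + b3)/2): junction-spanning reads over
#' junction plus boundary reads, the two exon-intron boundary counts
#' averaged to avoid double-counting. The gene-level coSI is the
#' read-weighted mean over introns (weights j + (b5 + b3)/2). Introns
#' with zero supporting reads are undefined and excluded.
#'
#' @param j Junction-spanning (exon-exon) read counts per intron.
#' @param b5,b3 Reads overlapping the 5' and 3' exon-intron boundaries.
#' @param gene Optional gene id for the record.
#' @return List of class `cosi_record`: `per_intron` coSI vector,
#'   `cosi` (gene-level), `junction_reads`, `boundary_reads`.
#' @examples
#' compute_cosi(j = 6, b5 = 2, b3 = 2)$cosi  # 0.75
#' @export
compute_cosi <- function(j, b5, b3, gene = NA_character_) {
  if (any(c(j, b5, b3) < 0)) stop("counts must be non-negative", call. = FALSE)
  w <- j + (b5 + b3) / 2
  per_intron <- ifelse(w > 0, j / w, NA_real_)
  ok <- !is.na(per_intron)
  cosi <- if (any(ok)) sum(per_intron[ok] * w[ok]) / sum(w[ok]) else NA_real_
  structure(list(gene = gene, cosi = cosi, per_intron = per_intron,
                 junction_reads = sum(j), boundary_reads = sum(b5 + b3)),
            class = "cosi_record")
}

#' @export
print.cosi_record <- function(x, ...) {
  cat(sprintf("coSI%s: %.4f (%d junction, %d boundary reads; %d intron(s))\n",
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              x$cosi, x$junction_reads, x$boundary_reads,
              length(x$per_intron)))
  invisible(x)
}

#' Log10-modulus fold difference versus a reference group
#'
#' For each value v, the fold difference relative to the reference-group
#' median m is fd = (v - m)/m (mode `"relative"`, the default) or
#' fd = v/m (mode `"ratio"`), transformed with the sign-preserving
#' log-modulus sign(fd) * log10(1 + |fd|). A zero or undefined reference
#' median makes the statistic undefined (all-NA result with a warning).
#'
#' @param values Numeric vector of per-sample trait values.
#' @param reference Values of the reference-genotype group (non-empty).
#' @param mode `"relative"` or `"ratio"` (see Details in the vignette).
#' @return Numeric vector of per-sample statistics.
#' @examples
#' log_modulus_fold_difference(c(1, 9, 0), reference = c(1, 1, 1))
#' @export
log_modulus_fold_difference <- function(values, reference,
                                        mode = c("relative", "ratio")) {
  mode <- match.arg(mode)
  if (length(reference) == 0L || all(is.na(reference)))
    stop("reference group is empty", call. = FALSE)
  m <- stats::median(reference, na.rm = TRUE)
  if (is.na(m) || m == 0) {
    warning("reference median is zero; statistic undefined", call. = FALSE)
    return(rep(NA_real_, length(values)))
  }
  fd <- if (mode == "relative") (values - m) / m else values / m
  sign(fd) * log10(1 + abs(fd))
}

#' Genotype-contrast panels around a splice-site variant
#'
#' For a splice-site variant, contrasts carriers of the alternative
#' allele (dosage > 0) against reference homozygotes (dosage 0) across
#' one or more trait panels (e.g. affected elncRNA PSI, target-gene PSI,
#' target/non-target/elncRNA RPKM, enhancer H3K4me1/H3K27ac CPM). Per
#' trait, every sample's log10-modulus fold difference is computed
#' against the reference-group median; the panel p-value is a two-tailed
#' Mann-Whitney U test of alternative-carrier versus reference statistics
#' pooled over the panel's traits.
#'
#' @param dosage Genotype dosages (0/1/2, NA allowed), one per sample.
#' @param panels Named list of numeric matrices (traits x samples, sample
#'   columns aligned with `dosage`) or numeric vectors (single trait).
#' @param min_group Minimum samples per genotype group with data for a
#'   trait to enter the panel (default 2); panels left with no usable
#'   trait are skipped with a warning.
#' @param mode Passed to [log_modulus_fold_difference()].
#' @return A list of class `ss_contrast`: `summary` data frame (panel,
#'   n_alt, n_ref, median statistic of the alternative group, MWU p) and
#'   `statistics` (per-panel lists of per-sample statistics).
#' @export
ss_variant_contrast <- function(dosage, panels, min_group = 2L,
                                mode = "relative") {
  ref <- which(!is.na(dosage) & dosage == 0)
  alt <- which(!is.na(dosage) & dosage > 0)
  if (length(ref) == 0L) stop("no reference-genotype samples", call. = FALSE)
  if (length(alt) == 0L) stop("no alternative-allele carriers", call. = FALSE)
  summaries <- list(); stats_out <- list()
  for (panel in names(panels)) {
    mat <- panels[[panel]]
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
    alt_stats <- numeric(0); ref_stats <- numeric(0)
    for (t in seq_len(nrow(mat))) {
      v <- mat[t, ]
      ok_ref <- ref[!is.na(v[ref])]; ok_alt <- alt[!is.na(v[alt])]
      if (length(ok_ref) < min_group || length(ok_alt) < min_group) next
      lm_stat <- suppressWarnings(
        log_modulus_fold_difference(v, v[ok_ref], mode = mode))
      alt_stats <- c(alt_stats, lm_stat[ok_alt])
      ref_stats <- c(ref_stats, lm_stat[ok_ref])
    }
    if (length(alt_stats) == 0L) {
      warning(sprintf("panel '%s' skipped: genotype group below %d samples",
                      panel, min_group), call. = FALSE)
      next
    }
    p <- suppressWarnings(
      stats::wilcox.test(alt_stats, ref_stats, alternative = "two.sided"))$p.value
    summaries[[panel]] <- data.frame(
      panel = panel, n_alt = length(alt_stats), n_ref = length(ref_stats),
      median_alt_statistic = stats::median(alt_stats, na.rm = TRUE),
      p_mwu = p)
    stats_out[[panel]] <- list(alt = alt_stats, ref = ref_stats)
  }
  structure(list(summary = do.call(rbind, c(summaries, make.row.names = FALSE)),
                 statistics = stats_out),
            class = "ss_contrast")
}

#' @export
print.ss_contrast <- function(x, ...) {
  cat("splice-site variant contrast:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Assign a splicing junction to the 5' or 3' end of its transcript
#'
#' Strand-aware: an intron whose midpoint falls in the first half of the
#' transcript span (along the direction of transcription) is a 5'-end
#' junction, otherwise 3'-end; a midpoint exactly at half is 5' by
#' convention.
#'
#' @param intron List or data frame row with `start`, `end` (0-based
#'   half-open), within the transcript span.
#' @param tx A [transcript_model()].
#' @return `"5prime"` or `"3prime"`.
#' @export
junction_end_position <- function(intron, tx) {
  if (intron$start < tx$start || intron$end > tx$end)
    stop("intron lies outside the transcript span", call. = FALSE)
  mid <- (intron$start + intron$end) / 2
  rel <- (mid - tx$start) / (tx$end - tx$start)
  if (tx$strand == "-") rel <- 1 - rel
  if (rel <= 0.5) "5prime" else "3prime"
}
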