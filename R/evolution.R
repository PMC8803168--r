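# Pairwise substitution-rate estimation, the matched ancestral-repeat
# permutation test of selective constraint, and derived-allele-frequency
# spectrum comparison.

#' Construct a pairwise alignment
#'
#' Two equal-length gapped sequences over `{A,C,G,T,-,N}` with cached
#' ungapped-site count and the GC fraction of the first (reference)
#' sequence.
#'
#' @param seq1,seq2 Aligned sequences (equal length).
#' @return Object of class `pairwise_alignment`: `seq1`, `seq2`,
#'   `ungapped_sites`, `gc`.
#' @export
pairwise_alignment <- function(seq1, seq2) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2))
    stop("aligned sequences must have equal length", call. = FALSE)
  if (grepl("[^ACGTN-]", seq1) || grepl("[^ACGTN-]", seq2))
    stop("alphabet must be {A,C,G,T,-,N}", call. = FALSE)
  ok <- alignment_site_mask(seq1, seq2)
  structure(list(seq1 = seq1, seq2 = seq2, ungapped_sites = sum(ok),
                 gc = gc_fraction(seq1)),
            class = "pairwise_alignment")
}

# Logical mask of comparable sites: both characters in {A,C,G,T}.
alignment_site_mask <- function(seq1, seq2) {
  a <- strsplit(seq1, "")[[1]]; b <- strsplit(seq2, "")[[1]]
  a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
}

alignment_mismatch_mask <- function(seq1, seq2) {
  a <- strsplit(seq1, "")[[1]]; b <- strsplit(seq2, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  ok & a != b
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: %d columns, %d comparable sites, GC %.3f\n",
              nchar(x$seq1), x$ungapped_sites, x$gc))
  invisible(x)
}

#' Concatenate pairwise alignments of one feature class
#'
#' Site order is preserved within and across features (input order).
#' Gapped or ambiguous columns are retained in the sequences and dropped
#' later by the distance estimator.
#'
#' @param alignments Non-empty list of [pairwise_alignment()] objects.
#' @return A single [pairwise_alignment()].
#' @export
concat_alignments <- function(alignments) {
  if (length(alignments) == 0L)
    stop("no alignments to concatenate", call. = FALSE)
  pairwise_alignment(
    paste(vapply(alignments, function(a) a$seq1, ""), collapse = ""),
    paste(vapply(alignments, function(a) a$seq2, ""), collapse = ""))
}

#' Pairwise nucleotide substitution rate
#'
#' `JC69`: closed form d = -(3/4) log(1 - (4/3) p) with p the mismatch
#' fraction over comparable (ungapped, unambiguous) sites; saturated
#' alignments (p >= 3/4) return `Inf`. `GTR`: two-sequence
#' maximum-likelihood distance under the general time-reversible model
#' with empirical base frequencies and exchangeabilities estimated from
#' the symmetrized pair-count matrix, the branch length optimized
#' numerically (for two taxa the REV tree degenerates to a single
#' branch).
#'
#' @param aln A [pairwise_alignment()].
#' @param model `"JC69"` or `"GTR"`.
#' @param min_sites Minimum comparable sites (default 50).
#' @return Estimated substitutions/site (>= 0).
#' @examples
#' a <- pairwise_alignment(strrep("ACGT", 25),
#'                         paste0("T", substr(strrep("ACGT", 25), 2, 100)))
#' substitution_rate(a)
#' @export
substitution_rate <- function(aln, model = c("JC69", "GTR"), min_sites = 50L) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "pairwise_alignment"))
  ok <- alignment_site_mask(aln$seq1, aln$seq2)
  n_sites <- sum(ok)
  if (n_sites < min_sites)
    stop(sprintf("only %d comparable sites (< %d)", n_sites, min_sites),
         call. = FALSE)
  a <- strsplit(aln$seq1, "")[[1]][ok]
  b <- strsplit(aln$seq2, "")[[1]][ok]
  p_hat <- mean(a != b)
  if (model == "JC69") return(jc69_distance(p_hat))
  gtr_distance(a, b)
}

jc69_distance <- function(p_hat) {
  if (p_hat >= 0.75) {
    warning("saturated alignment (p >= 3/4)", call. = FALSE)
    return(Inf)
  }
  -0.75 * log(1 - 4 / 3 * p_hat)
}

# Two-sequence ML distance under GTR. Exchangeabilities come from the
# symmetrized observed pair proportions; the likelihood in t is
# sum_ij N_ij log(pi_i P_ij(t)) with P(t) = exp(Qt) via the symmetric
# eigendecomposition of the reversible rate matrix.
gtr_distance <- function(a, b) {
  bases <- c("A", "C", "G", "T")
  N <- table(factor(a, bases), factor(b, bases))
  N <- (N + t(N)) / 2
  if (sum(N[upper.tri(N)]) == 0) return(0)
  pi_hat <- (rowSums(N) + colSums(N)) / (2 * sum(N))
  pi_hat <- pmax(pi_hat, 1e-6); pi_hat <- pi_hat / sum(pi_hat)
  M <- N / sum(N)
  S <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j)
    S[i, j] <- (M[i, j] + 1e-8) / (pi_hat[i] * pi_hat[j])
  Q <- S %*% diag(pi_hat)
  # reversible Q: S here is already symmetric; rebuild off-diagonals
  Q <- sweep(S, 2, pi_hat, "*")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale_f <- -sum(pi_hat * diag(Q))
  Q <- Q / scale_f
  # symmetric form B = D^{1/2} Q D^{-1/2}
  d_half <- sqrt(pi_hat)
  B <- diag(d_half) %*% Q %*% diag(1 / d_half)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- diag(1 / d_half) %*% eig$vectors
  Uinv <- t(eig$vectors) %*% diag(d_half)
  transition <- function(t) {
    P <- U %*% diag(exp(eig$values * t)) %*% Uinv
    pmax(P, 1e-12)
  }
  negll <- function(t) {
    P <- transition(t)
    -sum(N * log(pi_hat * P))
  }
  stats::optimize(negll, c(1e-8, 10))$minimum
}

#' Sample length- and GC-matched ancestral-repeat replicates
#'
#' For each feature segment and each of `n_reps` replicates, draws (with
#' replacement) an ancestral-repeat subsequence of identical length from
#' an AR lying within `locality` bp of the feature with AR-level GC
#' within `gc_tolerance`. When no AR qualifies for a segment the GC
#' tolerance widens stepwise (logged), then the locality doubles once;
#' segments still unmatched are dropped from all replicates (logged).
#'
#' @param features BED-style data frame (`chrom`, `start`, `end`, `gc`).
#' @param ar_catalog BED-style data frame for the AR segments (`chrom`,
#'   `start`, `end`, `gc`), rows aligned with the AR alignment list used
#'   downstream.
#' @param n_reps Number of replicate sets (default 1000).
#' @param locality Maximum feature-AR distance in bp (default 1 Mb).
#' @param gc_tolerance Absolute GC tolerance (default 0.02), widened in
#'   steps of the same size when needed.
#' @param seed Integer RNG seed.
#' @return List of class `ar_replicates`: `ar_index` and `offset`
#'   matrices (`n_reps` x kept features; offsets are 0-based starts of
#'   the sampled subsequence within the AR), `feature_index` (kept rows
#'   of `features`), `lengths`, `gc_tolerance_used` (per kept feature,
#'   after any widening), `dropped`.
#' @export
sample_matched_ars <- function(features, ar_catalog, n_reps = 1000L,
                               locality = 1e6, gc_tolerance = 0.02,
                               seed = 1L) {
  if (nrow(ar_catalog) == 0L) stop("AR catalog is empty", call. = FALSE)
  n_feat <- nrow(features)
  eligible <- vector("list", n_feat)
  tol_used <- rep(NA_real_, n_feat)
  dropped <- integer(0)
  for (i in seq_len(n_feat)) {
    len <- features$end[i] - features$start[i]
    find_ok <- function(tol, loc) {
      same <- ar_catalog$chrom == features$chrom[i]
      near <- pmax(ar_catalog$start - features$end[i],
                   features$start[i] - ar_catalog$end, 0) <= loc
      long <- (ar_catalog$end - ar_catalog$start) >= len
      gc_ok <- abs(ar_catalog$gc - features$gc[i]) <= tol
      which(same & near & long & gc_ok)
    }
    tol <- gc_tolerance; loc <- locality
    ok <- find_ok(tol, loc)
    while (length(ok) == 0L && tol < 0.5) {
      tol <- tol + gc_tolerance
      ok <- find_ok(tol, loc)
      if (length(ok))
        message(sprintf("feature %d: GC tolerance widened to %.2f", i, tol))
    }
    if (length(ok) == 0L) {
      loc <- loc * 2
      ok <- find_ok(tol, loc)
      if (length(ok))
        message(sprintf("feature %d: locality doubled to %g bp", i, loc))
    }
    if (length(ok) == 0L) {
      message(sprintf("feature %d: no eligible AR, dropped", i))
      dropped <- c(dropped, i)
    } else {
      tol_used[i] <- tol
    }
    eligible[[i]] <- ok
  }
  keep <- setdiff(seq_len(n_feat), dropped)
  if (length(keep) == 0L)
    stop("no feature could be matched to an ancestral repeat", call. = FALSE)
  lengths <- features$end[keep] - features$start[keep]
  with_seed(seed, {
    ar_index <- matrix(0L, n_reps, length(keep))
    offset <- matrix(0L, n_reps, length(keep))
    for (k in seq_along(keep)) {
      cand <- eligible[[keep[k]]]
      pick <- cand[sample.int(length(cand), n_reps, replace = TRUE)]
      ar_index[, k] <- pick
      room <- (ar_catalog$end - ar_catalog$start)[pick] - lengths[k]
      offset[, k] <- floor(stats::runif(n_reps) * (room + 1L))
    }
    structure(list(ar_index = ar_index, offset = offset,
                   feature_index = keep, lengths = lengths,
                   gc_tolerance_used = tol_used[keep], dropped = dropped),
              class = "ar_replicates")
  })
}

# Per-replicate substitution rates from sampled AR subsequences.
# Mismatch/site counts per AR are looked up through cumulative sums, so
# 1000 replicates cost one pass over the catalog.
ar_replicate_rates <- function(reps, ar_alignments, model = "JC69") {
  cs_mm <- lapply(ar_alignments, function(a) {
    c(0, cumsum(alignment_mismatch_mask(a$seq1, a$seq2)))
  })
  cs_ok <- lapply(ar_alignments, function(a) {
    c(0, cumsum(alignment_site_mask(a$seq1, a$seq2)))
  })
  n_reps <- nrow(reps$ar_index)
  mm <- matrix(0, n_reps, ncol(reps$ar_index))
  ok <- matrix(0, n_reps, ncol(reps$ar_index))
  for (k in seq_len(ncol(reps$ar_index))) {
    idx <- reps$ar_index[, k]
    o <- reps$offset[, k]
    len <- reps$lengths[k]
    for (ar in unique(idx)) {
      w <- idx == ar
      mm[w, k] <- cs_mm[[ar]][o[w] + len + 1L] - cs_mm[[ar]][o[w] + 1L]
      ok[w, k] <- cs_ok[[ar]][o[w] + len + 1L] - cs_ok[[ar]][o[w] + 1L]
    }
  }
  p <- rowSums(mm) / pmax(rowSums(ok), 1)
  vapply(p, function(pi) {
    if (pi >= 0.75) Inf else -0.75 * log(1 - 4 / 3 * pi)
  }, 0)
}

#' Permutation test of selective constraint against matched ARs
#'
#' One-tailed empirical test of whether the observed substitution rate is
#' lower than expected under neutrality:
#' p = (1 + #\{d_AR <= d_obs\}) / (1 + N) over the N completed matched
#' ancestral-repeat replicates (add-one rule, so the reportable floor at
#' 1000 replicates is ~1e-3). The relative rate d_obs / median(d_AR) is
#' reported alongside.
#'
#' @param d_obs Observed substitution rate of the concatenated motifs.
#' @param d_ar Numeric vector of replicate AR rates (>= 100 required).
#' @return Object of class `constraint_test`: `d_obs`, `relative_rate`,
#'   `p`, `n_reps`.
#' @export
constraint_test <- function(d_obs, d_ar) {
  d_ar <- d_ar[is.finite(d_ar)]
  if (length(d_ar) < 100L)
    stop("need >= 100 completed AR replicates", call. = FALSE)
  structure(list(d_obs = d_obs,
                 relative_rate = d_obs / stats::median(d_ar),
                 p = (1 + sum(d_ar <= d_obs)) / (1 + length(d_ar)),
                 n_reps = length(d_ar), d_ar = d_ar),
            class = "constraint_test")
}

#' @export
print.constraint_test <- function(x, ...) {
  cat(sprintf(paste0("constraint_test: d_obs = %.4f, relative rate = %.3f, ",
                     "empirical p = %.4g (%d AR replicates)\n"),
              x$d_obs, x$relative_rate, x$p, x$n_reps))
  invisible(x)
}

#' Full motif-versus-AR constraint analysis
#'
#' Concatenates the motif alignments, estimates their substitution rate,
#' builds `n_reps` GC/length-matched local AR replicate sets, and runs
#' the one-tailed permutation test.
#'
#' @param motif_alignments List of [pairwise_alignment()]s (one per motif
#'   segment).
#' @param motif_bed BED-style data frame for the motif segments
#'   (`chrom`, `start`, `end`, `gc`).
#' @param ar_alignments,ar_bed The AR catalog (aligned lists/rows).
#' @param n_reps Number of replicates (default 1000).
#' @param model Substitution model for the observed rate (default JC69;
#'   replicate rates always use the JC69 closed form for speed).
#' @param seed Integer RNG seed.
#' @param ... Passed to [sample_matched_ars()].
#' @return A `constraint_test` object.
#' @export
test_motif_constraint <- function(motif_alignments, motif_bed,
                                  ar_alignments, ar_bed,
                                  n_reps = 1000L, model = "JC69",
                                  seed = 1L, ...) {
  reps <- sample_matched_ars(motif_bed, ar_bed, n_reps = n_reps,
                             seed = seed, ...)
  kept <- reps$feature_index
  d_obs <- substitution_rate(concat_alignments(motif_alignments[kept]),
                             model = model)
  d_ar <- ar_replicate_rates(reps, ar_alignments)
  constraint_test(d_obs, d_ar)
}

#' Derived allele frequencies from ancestral-allele calls
#'
#' DAF is the population frequency of the non-ancestral allele:
#' `alt_freq` when the ancestral allele equals REF, `1 - alt_freq` when
#' it equals ALT. SNPs whose ancestral call matches neither observed
#' allele (or is missing) are dropped, with the count logged.
#'
#' @param snps Data frame with columns `id`, `ref`, `alt`, `ancestral`,
#'   `alt_freq`, and optionally `class`.
#' @return Data frame `id`, `class`, `daf`.
#' @export
daf_spectrum <- function(snps) {
  anc <- toupper(as.character(snps$ancestral))
  ref <- toupper(as.character(snps$ref)); alt <- toupper(as.character(snps$alt))
  daf <- ifelse(anc == ref, snps$alt_freq,
                ifelse(anc == alt, 1 - snps$alt_freq, NA_real_))
  drop <- is.na(daf)
  if (any(drop))
    message(sum(drop), " SNP(s) without usable ancestral call dropped")
  data.frame(id = snps$id[!drop],
             class = if (is.null(snps$class)) NA_character_
                     else snps$class[!drop],
             daf = daf[!drop])
}

#' Compare two DAF spectra for excess rare derived alleles
#'
#' Two-tailed Fisher's exact test on the 2x2 table of (DAF < threshold)
#' versus (DAF >= threshold) counts in the two classes. The reported
#' odds ratio is the sample cross-product ratio, with a Haldane
#' correction of 0.5 per cell when any cell is zero.
#'
#' @param daf_a,daf_b Numeric DAF vectors (non-empty) for the two classes.
#' @param threshold Rare-derived-allele cutoff (default 0.1).
#' @return List of class `daf_comparison`: `odds_ratio`, `p`, `table`.
#' @export
daf_compare <- function(daf_a, daf_b, threshold = 0.1) {
  if (length(daf_a) == 0L || length(daf_b) == 0L)
    stop("both DAF classes must be non-empty", call. = FALSE)
  tab <- rbind(a = c(low = sum(daf_a < threshold),
                     high = sum(daf_a >= threshold)),
               b = c(low = sum(daf_b < threshold),
                     high = sum(daf_b >= threshold)))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  t2 <- tab
  if (any(tab == 0)) t2 <- tab + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  structure(list(odds_ratio = unname(or), p = ft$p.value, table = tab),
            class = "daf_comparison")
}

#' @export
print.daf_comparison <- function(x, ...) {
  cat(sprintf("DAF comparison (low vs high): OR = %.3f, Fisher p = %.4g\n",
              x$odds_ratio, x$p))
  print(x$table)
  invisible(x)
}
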