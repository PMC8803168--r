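# Cis-QTL mapping with gene-level permutation calibration and BH FDR,
# target prediction by shared eQTLs, joint triplet assembly, and
# replication utilities.

#' Rank-based inverse-normal transform
#'
#' Maps a trait vector to standard-normal scores qnorm(rank/(n+1)) with
#' ties averaged, then centers to mean 0. Missing values are preserved.
#'
#' @param x Numeric vector with >= 3 non-missing values.
#' @return Numeric vector of the same length.
#' @export
rank_normalize <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) < 3L) stop("need >= 3 non-missing values", call. = FALSE)
  v <- x[obs]
  if (max(v) == min(v)) stop("constant trait vector", call. = FALSE)
  z <- stats::qnorm(rank(v, ties.method = "average") / (length(v) + 1))
  z <- z - mean(z)
  out <- rep(NA_real_, length(x))
  out[obs] <- z
  out
}

#' Filter variants by minor allele frequency
#'
#' Keeps variants with MAF strictly greater than `threshold` (a variant
#' at exactly 5% is dropped).
#'
#' @param gm A [genotype_matrix()].
#' @param threshold MAF cutoff (default 0.05).
#' @return A [genotype_matrix()] restricted to the retained variants.
#' @export
maf_filter <- function(gm, threshold = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- !is.na(gm$variants$maf) & gm$variants$maf > threshold
  if (!any(keep)) warning("no variant passes the MAF filter", call. = FALSE)
  genotype_matrix(gm$dosage[, keep, drop = FALSE],
                  gm$variants[keep, , drop = FALSE])
}

#' Cis association scan of one trait against its candidate variants
#'
#' Ordinary least squares of the rank-normalized trait on dosage, one
#' variant at a time: slope (trait SD units per allele), Pearson r, and
#' the two-tailed p-value from the t statistic. Variants with zero
#' genotype variance among the analysed samples are skipped.
#'
#' @param trait Numeric trait vector (one value per sample).
#' @param genotypes Dosage matrix (samples x variants) aligned with
#'   `trait`.
#' @param min_samples Minimum complete cases (default 20).
#' @param normalize Rank-normalize the trait first (default TRUE).
#' @return Data frame: `variant`, `slope`, `r`, `p`, `n`.
#' @export
cis_associate <- function(trait, genotypes, min_samples = 20L,
                          normalize = TRUE) {
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- sprintf("var%05d", seq_len(ncol(genotypes)))
  use <- which(!is.na(trait))
  if (length(use) < min_samples)
    stop(sprintf("only %d samples with trait data (< %d)",
                 length(use), min_samples), call. = FALSE)
  y <- if (normalize) rank_normalize(trait)[use] else trait[use]
  G <- genotypes[use, , drop = FALSE]
  sd_g <- apply(G, 2, stats::sd)
  keep <- which(sd_g > 0 & !is.na(sd_g))
  n <- length(use)
  r <- as.vector(stats::cor(y, G[, keep, drop = FALSE]))
  slope <- r * stats::sd(y) / sd_g[keep]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(variant = colnames(genotypes)[keep], slope = slope, r = r,
             p = p, n = n, row.names = NULL)
}

#' Gene-level permutation pass/fail for a cis scan
#'
#' Shuffles the trait across samples `n_perm` times; for each
#' permutation records the maximum absolute correlation over the cis
#' variants (r_max). The trait passes when its observed maximum absolute
#' correlation exceeds 95% of the permuted r_max values.
#'
#' @inheritParams cis_associate
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer RNG seed.
#' @param pass_quantile Fraction of r_max values the observed statistic
#'   must exceed (default 0.95).
#' @return List of class `permutation_verdict`: `pass`, `r_obs`,
#'   `exceed_frac`, `r_max` (the permutation distribution).
#' @export
gene_level_permutation <- function(trait, genotypes, n_perm = 1000L,
                                   seed = 1L, min_samples = 20L,
                                   pass_quantile = 0.95) {
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  genotypes <- as.matrix(genotypes)
  use <- which(!is.na(trait))
  if (length(use) < min_samples)
    stop(sprintf("only %d samples with trait data (< %d)",
                 length(use), min_samples), call. = FALSE)
  y <- rank_normalize(trait)[use]
  G <- genotypes[use, , drop = FALSE]
  sd_g <- apply(G, 2, stats::sd)
  G <- G[, sd_g > 0 & !is.na(sd_g), drop = FALSE]
  if (ncol(G) == 0L) stop("no polymorphic cis variant", call. = FALSE)
  n <- length(use)
  Gs <- scale(G)
  ys <- (y - mean(y)) / stats::sd(y)
  r_obs <- max(abs(crossprod(Gs, ys) / (n - 1)))
  with_seed(seed, {
    Y <- vapply(seq_len(n_perm), function(k) ys[sample.int(n)], numeric(n))
    R <- crossprod(Gs, Y) / (n - 1)           # variants x permutations
    r_max <- apply(abs(R), 2, max)
    exceed <- mean(r_max < r_obs)
    structure(list(pass = exceed >= pass_quantile, r_obs = r_obs,
                   exceed_frac = exceed, r_max = r_max),
              class = "permutation_verdict")
  })
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjustment (via [stats::p.adjust()]); the
#' significant set is `q < fdr`.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param fdr FDR level for the significance flag (default 0.05).
#' @return Data frame `p`, `q`, `significant`.
#' @export
bh_fdr <- function(p, fdr = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q, significant = !is.na(q) & q < fdr)
}

# Assign intervals (or point positions) to TADs by containment of the
# interval start (TSS-side anchor). Returns the TAD name or NA.
assign_tad <- function(chrom, pos, tads) {
  vapply(seq_along(pos), function(i) {
    hit <- which(tads$chrom == chrom[i] &
                   tads$start <= pos[i] & pos[i] < tads$end)
    if (length(hit)) as.character(tads$name[hit[1]]) else NA_character_
  }, "")
}

#' Map cis-QTLs for a phenotype matrix
#'
#' For each trait: restricts to variants in the trait's TAD (the
#' cis-window), runs [cis_associate()] on the rank-normalized trait,
#' applies the 1000-permutation gene-level threshold
#' ([gene_level_permutation()]), and adjusts the nominal p-values of the
#' trait's cis variants with Benjamini-Hochberg. A variant-trait pair is
#' a significant QTL when the trait passes its permutation threshold and
#' the pair's q-value is below `fdr`. Traits without a containing TAD are
#' skipped with a warning. Variants are MAF-filtered (> `maf`) first.
#'
#' @param phenotypes Numeric matrix, traits x samples.
#' @param gm A [genotype_matrix()] with sample rows aligned to the
#'   phenotype columns.
#' @param trait_pos Data frame with `trait`, `chrom`, `pos` anchoring
#'   each trait (e.g. the gene TSS or intron start).
#' @param tads BED-style data frame (`chrom`, `start`, `end`, `name`).
#' @param kind Trait-kind tag stored in the records (`"splicing"`,
#'   `"expression"`, `"chromatin"`).
#' @param n_perm,seed,fdr,maf,min_samples Tuning parameters (defaults
#'   1000, 1, 0.05, 0.05, 20).
#' @return Data frame of QTL records: `trait`, `variant`, `kind`, `tad`,
#'   `slope`, `r`, `p`, `q`, `perm_pass`, `significant`.
#' @export
map_qtls <- function(phenotypes, gm, trait_pos, tads, kind = "expression",
                     n_perm = 1000L, seed = 1L, fdr = 0.05, maf = 0.05,
                     min_samples = 20L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm <- maf_filter(gm, maf)
  var_tad <- assign_tad(gm$variants$chrom, gm$variants$pos - 1L, tads)
  out <- list()
  for (i in seq_len(nrow(trait_pos))) {
    trait_id <- trait_pos$trait[i]
    if (!trait_id %in% rownames(phenotypes)) next
    tad <- assign_tad(trait_pos$chrom[i], trait_pos$pos[i], tads)
    if (is.na(tad)) {
      warning(sprintf("trait %s has no containing TAD; skipped", trait_id),
              call. = FALSE)
      next
    }
    cis <- which(var_tad == tad)
    if (length(cis) == 0L) next
    trait <- phenotypes[trait_id, ]
    G <- gm$dosage[, cis, drop = FALSE]
    assoc <- cis_associate(trait, G, min_samples = min_samples)
    verdict <- gene_level_permutation(trait, G, n_perm = n_perm,
                                      seed = seed + i,
                                      min_samples = min_samples)
    adj <- bh_fdr(assoc$p, fdr = fdr)
    out[[length(out) + 1L]] <- data.frame(
      trait = trait_id, variant = assoc$variant, kind = kind, tad = tad,
      slope = assoc$slope, r = assoc$r, p = assoc$p, q = adj$q,
      perm_pass = verdict$pass,
      significant = verdict$pass & adj$significant)
  }
  if (length(out) == 0L)
    return(data.frame(trait = character(0), variant = character(0),
                      kind = character(0), tad = character(0),
                      slope = numeric(0), r = numeric(0), p = numeric(0),
                      q = numeric(0), perm_pass = logical(0),
                      significant = logical(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Predict elncRNA targets by shared eQTL variants
#'
#' An (elncRNA, protein-coding gene) pair is reported when the two genes
#' share a TAD and at least one variant is a significant eQTL for both.
#'
#' @param elnc_eqtls,pcg_eqtls QTL record data frames (from
#'   [map_qtls()]); only rows with `significant == TRUE` are used.
#' @return Data frame `elncrna`, `target`, `tad`, `n_shared_variants`.
#' @export
predict_targets <- function(elnc_eqtls, pcg_eqtls) {
  e <- elnc_eqtls[elnc_eqtls$significant, , drop = FALSE]
  g <- pcg_eqtls[pcg_eqtls$significant, , drop = FALSE]
  if (nrow(e) == 0L || nrow(g) == 0L)
    return(data.frame(elncrna = character(0), target = character(0),
                      tad = character(0), n_shared_variants = integer(0)))
  m <- merge(e[, c("trait", "variant", "tad")],
             g[, c("trait", "variant", "tad")],
             by = c("variant", "tad"), suffixes = c("_elnc", "_pcg"))
  if (nrow(m) == 0L)
    return(data.frame(elncrna = character(0), target = character(0),
                      tad = character(0), n_shared_variants = integer(0)))
  agg <- stats::aggregate(variant ~ trait_elnc + trait_pcg + tad, data = m,
                          FUN = function(v) length(unique(v)))
  data.frame(elncrna = agg$trait_elnc, target = agg$trait_pcg,
             tad = agg$tad, n_shared_variants = agg$variant)
}

#' Assemble joint seQTL/scQTL triplets
#'
#' A triplet (variant E, mediator trait A = elncRNA intron PSI, outcome
#' trait B = target RPKM or cognate-enhancer mark CPM) is formed when E
#' is a significant sQTL for A and a significant eQTL/cQTL for B, with B
#' belonging to a predicted target of A's elncRNA (expression mode) or to
#' its cognate enhancer (chromatin mode). Exclusion audit: E is flagged
#' (and excluded) when it is also a significant eQTL for the elncRNA
#' itself, or a significant sQTL for the target gene.
#'
#' @param sqtls sQTL records for elncRNA splicing traits (mediators).
#' @param outcome_qtls eQTL (or cQTL) records for the outcome traits.
#' @param pairs Data frame `elncrna`, `outcome` linking elncRNAs to their
#'   outcome traits (e.g. from [predict_targets()], with outcome trait
#'   ids in `outcome`).
#' @param splice_traits Data frame `trait`, `elncrna` mapping each
#'   splicing trait to its elncRNA.
#' @param elnc_eqtls Optional eQTL records for elncRNA expression
#'   (exclusion rule 1).
#' @param target_sqtls Optional sQTL records for outcome-gene splicing
#'   (exclusion rule 2); must carry an `elncrna`-style `trait` matching
#'   the outcome ids in `pairs`.
#' @return Data frame of class `joint_triplets`: `variant`,
#'   `mediator_trait`, `outcome_trait`, `elncrna`, `tad`,
#'   `excluded_elnc_eqtl`, `excluded_target_sqtl`, `included`.
#' @export
build_joint_triplets <- function(sqtls, outcome_qtls, pairs, splice_traits,
                                 elnc_eqtls = NULL, target_sqtls = NULL) {
  s <- sqtls[sqtls$significant, , drop = FALSE]
  o <- outcome_qtls[outcome_qtls$significant, , drop = FALSE]
  if (nrow(s) == 0L || nrow(o) == 0L) {
    empty <- data.frame(variant = character(0), mediator_trait = character(0),
                        outcome_trait = character(0), elncrna = character(0),
                        tad = character(0), excluded_elnc_eqtl = logical(0),
                        excluded_target_sqtl = logical(0), included = logical(0))
    class(empty) <- c("joint_triplets", "data.frame")
    return(empty)
  }
  s <- merge(s, splice_traits, by = "trait")
  m <- merge(s[, c("variant", "trait", "elncrna", "tad")],
             o[, c("variant", "trait")],
             by = "variant", suffixes = c("_med", "_out"))
  names(m)[names(m) == "trait_med"] <- "mediator_trait"
  names(m)[names(m) == "trait_out"] <- "outcome_trait"
  m <- merge(m, pairs, by.x = c("elncrna", "outcome_trait"),
             by.y = c("elncrna", "outcome"))
  excl1_keys <- if (!is.null(elnc_eqtls)) {
    e <- elnc_eqtls[elnc_eqtls$significant, , drop = FALSE]
    paste(e$variant, e$trait)
  } else character(0)
  excl2_keys <- if (!is.null(target_sqtls)) {
    t <- target_sqtls[target_sqtls$significant, , drop = FALSE]
    paste(t$variant, t$trait)
  } else character(0)
  m$excluded_elnc_eqtl <- paste(m$variant, m$elncrna) %in% excl1_keys
  m$excluded_target_sqtl <- paste(m$variant, m$outcome_trait) %in% excl2_keys
  m$included <- !m$excluded_elnc_eqtl & !m$excluded_target_sqtl
  out <- m[, c("variant", "mediator_trait", "outcome_trait", "elncrna",
               "tad", "excluded_elnc_eqtl", "excluded_target_sqtl",
               "included")]
  out <- out[order(out$variant, out$mediator_trait, out$outcome_trait), ]
  rownames(out) <- NULL
  class(out) <- c("joint_triplets", "data.frame")
  out
}

#' Convert an association Z-score to a regression slope
#'
#' slope = z / sqrt(2 f (1 - f) (n + z^2)), with f the variant allele
#' frequency and n the sample size (used to place summary-statistic
#' replication cohorts on the discovery slope scale).
#'
#' @param z Association Z-score.
#' @param f Allele frequency in (0, 1).
#' @param n Sample size (> 0).
#' @return Slope estimate (same sign as `z`).
#' @examples
#' zscore_to_slope(5, 0.3, 1000)
#' @export
zscore_to_slope <- function(z, f, n) {
  if (any(f <= 0 | f >= 1)) stop("allele frequency must be in (0, 1)",
                                 call. = FALSE)
  if (any(n <= 0)) stop("sample size must be positive", call. = FALSE)
  z / sqrt(2 * f * (1 - f) * (n + z^2))
}

#' Flag replicated associations in an independent cohort
#'
#' An association replicates when its BH-adjusted replication p-value is
#' below `fdr` and the replication effect (slope or Z-score) has the
#' same sign as the discovery slope.
#'
#' @param discovery Data frame with `key` (variant-trait identifier) and
#'   `slope`.
#' @param replication Data frame with `key`, `effect` (slope or Z) and
#'   `p`.
#' @param fdr BH threshold (default 0.05).
#' @return The merged data frame with `q` and `replicated` columns.
#' @export
replication_check <- function(discovery, replication, fdr = 0.05) {
  m <- merge(discovery, replication, by = "key")
  m$q <- stats::p.adjust(m$p, method = "BH")
  m$replicated <- m$q < fdr & sign(m$effect) == sign(m$slope) &
    m$effect != 0 & m$slope != 0
  m
}
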