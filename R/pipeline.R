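# End-to-end synthetic cohort study: simulate -> PSI -> QTL mapping ->
# joint triplets -> mediation classification -> report.

#' Run the full inference chain on a synthetic cohort
#'
#' Simulates a cohort of elncRNA loci, each in its own TAD with
#' `variants_per_tad` Hardy-Weinberg variants of which the first is a
#' planted sQTL acting on the logit-PSI of a two-intron cluster. A
#' planted fraction of loci follows the causal mediation model (target
#' expression driven by the realized splicing signal); the rest follow
#' the independent model (target expression driven by the variant
#' directly). The chain then runs with no knowledge of the planted
#' truth: PSI quantification, permutation-calibrated cis-sQTL/eQTL
#' mapping within TADs, joint triplet assembly, four-model mediation
#' classification, and the per-elncRNA causal summary.
#'
#' @param n_samples Cohort size (default 200).
#' @param n_elncrnas Number of elncRNA loci (default 50).
#' @param causal_fraction Planted fraction of causal loci (default 0.5).
#' @param variants_per_tad Cis-window width in variants (default 20).
#' @param maf_range Allele-frequency bounds (default `c(0.1, 0.5)`).
#' @param depth Mean junction reads per cluster per sample (default 50).
#' @param sqtl_effect Planted per-allele logit-PSI effect (default 1).
#' @param beta_AB Mediator-to-outcome (or direct variant-to-outcome)
#'   effect in outcome-SD units (default 0.7).
#' @param splicing_noise_sd Per-sample biological logit-PSI variability
#'   (default 0.8). This must dominate the junction-count sampling noise
#'   of the PSI assay (binomial SD ~0.07 at depth 50) for mediation to
#'   be identifiable; see the methods vignette.
#' @param outcome_noise_sd Outcome noise SD (default 1).
#' @param n_perm Permutations for the gene-level QTL threshold
#'   (default 1000).
#' @param n_perm_causal Permutations per mediation null (default 200).
#' @param lfdr_threshold Mediation decision threshold (default 0.1).
#' @param min_triplets Minimum triplet ensemble for classification
#'   (default 30: a 50-locus cohort can yield slightly fewer than 50
#'   triplets after significance gating).
#' @param seed Integer RNG seed for the whole study.
#' @return List of class `cohort_study`: `planted` (per-locus truth),
#'   `genotypes`, `psi`, `expression`, `sqtls`, `eqtls`, `triplets`,
#'   `calls`, `summary`, `planted_fraction`, `observed_causal_fraction`.
#' @examples
#' \donttest{
#' study <- simulate_cohort_study(n_samples = 120, n_elncrnas = 30,
#'                                n_perm = 200, seed = 7)
#' print(study)
#' }
#' @export
simulate_cohort_study <- function(n_samples = 200L, n_elncrnas = 50L,
                                  causal_fraction = 0.5,
                                  variants_per_tad = 20L,
                                  maf_range = c(0.1, 0.5), depth = 50,
                                  sqtl_effect = 1, beta_AB = 0.7,
                                  splicing_noise_sd = 0.8,
                                  outcome_noise_sd = 1,
                                  n_perm = 1000L, n_perm_causal = 200L,
                                  lfdr_threshold = 0.1, min_triplets = 30L,
                                  seed = 1L) {
  V <- variants_per_tad
  n_causal <- round(causal_fraction * n_elncrnas)
  planted <- data.frame(
    elncrna = sprintf("elnc%03d", seq_len(n_elncrnas)),
    model = rep(c("causal", "independent"),
                c(n_causal, n_elncrnas - n_causal)))
  cfg <- cohort_config(n_samples = n_samples,
                       n_variants = n_elncrnas * V,
                       maf_range = maf_range, seed = seed,
                       read_depth = depth)
  gm <- simulate_genotypes(cfg)
  tads <- data.frame(chrom = "chr1",
                     start = (seq_len(n_elncrnas) - 1L) * V * 1000L + 600L,
                     end = seq_len(n_elncrnas) * V * 1000L + 600L,
                     name = sprintf("tad%03d", seq_len(n_elncrnas)))
  psi_traits <- sprintf("psi_%s", planted$elncrna)
  expr_traits <- sprintf("target%03d", seq_len(n_elncrnas))
  psi_pheno <- matrix(NA_real_, n_elncrnas, n_samples,
                      dimnames = list(psi_traits, gm$samples))
  expr_pheno <- matrix(NA_real_, n_elncrnas, n_samples,
                       dimnames = list(expr_traits, gm$samples))
  with_seed(seed + 1L, {
    for (i in seq_len(n_elncrnas)) {
      causal_var <- (i - 1L) * V + 1L
      dosage <- gm$dosage[, causal_var]
      ict <- simulate_junction_counts(
        psi_base = c(0.5, 0.5), sqtl_effect = c(sqtl_effect, 0),
        dosage = dosage, depth = depth,
        seed = sample.int(.Machine$integer.max, 1L),
        noise_sd = splicing_noise_sd)
      psi_pheno[i, ] <- psi_matrix(ict)[1L, ]
      # the causal mediator is the realized splicing fraction itself
      psi1 <- attr(ict, "psi_true")[1L, ]
      driver <- if (planted$model[i] == "causal") psi1 else dosage
      expr_pheno[i, ] <- beta_AB * as.vector(scale(driver)) +
        stats::rnorm(n_samples, 0, outcome_noise_sd)
    }
  })
  anchor <- ((seq_len(n_elncrnas) - 1L) * V + 1L) * 1000L
  trait_pos_psi <- data.frame(trait = psi_traits, chrom = "chr1",
                              pos = anchor)
  trait_pos_expr <- data.frame(trait = expr_traits, chrom = "chr1",
                               pos = anchor + 100L)
  sqtls <- map_qtls(psi_pheno, gm, trait_pos_psi, tads, kind = "splicing",
                    n_perm = n_perm, seed = seed + 2L)
  eqtls <- map_qtls(expr_pheno, gm, trait_pos_expr, tads,
                    kind = "expression", n_perm = n_perm, seed = seed + 3L)
  pairs <- data.frame(elncrna = planted$elncrna, outcome = expr_traits)
  splice_traits <- data.frame(trait = psi_traits, elncrna = planted$elncrna)
  triplets <- build_joint_triplets(sqtls, eqtls, pairs, splice_traits)
  triplets <- triplets[triplets$included, , drop = FALSE]
  if (nrow(triplets) < min_triplets)
    stop(sprintf("only %d joint triplets survived QTL gating (< %d)",
                 nrow(triplets), min_triplets), call. = FALSE)
  # rank-normalize mediator and outcome traits (QTL-mapping convention);
  # residual missing PSI values (low-coverage samples) are mean-imputed
  fill_na <- function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x }
  prep <- function(x) fill_na(rank_normalize(x))
  E <- gm$dosage[, triplets$variant, drop = FALSE]
  A <- apply(psi_pheno[triplets$mediator_trait, , drop = FALSE], 1, prep)
  B <- apply(expr_pheno[triplets$outcome_trait, , drop = FALSE], 1, prep)
  trip_ids <- sprintf("jtrip%04d", seq_len(nrow(triplets)))
  colnames(E) <- colnames(A) <- colnames(B) <- trip_ids
  triplets$triplet <- trip_ids
  calls <- classify_triplets(E, A, B, lfdr_threshold = lfdr_threshold,
                             n_perm = n_perm_causal, seed = seed + 4L,
                             min_triplets = min_triplets)
  summ <- summarize_calls(calls,
                          triplet_map = triplets[, c("triplet", "elncrna")])
  tested <- unique(triplets$elncrna)
  structure(list(
    planted = planted, genotypes = gm, psi = psi_pheno,
    expression = expr_pheno, tads = tads, sqtls = sqtls, eqtls = eqtls,
    triplets = triplets, calls = calls, summary = summ,
    planted_fraction = n_causal / n_elncrnas,
    tested_elncrnas = tested,
    observed_causal_fraction = summ$elncrna_causal_fraction),
    class = "cohort_study")
}

#' @export
print.cohort_study <- function(x, ...) {
  cat("synthetic cohort study\n")
  cat(sprintf("  samples: %d, elncRNA loci: %d (planted causal fraction %.2f)\n",
              ncol(x$psi), nrow(x$planted), x$planted_fraction))
  cat(sprintf("  significant sQTL records: %d; eQTL records: %d\n",
              sum(x$sqtls$significant), sum(x$eqtls$significant)))
  cat(sprintf("  joint triplets classified: %d (%d elncRNAs)\n",
              nrow(x$calls), length(x$tested_elncrnas)))
  print(x$summary$by_model, row.names = FALSE)
  cat(sprintf("  causal-elncRNA fraction: %.2f (planted %.2f)\n",
              x$observed_causal_fraction, x$planted_fraction))
  invisible(x)
}
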