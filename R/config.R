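#' Cohort configuration for synthetic genotype/phenotype generation
#'
#' Bundles the parameters of a simulated genotyping cohort: sample size,
#' number of biallelic variants, the range from which per-variant minor
#' allele frequencies are drawn, the mean junction-read depth per intron
#' cluster, and the RNG seed. Genotypes are simulated under Hardy-Weinberg
#' equilibrium with no linkage disequilibrium (see
#' [simulate_genotypes()] for an optional tagged-copy mode).
#'
#' @param n_samples Number of individuals (>= 2).
#' @param n_variants Number of biallelic variants (>= 1).
#' @param maf_range Length-2 numeric, allele-frequency bounds in (0, 0.5].
#' @param seed Integer RNG seed.
#' @param read_depth Mean junction reads per intron cluster per sample (> 0).
#' @return An object of class `cohort_config`.
#' @examples
#' cohort_config(n_samples = 100, n_variants = 20)
#' @export
cohort_config <- function(n_samples = 373L, n_variants = 100L,
                          maf_range = c(0.05, 0.5), seed = 1L,
                          read_depth = 50) {
  stopifnot_scalar_number(n_samples, "n_samples", lower = 2)
  stopifnot_scalar_number(n_variants, "n_variants", lower = 1)
  stopifnot_scalar_number(read_depth, "read_depth", lower = .Machine$double.xmin)
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      any(is.na(maf_range)) || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("`maf_range` must be two frequencies in (0, 0.5] with low <= high",
         call. = FALSE)
  structure(
    list(n_samples = as.integer(n_samples),
         n_variants = as.integer(n_variants),
         maf_range = as.numeric(maf_range),
         seed = as.integer(seed),
         read_depth = as.numeric(read_depth)),
    class = "cohort_config")
}

#' Generative scenario for a mediation triplet
#'
#' Describes one of the four topologies relating a genetic variant E, a
#' mediator trait A (elncRNA splicing) and an outcome trait B (target
#' expression or enhancer chromatin mark):
#' \describe{
#'   \item{causal}{A = beta_EA*E + e1;  B = beta_AB*A + e2 (no direct E->B edge).}
#'   \item{reactive}{B = beta_EB*E + e1;  A = beta_AB*B + e2.}
#'   \item{independent}{A = beta_EA*E + e1;  B = beta_EB*E + e2, independent noise.}
#'   \item{undecided}{A = beta_EA*E + e1;  B = beta_AB*A + beta_EB*E + e2.}
#' }
#' Noise terms are independent Normal(0, noise_sd^2). Effects are in units
#' of trait SD per allele.
#'
#' @param model One of `"causal"`, `"reactive"`, `"independent"`, `"undecided"`.
#' @param beta_EA Genotype -> mediator effect.
#' @param beta_AB Mediator -> outcome (or outcome -> mediator, reactive) effect.
#' @param beta_EB Direct genotype -> outcome effect.
#' @param noise_sd Positive noise standard deviation.
#' @return An object of class `mediation_scenario`.
#' @export
mediation_scenario <- function(model, beta_EA = 0.7, beta_AB = 0.7,
                               beta_EB = 0.7, noise_sd = 1) {
  model <- match.arg(model, c("causal", "reactive", "independent", "undecided"))
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = .Machine$double.xmin)
  for (nm in c("beta_EA", "beta_AB", "beta_EB"))
    stopifnot_scalar_number(get(nm), nm)
  # Structural zeros implied by each topology
  if (model == "causal") beta_EB <- 0
  if (model == "independent") beta_AB <- 0
  if (model == "undecided" && (beta_EB == 0 || beta_AB == 0))
    stop("undecided model requires beta_EB != 0 and beta_AB != 0", call. = FALSE)
  structure(list(model = model, beta_EA = beta_EA, beta_AB = beta_AB,
                 beta_EB = beta_EB, noise_sd = noise_sd),
            class = "mediation_scenario")
}

#' Scenario for simulated human/mouse sequence-pair evolution
#'
#' Parameters of the two-lineage Jukes-Cantor simulation used to emulate
#' splice-motif sequences evolving under constraint next to neutrally
#' evolving ancestral repeats (ARs).
#'
#' @param neutral_rate Total pairwise divergence (substitutions/site)
#'   separating the two lineages at neutral sites. The human-mouse default
#'   of 0.5 is typical of ancestral-repeat divergence.
#' @param constraint_ratio Fraction in (0, 1] multiplying `neutral_rate`
#'   at constrained motif sites (1 = no constraint).
#' @param motif_length Length (nt) of each motif segment.
#' @param n_motif_segments Number of motif segments.
#' @param n_ar_segments Number of AR segments in the catalog.
#' @param ar_length Length (nt) of each AR segment (must be >= motif_length).
#' @param seed Integer RNG seed.
#' @return An object of class `evolution_scenario`.
#' @export
evolution_scenario <- function(neutral_rate = 0.5, constraint_ratio = 1,
                               motif_length = 24L, n_motif_segments = 30L,
                               n_ar_segments = 120L, ar_length = 240L,
                               seed = 1L) {
  stopifnot_scalar_number(neutral_rate, "neutral_rate", lower = 0)
  stopifnot_scalar_number(constraint_ratio, "constraint_ratio",
                          lower = .Machine$double.xmin, upper = 1)
  stopifnot_scalar_number(motif_length, "motif_length", lower = 1)
  stopifnot_scalar_number(n_motif_segments, "n_motif_segments", lower = 1)
  stopifnot_scalar_number(n_ar_segments, "n_ar_segments", lower = 1)
  stopifnot_scalar_number(ar_length, "ar_length", lower = motif_length)
  structure(
    list(neutral_rate = neutral_rate, constraint_ratio = constraint_ratio,
         motif_length = as.integer(motif_length),
         n_motif_segments = as.integer(n_motif_segments),
         n_ar_segments = as.integer(n_ar_segments),
         ar_length = as.integer(ar_length), seed = as.integer(seed)),
    class = "evolution_scenario")
}
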