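---
title: "Methods: from elncRNA splicing to enhancer activity"
author: "elsplice authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from elncRNA splicing to enhancer activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elsplice)
```

## The scientific question and the inference chain

Most active enhancers are transcribed. A minority produce stable,
unidirectional, often spliced long noncoding RNAs (elncRNAs) rather
than short bidirectional eRNAs, and enhancers transcribing multi-exonic
elncRNAs tend to be more active. The open question is directional: does
elncRNA *splicing* contribute to enhancer activity and target-gene
regulation, or is splicing a passive consequence of an already-active
enhancer?

`elsplice` implements the two complementary lines of evidence a
population-genomics cohort (RNA-seq + genotypes + optionally chromatin
marks) can provide:

1. **Selection on splicing signals.** If elncRNA splicing were
   transcriptional noise, its splice sites, exonic splicing enhancers
   (ESEs) and U1 snRNP binding motifs should evolve neutrally. The
   package measures substitution rates of these motifs between two
   diverged genomes and compares them with matched neutral sequence
   (local ancestral repeats), and contrasts derived-allele-frequency
   (DAF) spectra in the modern population.
2. **Genetic mediation.** Nucleotide variants that change elncRNA
   splicing are natural perturbation experiments. For variants jointly
   associated with elncRNA splicing and a downstream trait (target-gene
   expression or cognate-enhancer chromatin marks), a four-model causal
   inference test asks whether the splicing change *mediates* the
   downstream change.

## Transcript classes and splice-site variants

A transcript's class is decided by its strand-aware 5' terminus: a
lncRNA whose TSS lies within 500 bp (inclusive, distance 0 for overlap)
of an enhancer is an elncRNA; otherwise proximity to a promoter makes it
a plncRNA or a protein-coding gene by biotype; enhancers left without an
assigned transcript form the eRNA background class. Where a lncRNA TSS
is near both annotations the enhancer wins — the elncRNA set is defined
first; this tie-break is a documented dialect choice, as is measuring
distance symmetrically to the nearest interval edge.

Splice-site variants are SNPs overlapping the GT donor dinucleotide
(first two intronic nucleotides in transcript orientation) or the AG
acceptor dinucleotide (last two) of any intron of a multi-exonic
elncRNA. On the minus strand the donor dinucleotide sits at the
genomic *end* of the intron; the test suite pins this with
reverse-complement fixtures.

## Splicing quantification

**PSI** (intron-centric percent-spliced-in): within a cluster of
introns sharing splice sites, `PSI_i = n_i / sum(n)` per sample, with
all values missing when the cluster total falls below
`min_cluster_reads` (default 10, mirroring LeafCutter's low-coverage
filtering; the threshold is configurable). Clusters are connected
components of the "shares a donor or acceptor coordinate" relation —
an intron that merely starts where another ends is *not* linked.

**coSI** (completed splicing index): per intron,
`j / (j + (b5 + b3)/2)` — junction-spanning reads over junction plus
exon-intron boundary reads, the two boundaries averaged so each
incompletely spliced molecule is counted once. The gene value is the
read-weighted mean across introns. Both statistics are exactly
invariant under uniform integer scaling of counts.

**Genotype contrasts** (splice-site variant panels) transform each
sample's trait value to the log10-modulus fold difference versus the
reference-genotype median, `sign(fd) * log10(1 + |fd|)` with
`fd = (v - m)/m`. Whether the published dialect uses the relative
difference or the plain ratio `v/m` before the log-modulus is
ambiguous; the relative difference centers the reference group at 0 and
is the default, the ratio is exposed via `mode = "ratio"`. Panels are
compared with two-tailed Mann-Whitney U tests; under label permutation
the panel p-values are uniform (property-tested).

**Junction position.** A splicing junction is assigned to the 5' or 3'
end of its transcript by whether its midpoint falls in the first half
of the span along the direction of transcription; an exact-half
midpoint is 5' by convention (no threshold is stated for this split in
the source analyses, so the midpoint rule is ours).

## Motif scans and GC profiles

ESE scans use the 50 exonic nucleotides flanking each splice site of
internal exons longer than 100 nt, with the 5 nt adjacent to the splice
site masked to neutralize splice-site-proximal composition bias;
hexamer matches are exact, counted at every unmasked offset (overlaps
allowed), and densities divide by the unmasked (effective) length —
45 nt per window. U1 windows span 3 exonic + 6 intronic nt at 5' splice
sites, so any of the three canonical U1 hexamers can sit at any of the
four possible registers. All windows are reverse-complemented on the
minus strand, and all counts are invariant under
reverse-complementing the genome and flipping strands (property-tested).

The shipped 238- and 54-hexamer ESE lists are deterministic *synthetic*
stand-ins (purine-rich 6-mers, the 54 a subset of the 238): the real
published catalogues are external inputs and can be supplied via
`motif_set(hexamers = ...)`. The U1 set {GGTAAG, GGTGAG, GTGAGT} is the
canonical one.

GC profiles report the first exon, remaining exons, introns, and
flanking intergenic sequence of matching span length after excluding
the 500 nt adjacent to the annotation, pooled over both flanks.

## Substitution rates and the matched-AR permutation test

Motif alignments are concatenated per feature class and dated with
either the JC69 closed form `d = -(3/4) ln(1 - (4/3) p̂)` (saturating at
p̂ ≥ 3/4) or a two-sequence maximum-likelihood GTR distance: with two
taxa the reversible-model tree degenerates to a single branch, so the
package estimates empirical base frequencies and symmetrized
exchangeabilities from the pair counts and optimizes the branch length
numerically. On JC-generated data the GTR estimate collapses onto JC69
(tested to within 0.005 on 10-kb pairs).

The constraint test draws, 1000 times, a pseudo-motif set from
ancestral repeats within 1 Mb of each motif, of identical length and
matching GC (tolerance ±0.02, widening stepwise when no repeat
qualifies, then doubling the locality once, then dropping the segment —
each fallback logged and the effective tolerance reported). The
empirical p-value uses the add-one rule
`p = (1 + #{d_AR <= d_obs}) / (1 + N)`, one-tailed for *lower* observed
rates: the question is whether motifs accumulated *fewer* substitutions
than neutral sequence, and the add-one floor (~1e-3 at 1000 replicates)
matches the reportable floor of a 1000-permutation design. Calibration
is verified by simulation: ~5% rejection under neutrality, super-uniform
p-values, and essentially complete power at a 5-fold rate reduction.

GC matching operates on repeat-level GC: a subsequence of a
composition-homogeneous repeat has the repeat's expected GC, and the
replicate-mean GC concentrates accordingly. Matching every sampled
subsequence's realized GC individually would bias sampling toward
atypical windows of short repeats.

**DAF spectra.** Derived allele frequency polarizes each SNP by its
ancestral allele (SNPs whose ancestral call matches neither allele are
dropped and counted). Classes are compared on the 2x2 table of
DAF < 0.1 versus DAF ≥ 0.1 by two-tailed Fisher's exact test; the
reported odds ratio is the sample cross-product ratio (Haldane 0.5
correction on zero cells), not the conditional MLE.

## QTL mapping

Traits are transformed by the rank-based inverse-normal map
`qnorm(rank/(n+1))` (ties averaged, centered) — the convention of
standard QTL mappers; no expression covariates are used. Variants must
have MAF strictly above 5%. The cis-window is the trait's TAD. Per
trait, OLS of the transformed trait on dosage gives slope, r and a
two-tailed t-test p-value; trait-level significance requires the
observed max |r| to beat 95% of 1000 permutation maxima (r_max), and
variant-level significance additionally requires a Benjamini-Hochberg
q-value below 5% among the trait's cis variants. The permutation rule
is applied per gene, as stated. By construction the null pass rate is
5% (calibration-tested at 500 genes), and planted logit-PSI effects of
1.0 at n = 300, depth 50 are recovered essentially always.

Targets of an elncRNA are protein-coding genes in the same TAD sharing
a significant eQTL variant with it. Joint triplets (seQTLs/scQTLs) pair
a variant significant both as an elncRNA sQTL and as a target
eQTL/cQTL, excluding — with audit flags retained — variants that are
also eQTLs for the elncRNA itself (to decouple splicing from
expression) or sQTLs of the target. For summary-statistic replication
cohorts, `slope = z / sqrt(2 f (1-f) (n + z^2))`, and replication
requires BH-adjusted p < 5% *and* matching direction.

## Four-model mediation classification

For each triplet (E, A, B) the package computes Pearson and first-order
partial correlations with Fisher z-statistics
`z = atanh(r) * sqrt(n - k - 3)` and three composite scores:

- causal: `min(|z(E,B)|, |z(A,B|E)|) - |z(E,B|A)|` — both required
  associations present, the direct E-B edge vanishing given A;
- reactive: the A/B mirror;
- independent: `min(|z(E,A)|, |z(E,B)|) - |z(A,B|E)|` — both marginal
  associations present, no A-B edge beyond E.

The independent score uses *both* marginal associations so that
exchanging A and B maps causal to reactive scores exactly and fixes the
independent score — the exchange symmetry the classifier guarantees at
label level (and which the acceptance suite verifies bitwise). Null
score ensembles come from permuting B across samples (causal),
permuting A (reactive), and pooling both (independent), preserving the
E-A association that triplet construction guarantees and keeping the
whole procedure exchange-symmetric.

Each model's local false discovery rate is the two-group estimate
`lfdr(s) = pi0 f0(s) / f(s)` with Gaussian-kernel densities (Silverman
bandwidth) for the null (f0) and observed (f) ensembles and
`pi0 = min(1, 2 * frac(observed <= null median))`. Three numerical
choices matter and are deliberate:

- densities are evaluated *exactly* in log space (log-sum-exp over
  kernels): far beyond the null support a gridded KDE flattens into a
  clamp and every strong score of every model collapses to the same
  meaningless lfdr, making the argmin arbitrary;
- the test is one-sided — scores at or below the null median get
  lfdr 1, because a large *negative* score contradicts a model yet
  would also make the density ratio vanish;
- lfdr is made monotone non-increasing in the score by isotonic
  regression (on the log scale), and the winning model is the argmin of
  the *log*-lfdr among models below the 0.1 threshold; ties and empty
  candidate sets yield `undecided`.

With 500 triplets at n = 300 and standardized effects 0.7 (noise 1),
causal sensitivity is ~0.94 and the false-causal rate under the
independent model is ~0. Triplets generated under the *undecided*
topology (both a direct and a mediated edge) are typically absorbed
into the causal/reactive labels — partial-correlation mediation scores
are not consistent against the combined topology; this is a known
limitation shared by this family of tests, and the `undecided` label
functions as the abstention outcome rather than a detected class.
Classification requires an ensemble (≥ 50 triplets by default) because
the lfdr is estimated from the score distribution.

## The synthetic-cohort generator

Generators are pure functions of (configuration, seed); repeated calls
are byte-identical, and every stochastic routine takes an explicit
seed.

- **Genotypes**: Hardy-Weinberg Binomial(2, f) dosages, f uniform in
  the configured range; no linkage disequilibrium by default, with an
  optional tagged-copy mode (re-draw probability p) for best-variant
  sensitivity analyses.
- **Junction counts**: cluster totals Poisson(depth), intron counts
  multinomial with `softmax(qlogis(psi_base) + effect*dosage + noise)`
  — the planted sQTL acts on the logit-PSI scale. The latent linear
  predictor and the realized softmax PSI are exposed as attributes.
- **Mediation triplets**: the four generative topologies with
  configurable effects and Gaussian noise.
- **Sequence pairs**: two-lineage Jukes-Cantor divergence at the
  neutral rate for ancestral repeats and `rate * constraint_ratio` for
  motifs, with repeats anchored within 1 Mb of motifs and sharing their
  base composition so matched subsampling is feasible.
- **DAF tables**: the neutral 1/x site-frequency spectrum discretized
  on 100 bins; the constrained class mixes extra mass below 0.1 with
  the configured probability.

The end-to-end cohort (`simulate_cohort_study()`) plants one sQTL per
elncRNA locus in its own 20-variant TAD and generates the target trait
under the causal model (driven by the *realized splicing fraction*) for
a configurable fraction of loci and under the independent model for the
rest. Defaults: 200 samples, 50 loci, depth 50, per-allele logit effect
1.0, mediated/direct effect 0.7 SD, outcome noise SD 1, inter-individual
biological logit-PSI SD 0.8. The biological splicing variability must
dominate the PSI assay's counting noise (binomial SD ~0.07 at depth 50)
for mediation to be identifiable — at low depth or low biological
variance the E-B association survives conditioning on the measured
mediator and causal loci drift toward independent calls; this
attenuation is a real property of mediation analysis on noisy molecular
assays, not an artifact of the simulation. With the defaults the chain
recovers the planted causal-elncRNA fraction to within a few percentage
points (0.46 vs 0.50 at seed 1).

### What the simulations do and do not show

The generator emulates the statistical structure the inference chain
assumes: HWE genotypes without LD, a single causal variant per locus,
independent loci, Gaussian trait noise, Jukes-Cantor neutral evolution
and a clean 1/x neutral spectrum. Passing tests therefore demonstrate
correctness and calibration of the *methods*, not robustness to LD
(tag-variant confounding), population structure, shared batch effects,
imputation error, alignment artifacts, or selection models beyond a
uniform rate reduction. Real-data effect sizes for splicing QTLs are
not taken from any publication here — the planted values are free
parameters of the test harness.

## Problem sizes and runtimes

The test and acceptance workloads are sized for a single CPU: 1000
random PSI clusters; 10-kb GTR/JC69 pairs; 200 neutral + 50 constrained
constraint simulations with 1000 AR replicates each (20 motifs x 24 nt,
80 repeats x 240 nt); 500 null genes x 1000 permutations x 50 cis
variants plus 50 planted-recovery seeds at n = 300; 500 mediation
triplets per generative model with 200-permutation nulls; and one
200-sample, 50-locus cohort run. The full suite completes in about two
minutes; `scripts/acceptance.R` in about four.

## Known limitations

- The mediation classifier is a transparent partial-correlation /
  empirical-null construction with the same four-way output and
  lfdr < 0.1 decision rule as published Bayesian implementations; it
  does not reproduce any tool's posterior probabilities numerically.
- Junction counts are an input; the package does not extract them from
  alignments, and exon-centric (inclusion) PSI is out of scope.
- The pairwise GTR distance is a two-sequence ML estimate, not a
  tree-based fit; for two taxa these coincide up to parameterization.
- Chromatin-mode triplets reuse the expression-mode machinery with CPM
  traits; no chromatin-specific normalization is attempted.
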