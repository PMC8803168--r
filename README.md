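# elsplice

Does the splicing of enhancer-associated long noncoding RNAs (elncRNAs)
contribute to the activity of their cognate enhancers, or is it just a
by-product of transcription across highly accessible chromatin?
`elsplice` implements the full population-genomics inference chain that
addresses this question in an RNA-seq + genotyping cohort, for analysts
working with enhancer transcription, splicing QTLs, and molecular
mediation:

- **Annotation** — classify transcripts by the position of their
  strand-aware 5' end relative to enhancers and promoters (500-bp rule:
  elncRNA / plncRNA / protein-coding / eRNA-enhancer background), and
  locate variants disrupting GT/AG splice-site dinucleotides.
- **Splicing quantification** — intron-centric percent-spliced-in from
  LeafCutter-style intron clusters, PSI_i = n_i / Σ_cluster n, and the
  completed splicing index coSI = j / (j + (b5 + b3)/2) per intron
  (junction-spanning over junction-plus-boundary reads), read-weighted
  per gene; genotype contrasts use the log10-modulus fold difference
  sign(fd)·log10(1 + |fd|), fd = (v − median_ref)/median_ref, with
  two-tailed Mann-Whitney U tests.
- **Motifs** — ESE/U1 hexamer scans of splice-site-flanking windows
  (50 exonic nt of internal exons > 100 nt, 5 nt masked next to the
  splice site; 3 exonic + 6 intronic nt at 5' splice sites) and
  GC-content profiles.
- **Evolution** — pairwise substitution rates (JC69 closed form,
  d = −(3/4)·ln(1 − (4/3)·p̂), and a two-sequence maximum-likelihood
  GTR distance), a 1000-replicate permutation test against GC- and
  length-matched local ancestral repeats (ARs) with add-one empirical p,
  and derived-allele-frequency spectra compared by two-tailed Fisher's
  exact test on the DAF < 0.1 contrast.
- **QTL mapping** — rank-normalized OLS associations within TAD
  cis-windows, MAF > 5%, gene-level 1000-permutation r_max threshold
  (pass when r_obs beats 95% of permuted maxima), Benjamini-Hochberg
  FDR < 5%, target prediction by shared eQTLs, joint seQTL/scQTL
  triplet assembly with exclusion audits, and the Z-score-to-slope
  conversion slope = z / sqrt(2·f·(1 − f)·(n + z²)) for
  summary-statistic replication.
- **Causal mediation** — four-model classification (causal / reactive /
  independent / undecided) of each (variant E, elncRNA splicing A,
  target or chromatin trait B) triplet from Fisher-z partial-correlation
  scores against permutation nulls, decided at local FDR < 0.1.
- **Synthetic cohorts** — generators with planted genotype, splicing,
  mediation, substitution-rate and DAF structure, so every step above is
  testable without any data download.

## Worked example

Simulate a 200-sample cohort of 50 elncRNA loci, half of them with
target expression causally driven by the realized splicing fraction,
then run the blind inference chain (PSI → sQTL/eQTL mapping → joint
triplets → mediation classification):

```r
library(elsplice)
study <- simulate_cohort_study(n_samples = 200, n_elncrnas = 50,
                               causal_fraction = 0.5, seed = 1)
print(study)
#> synthetic cohort study
#>   samples: 200, elncRNA loci: 50 (planted causal fraction 0.50)
#>   significant sQTL records: 53; eQTL records: 49
#>   joint triplets classified: 46 (46 elncRNAs)
#>        model  n proportion
#>       causal 21 0.45652174
#>     reactive  0 0.00000000
#>  independent 24 0.52173913
#>    undecided  1 0.02173913
#>   causal-elncRNA fraction: 0.46 (planted 0.50)
```

46 of the 50 loci survive QTL significance gating; the classifier calls
a causal-elncRNA fraction of 0.46 against the planted 0.50 — the chain
recovers the planted mediation structure with the expected slight
conservatism (mediation tests trade sensitivity for a controlled
false-causal rate, here 0/24 among independent loci mislabelled).

Individual steps are exported too, e.g.:

```r
compute_psi(c(30, 10, 10))            # 0.6 0.2 0.2
compute_cosi(6, 2, 2)$cosi            # 0.75
zscore_to_slope(5, 0.3, 1000)         # 0.240981
```

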