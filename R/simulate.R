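# Synthetic-cohort generators. Every generator is a pure function of its
# configuration and seed: repeated calls return identical objects.

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws one allele frequency per variant uniformly within
#' `cfg$maf_range`, then per-sample dosages as Binomial(2, f). No linkage
#' disequilibrium is simulated by default; `ld_tag` appends, for each of
#' the first `ld_tag$n` variants, a tagged copy whose genotype is re-drawn
#' from the population frequency with probability `ld_tag$flip_prob`
#' (supporting best-variant sensitivity analyses).
#'
#' @param cfg A [cohort_config()].
#' @param ld_tag Optional list with elements `n` and `flip_prob`.
#' @return A [genotype_matrix()].
#' @examples
#' gm <- simulate_genotypes(cohort_config(n_samples = 50, n_variants = 10))
#' dim(gm$dosage)
#' @export
simulate_genotypes <- function(cfg, ld_tag = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    f <- stats::runif(cfg$n_variants, cfg$maf_range[1], cfg$maf_range[2])
    dosage <- matrix(stats::rbinom(cfg$n_samples * cfg$n_variants, 2L,
                                   rep(f, each = cfg$n_samples)),
                     nrow = cfg$n_samples, ncol = cfg$n_variants)
    rownames(dosage) <- sprintf("S%04d", seq_len(cfg$n_samples))
    colnames(dosage) <- sprintf("var%05d", seq_len(cfg$n_variants))
    variants <- data.frame(id = colnames(dosage), chrom = "chr1",
                           pos = seq_len(cfg$n_variants) * 1000L,
                           ref = "A", alt = "G")
    if (!is.null(ld_tag)) {
      n_tag <- min(ld_tag$n, cfg$n_variants)
      p_flip <- ld_tag$flip_prob
      tag <- dosage[, seq_len(n_tag), drop = FALSE]
      redraw <- matrix(stats::runif(cfg$n_samples * n_tag) < p_flip,
                       nrow = cfg$n_samples)
      fresh <- matrix(stats::rbinom(cfg$n_samples * n_tag, 2L,
                                    rep(f[seq_len(n_tag)], each = cfg$n_samples)),
                      nrow = cfg$n_samples)
      tag[redraw] <- fresh[redraw]
      colnames(tag) <- sprintf("tag%05d", seq_len(n_tag))
      tag_variants <- data.frame(id = colnames(tag), chrom = "chr1",
                                 pos = seq_len(n_tag) * 1000L + 1L,
                                 ref = "A", alt = "G")
      dosage <- cbind(dosage, tag)
      variants <- rbind(variants, tag_variants)
    }
    genotype_matrix(dosage, variants)
  })
}

#' Simulate (E, A, B) mediation triplets
#'
#' Generates `n_triplets` independent triplets of genotype E, mediator
#' trait A and outcome trait B under one of the four mediation topologies
#' (see [mediation_scenario()]). Each triplet gets its own variant with
#' allele frequency drawn from `cfg$maf_range`.
#'
#' @param n_triplets Number of triplets.
#' @param scenario A [mediation_scenario()].
#' @param cfg A [cohort_config()] (supplies `n_samples`, `maf_range`, `seed`).
#' @return A list of class `mediation_triplets` with numeric matrices
#'   `E`, `A`, `B` (samples x triplets) and the scenario.
#' @examples
#' trip <- simulate_mediation_triplets(5, mediation_scenario("causal"),
#'                                     cohort_config(n_samples = 100))
#' @export
simulate_mediation_triplets <- function(n_triplets, scenario, cfg) {
  stopifnot(inherits(scenario, "mediation_scenario"),
            inherits(cfg, "cohort_config"))
  stopifnot_scalar_number(n_triplets, "n_triplets", lower = 1)
  n <- cfg$n_samples
  with_seed(cfg$seed, {
    f <- stats::runif(n_triplets, cfg$maf_range[1], cfg$maf_range[2])
    E <- matrix(stats::rbinom(n * n_triplets, 2L, rep(f, each = n)), nrow = n)
    noise <- function() matrix(stats::rnorm(n * n_triplets, 0, scenario$noise_sd),
                               nrow = n)
    e1 <- noise(); e2 <- noise()
    A <- B <- NULL
    switch(scenario$model,
      causal = {
        A <- scenario$beta_EA * E + e1
        B <- scenario$beta_AB * A + e2
      },
      reactive = {
        B <- scenario$beta_EB * E + e1
        A <- scenario$beta_AB * B + e2
      },
      independent = {
        A <- scenario$beta_EA * E + e1
        B <- scenario$beta_EB * E + e2
      },
      undecided = {
        A <- scenario$beta_EA * E + e1
        B <- scenario$beta_AB * A + scenario$beta_EB * E + e2
      })
    dimnames(E) <- dimnames(A) <- dimnames(B) <-
      list(sprintf("S%04d", seq_len(n)), sprintf("trip%04d", seq_len(n_triplets)))
    structure(list(E = E, A = A, B = B, scenario = scenario),
              class = "mediation_triplets")
  })
}

#' Simulate junction counts for one intron cluster
#'
#' Per sample, the cluster read total is Poisson(`depth`) and intron
#' counts are Multinomial with probabilities
#' `softmax(qlogis(psi_base) + sqtl_effect * dosage + noise)`, planting a
#' splicing QTL whose per-allele effect acts on the logit-PSI scale.
#' An optional per-sample Gaussian logit-scale noise (`noise_sd`) models
#' inter-individual splicing variability beyond the genotype.
#'
#' @param psi_base Baseline PSI per intron; must sum to 1.
#' @param sqtl_effect Per-allele effect on logit PSI; recycled across
#'   introns (give a vector to target specific introns, e.g. `c(1, 0)`).
#' @param dosage Integer vector of genotype dosages (one per sample).
#' @param depth Mean cluster read total per sample (>= 0; 0 gives all-zero
#'   counts, which downstream PSI flags as missing).
#' @param seed Integer RNG seed.
#' @param noise_sd Per-sample logit-scale noise SD (default 0).
#' @param introns Optional data frame `chrom`, `start`, `end` (0-based
#'   half-open) for the member introns; a shared-donor default is built
#'   otherwise.
#' @param cluster_id Cluster identifier for the row keys.
#' @return An [intron_cluster_table()]; attribute `"logit_psi"` holds the
#'   latent introns x samples logit-scale linear predictor and
#'   `"psi_true"` the corresponding softmax inclusion probabilities
#'   (the noise-free PSI each sample's counts are drawn around).
#' @export
simulate_junction_counts <- function(psi_base, sqtl_effect, dosage, depth,
                                     seed = 1L, noise_sd = 0,
                                     introns = NULL, cluster_id = "clu1") {
  psi_base <- as.numeric(psi_base)
  if (any(psi_base <= 0) || abs(sum(psi_base) - 1) > 1e-8)
    stop("`psi_base` must be a strictly positive simplex (sums to 1)",
         call. = FALSE)
  stopifnot_scalar_number(depth, "depth", lower = 0)
  k <- length(psi_base)
  n <- length(dosage)
  eff <- rep_len(as.numeric(sqtl_effect), k)
  if (is.null(introns)) {
    introns <- data.frame(chrom = "chr1", start = 1000L,
                          end = 2000L + 1000L * seq_len(k))
  }
  introns$cluster <- cluster_id
  with_seed(seed, {
    eta <- qlogis(psi_base) + outer(eff, dosage)          # introns x samples
    if (noise_sd > 0)
      eta <- eta + matrix(stats::rnorm(k * n, 0, noise_sd), nrow = k)
    totals <- stats::rpois(n, depth)
    probs <- apply(eta, 2, softmax)
    counts <- vapply(seq_len(n), function(s) {
      if (totals[s] == 0L) return(integer(k))
      as.integer(stats::rmultinom(1, totals[s], probs[, s]))
    }, integer(k))
    counts <- matrix(counts, nrow = k)
    out <- intron_cluster_table(counts, introns)
    attr(out, "logit_psi") <- eta
    attr(out, "psi_true") <- probs
    out
  })
}

# Two-lineage Jukes-Cantor descendant pair: mutate an ancestor along two
# branches of length t/2 each so the pair diverges by t substitutions/site.
jc_pair <- function(ancestor, t) {
  bases <- c("A", "C", "G", "T")
  mutate <- function(chars, branch) {
    p_change <- 0.75 * (1 - exp(-4 / 3 * branch))
    hit <- stats::runif(length(chars)) < p_change
    if (any(hit)) {
      cur <- chars[hit]
      # uniform choice among the three other bases
      pick <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), "")
      chars[hit] <- pick
    }
    chars
  }
  anc <- strsplit(ancestor, "")[[1]]
  list(seq1 = paste(mutate(anc, t / 2), collapse = ""),
       seq2 = paste(mutate(anc, t / 2), collapse = ""))
}

random_dna <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Simulate aligned motif/ancestral-repeat sequence pairs
#'
#' Emulates splice-motif sequences evolving under constraint next to
#' neutrally evolving ancestral repeats (ARs): ancestor sequences are
#' mutated independently along two lineages under Jukes-Cantor, at
#' `neutral_rate` for ARs and `neutral_rate * constraint_ratio` for
#' motifs. AR segments are placed within 1 Mb of a motif anchor and drawn
#' with the anchor's base composition, so GC- and length-matched
#' subsampling is always feasible.
#'
#' @param scn An [evolution_scenario()].
#' @return A list of class `evo_simulation` with elements `motifs` /
#'   `ars` (lists of `pairwise_alignment` objects) and `motif_bed` /
#'   `ar_bed` (BED-style data frames with a `gc` column).
#' @export
simulate_sequence_pairs <- function(scn) {
  stopifnot(inherits(scn, "evolution_scenario"))
  with_seed(scn$seed, {
    chrom <- "chr1"
    gap <- 5000L
    m <- scn$n_motif_segments
    gc0 <- stats::runif(m, 0.35, 0.6)
    motif_start <- seq_len(m) * gap
    motifs <- vector("list", m)
    for (i in seq_len(m)) {
      anc <- random_dna(scn$motif_length, gc0[i])
      pr <- jc_pair(anc, scn$neutral_rate * scn$constraint_ratio)
      motifs[[i]] <- pairwise_alignment(pr$seq1, pr$seq2)
    }
    motif_bed <- data.frame(chrom = chrom, start = motif_start,
                            end = motif_start + scn$motif_length,
                            name = sprintf("motif%03d", seq_len(m)),
                            gc = vapply(motifs, function(a) a$gc, 0))
    a <- scn$n_ar_segments
    anchor <- sample.int(m, a, replace = TRUE)
    offset <- sample(c(-1L, 1L), a, replace = TRUE) *
      sample.int(5e5, a, replace = TRUE)
    ar_start <- pmax(motif_start[anchor] + offset, 1L)
    ars <- vector("list", a)
    for (i in seq_len(a)) {
      anc <- random_dna(scn$ar_length, gc0[anchor[i]])
      pr <- jc_pair(anc, scn$neutral_rate)
      ars[[i]] <- pairwise_alignment(pr$seq1, pr$seq2)
    }
    ar_bed <- data.frame(chrom = chrom, start = ar_start,
                         end = ar_start + scn$ar_length,
                         name = sprintf("AR%03d", seq_len(a)),
                         gc = vapply(ars, function(x) x$gc, 0))
    structure(list(motifs = motifs, motif_bed = motif_bed,
                   ars = ars, ar_bed = ar_bed, scenario = scn),
              class = "evo_simulation")
  })
}

#' Simulate derived-allele-frequency tables under neutrality and constraint
#'
#' The neutral class follows the standard 1/x site-frequency spectrum
#' discretized on `n_bins` bins over (0, 1); the constrained class draws,
#' with probability `constrained_shift`, from the sub-0.1 part of that
#' spectrum instead (excess rare derived alleles under purifying
#' selection), and from the neutral spectrum otherwise.
#'
#' @param n_neutral,n_constrained Number of SNPs per class.
#' @param constrained_shift Extra low-frequency mass in `[0, 1)`;
#'   0 makes the two classes exchangeable.
#' @param n_bins Number of spectrum bins (default 100).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `snp_id`, `class`
#'   (`"neutral"`/`"constrained"`) and `daf` in (0, 1).
#' @export
simulate_daf_table <- function(n_neutral, n_constrained, constrained_shift = 0,
                               n_bins = 100L, seed = 1L) {
  stopifnot_scalar_number(constrained_shift, "constrained_shift",
                          lower = 0, upper = 1 - 1e-9)
  with_seed(seed, {
    centers <- (seq_len(n_bins) - 0.5) / n_bins
    w <- (1 / centers) / sum(1 / centers)
    draw <- function(n, weights) {
      bin <- sample.int(n_bins, n, replace = TRUE, prob = weights)
      (bin - stats::runif(n)) / n_bins
    }
    low <- centers < 0.1
    w_low <- ifelse(low, w, 0)
    daf_neutral <- draw(n_neutral, w)
    from_low <- stats::runif(n_constrained) < constrained_shift
    daf_constr <- ifelse(from_low,
                         draw(n_constrained, w_low / sum(w_low)),
                         draw(n_constrained, w))
    data.frame(
      snp_id = sprintf("snp%05d", seq_len(n_neutral + n_constrained)),
      class = rep(c("neutral", "constrained"), c(n_neutral, n_constrained)),
      daf = c(daf_neutral, daf_constr))
  })
}
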