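test_that("alignment container validates and concatenates in order", {
  expect_error(pairwise_alignment("ACGT", "ACG"), "equal length")
  expect_error(pairwise_alignment("ACGT", "ACGZ"), "alphabet")
  a <- pairwise_alignment("ACG-T", "ACGNT")
  expect_equal(a$ungapped_sites, 4)
  b <- pairwise_alignment("GG", "GC")
  cc <- concat_alignments(list(a, b))
  expect_equal(cc$seq1, "ACG-TGG")
  expect_equal(cc$ungapped_sites, a$ungapped_sites + b$ungapped_sites)
  expect_error(concat_alignments(list()), "no alignments")
})

test_that("JC69 distance matches the closed form and saturates", {
  expect_equal(substitution_rate(make_aln_with_p(1000, 0)), 0)
  d <- substitution_rate(make_aln_with_p(1000, 100))
  expect_equal(d, -0.75 * log(1 - 4 / 3 * 0.1), tolerance = 1e-10)
  expect_equal(d, 0.10732, tolerance = 1e-4)
  expect_warning(dd <- substitution_rate(make_aln_with_p(1000, 800)),
                 "saturated")
  expect_equal(dd, Inf)
  expect_error(substitution_rate(make_aln_with_p(30, 3)), "comparable sites")
  # monotone increasing in the mismatch fraction
  ds <- vapply(c(10, 50, 100, 300, 500),
               function(k) substitution_rate(make_aln_with_p(1000, k)), 0)
  expect_true(all(diff(ds) > 0))
})

test_that("JC69 agrees with an established phylogenetics implementation", {
  set.seed(2)
  chars1 <- sample(c("a", "c", "g", "t"), 500, TRUE)
  chars2 <- chars1
  flip <- sample(500, 60)
  chars2[flip] <- sample(c("a", "c", "g", "t"), 60, TRUE)
  m <- rbind(chars1, chars2)
  d_ape <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "JC69"))
  aln <- pairwise_alignment(paste(chars1, collapse = ""),
                            paste(chars2, collapse = ""))
  expect_equal(substitution_rate(aln), d_ape, tolerance = 1e-10)
})

test_that("GTR collapses to JC69 on JC-generated data", {
  scn <- evolution_scenario(neutral_rate = 0.3, motif_length = 10000L,
                            n_motif_segments = 1L, n_ar_segments = 1L,
                            ar_length = 10000L, seed = 6)
  sim <- simulate_sequence_pairs(scn)
  aln <- sim$motifs[[1]]
  d_jc <- substitution_rate(aln, "JC69")
  d_gtr <- substitution_rate(aln, "GTR")
  expect_lt(abs(d_gtr - d_jc), 0.005)
})

test_that("matched AR sampling preserves length, GC and determinism", {
  # a catalog of exact copies at distance 0 matches trivially: every
  # replicate reproduces the features' lengths and GC exactly
  scn <- evolution_scenario(seed = 3)
  sim <- simulate_sequence_pairs(scn)
  copies <- sim$motif_bed
  copies$name <- paste0("copy_", copies$name)
  reps0 <- sample_matched_ars(sim$motif_bed, copies, n_reps = 20, seed = 5)
  expect_true(all(reps0$gc_tolerance_used == 0.02))
  for (k in seq_along(reps0$feature_index)) {
    expect_true(all(copies$gc[reps0$ar_index[, k]] ==
                      sim$motif_bed$gc[reps0$feature_index[k]]))
    expect_true(all((copies$end - copies$start)[reps0$ar_index[, k]] ==
                      reps0$lengths[k]))
  }

  # realistic catalog: GC matched within the (possibly widened)
  # per-feature tolerance, total length preserved exactly
  reps <- suppressMessages(
    sample_matched_ars(sim$motif_bed, sim$ar_bed, n_reps = 50, seed = 5))
  expect_equal(dim(reps$ar_index)[1], 50)
  expect_equal(sum(reps$lengths),
               sum((sim$motif_bed$end - sim$motif_bed$start)[
                 reps$feature_index]))
  for (k in seq_along(reps$feature_index)) {
    gc_diff <- abs(sim$ar_bed$gc[reps$ar_index[, k]] -
                     sim$motif_bed$gc[reps$feature_index[k]])
    expect_true(all(gc_diff <= reps$gc_tolerance_used[k] + 1e-12))
  }
  reps2 <- suppressMessages(
    sample_matched_ars(sim$motif_bed, sim$ar_bed, n_reps = 50, seed = 5))
  expect_identical(reps$ar_index, reps2$ar_index)
  expect_identical(reps$offset, reps2$offset)
})

test_that("AR matching falls back by widening GC tolerance, then drops", {
  features <- data.frame(chrom = "chr1", start = 0L, end = 20L, gc = 0.5)
  ars <- data.frame(chrom = "chr1", start = 1000L, end = 1200L, gc = 0.58)
  expect_message(reps <- sample_matched_ars(features, ars, n_reps = 10,
                                            gc_tolerance = 0.02, seed = 1),
                 "widened")
  expect_equal(unique(as.vector(reps$ar_index)), 1L)
  # nothing on the same chromosome within reach: segment dropped
  far <- data.frame(chrom = "chr2", start = 0L, end = 200L, gc = 0.5)
  expect_error(
    suppressMessages(sample_matched_ars(features, far, n_reps = 10, seed = 1)),
    "no feature")
})

test_that("constraint test applies the add-one empirical rule", {
  d_ar <- seq(0.4, 0.6, length.out = 1000)
  ct_low <- constraint_test(0.1, d_ar)
  expect_equal(ct_low$p, 1 / 1001)
  ct_med <- constraint_test(stats::median(d_ar), d_ar)
  expect_equal(ct_med$p, 0.5, tolerance = 0.01)
  expect_equal(ct_med$relative_rate, 1, tolerance = 1e-6)
  expect_error(constraint_test(0.1, d_ar[1:50]), "100")
})

test_that("constrained motifs are detected against matched ARs", {
  scn <- evolution_scenario(neutral_rate = 0.5, constraint_ratio = 0.2,
                            seed = 12)
  sim <- simulate_sequence_pairs(scn)
  ct <- suppressMessages(
    test_motif_constraint(sim$motifs, sim$motif_bed, sim$ars,
                          sim$ar_bed, n_reps = 500, seed = 2))
  expect_lt(ct$p, 0.01)
  expect_lt(ct$relative_rate, 0.5)
})

test_that("DAF polarization follows the ancestral allele", {
  snps <- data.frame(id = c("s1", "s2", "s3"),
                     ref = c("A", "A", "A"), alt = c("G", "G", "G"),
                     ancestral = c("A", "G", "T"),
                     alt_freq = c(0.07, 0.93, 0.5))
  expect_message(out <- daf_spectrum(snps), "dropped")
  expect_equal(out$id, c("s1", "s2"))
  expect_equal(out$daf, c(0.07, 0.07))
})

test_that("DAF comparison reproduces the exact-test oracle", {
  ident <- daf_compare(c(0.05, 0.5, 0.9), c(0.05, 0.5, 0.9))
  expect_equal(ident$odds_ratio, 1)
  expect_equal(ident$p, 1)
  # table [[20,80],[10,90]] via DAF vectors
  a <- c(rep(0.05, 20), rep(0.5, 80))
  b <- c(rep(0.05, 10), rep(0.5, 90))
  cmp <- daf_compare(a, b)
  expect_equal(cmp$odds_ratio, 2.25)
  expect_equal(cmp$p, fisher_exact_oracle(cmp$table), tolerance = 1e-10)
  expect_error(daf_compare(numeric(0), b), "non-empty")
})
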