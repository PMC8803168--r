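test_that("rank normalization is monotone, tie-safe and centered", {
  x <- c(3, 1, 2, 2, 10, NA)
  z <- rank_normalize(x)
  expect_true(is.na(z[6]))
  obs <- z[!is.na(z)]
  expect_equal(mean(obs), 0)
  expect_equal(order(obs), order(x[!is.na(x)]))
  expect_equal(z[3], z[4])  # ties averaged
  expect_error(rank_normalize(rep(1, 10)), "constant")
  expect_error(rank_normalize(c(1, NA, NA)), "3 non-missing")
})

test_that("the MAF filter is strict at the threshold", {
  # 200 samples: 20 alt alleles -> MAF exactly 0.05; 21 -> 0.0525
  d_at <- c(rep(1, 20), rep(0, 180))
  d_above <- c(rep(1, 21), rep(0, 179))
  gm <- genotype_matrix(cbind(v_at = d_at, v_above = d_above))
  kept <- maf_filter(gm, 0.05)
  expect_equal(kept$variants$id, "v_above")
  mono <- genotype_matrix(matrix(0, 50, 2))
  expect_warning(maf_filter(mono), "no variant")
})

test_that("cis association recovers exact and planted effects", {
  set.seed(31)
  g <- stats::rbinom(100, 2, 0.4)
  res <- cis_associate(g + 0, matrix(g, ncol = 1), normalize = FALSE)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-50)

  # planted slope recovered within its 95% CI (un-normalized trait)
  g2 <- stats::rbinom(300, 2, 0.3)
  y <- 0.5 * g2 + stats::rnorm(300)
  res2 <- cis_associate(y, matrix(g2, ncol = 1), normalize = FALSE)
  se <- abs(res2$slope / (stats::qnorm(res2$p / 2)))
  expect_lt(abs(res2$slope - 0.5), 1.96 * se * 1.5)
  fit <- stats::lm(y ~ g2)
  expect_equal(res2$slope, unname(stats::coef(fit)[2]), tolerance = 1e-10)

  # monomorphic variants are skipped
  G <- cbind(g2, 1)
  expect_equal(nrow(cis_associate(y, G)), 1)
})

test_that("null nominal p-values are uniform", {
  set.seed(13)
  y <- stats::rnorm(150)
  G <- matrix(stats::rbinom(150 * 1000, 2, 0.3), 150)
  res <- cis_associate(y, G)
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("gene-level permutation passes real signal and is seeded", {
  set.seed(17)
  G <- matrix(stats::rbinom(120 * 20, 2, 0.3), 120)
  y <- 0.8 * G[, 1] + stats::rnorm(120)
  v <- gene_level_permutation(y, G, n_perm = 200, seed = 4)
  expect_true(v$pass)
  v2 <- gene_level_permutation(y, G, n_perm = 200, seed = 4)
  expect_identical(v$r_max, v2$r_max)
  expect_error(gene_level_permutation(y, G, n_perm = 50), "100")
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(bh_fdr(0.01)$q, 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.9))$q, c(0.03, 0.03, 0.9))
  expect_false(any(bh_fdr(rep(1, 5))$significant))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  step_up <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * n / (n:1)))[ro]
  }
  set.seed(23)
  for (i in 1:200) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_fdr(p)$q, step_up(p))
  }
})

test_that("flipping genotype coding flips slopes but not inference", {
  set.seed(41)
  G <- matrix(stats::rbinom(150 * 10, 2, 0.3), 150)
  y <- 0.4 * G[, 3] + stats::rnorm(150)
  a <- cis_associate(y, G)
  b <- cis_associate(y, 2 - G)
  expect_equal(a$slope, -b$slope)
  expect_equal(a$r, -b$r)
  expect_equal(a$p, b$p)
  va <- gene_level_permutation(y, G, n_perm = 200, seed = 9)
  vb <- gene_level_permutation(y, 2 - G, n_perm = 200, seed = 9)
  expect_equal(va$pass, vb$pass)
  expect_equal(va$r_obs, vb$r_obs)
})

test_that("target prediction requires a shared variant in a shared TAD", {
  rec <- function(trait, variant, tad, sig = TRUE)
    data.frame(trait = trait, variant = variant, tad = tad,
               significant = sig)
  elnc <- rbind(rec("L1", "v1", "tadA"), rec("L2", "v2", "tadB"),
                rec("L3", "v9", "tadC"))
  pcg <- rbind(rec("G1", "v1", "tadA"), rec("G2", "v2", "tadZ"),
               rec("G3", "v8", "tadC"))
  out <- predict_targets(elnc, pcg)
  expect_equal(nrow(out), 1)
  expect_equal(out$elncrna, "L1")
  expect_equal(out$target, "G1")
})

test_that("joint triplet assembly applies the exclusion audit", {
  rec <- function(trait, variant, sig = TRUE)
    data.frame(trait = trait, variant = variant, tad = "tadA",
               significant = sig)
  sqtls <- rbind(rec("psiL1", "v1"), rec("psiL1", "v2"), rec("psiL1", "v3"))
  eqtls <- rbind(rec("G1", "v1"), rec("G1", "v2"), rec("G1", "v4"))
  pairs <- data.frame(elncrna = "L1", outcome = "G1")
  smap <- data.frame(trait = "psiL1", elncrna = "L1")
  # v1 is also an eQTL for the elncRNA itself -> excluded
  elnc_e <- rec("L1", "v1")
  trip <- build_joint_triplets(sqtls, eqtls, pairs, smap,
                               elnc_eqtls = elnc_e)
  expect_equal(nrow(trip), 2)  # v1 and v2 jointly significant
  expect_true(trip$excluded_elnc_eqtl[trip$variant == "v1"])
  expect_false(trip$included[trip$variant == "v1"])
  expect_true(trip$included[trip$variant == "v2"])

  # brute-force five-variant fixture: shared variants minus exclusions
  sq5 <- do.call(rbind, lapply(paste0("v", 1:5), rec, trait = "psiL1"))
  eq5 <- do.call(rbind, lapply(paste0("v", c(1, 2, 3)), rec, trait = "G1"))
  tgt_s <- rec("G1", "v3")  # v3 is an sQTL of the target
  t5 <- build_joint_triplets(sq5, eq5, pairs, smap, elnc_eqtls = elnc_e,
                             target_sqtls = tgt_s)
  brute_included <- setdiff(intersect(paste0("v", 1:5), paste0("v", 1:3)),
                            c("v1", "v3"))
  expect_setequal(t5$variant[t5$included], brute_included)
})

test_that("Z-score to slope conversion is exact and sign-preserving", {
  expect_equal(zscore_to_slope(0, 0.3, 1000), 0)
  oracle <- 5 / sqrt(2 * 0.3 * 0.7 * (1000 + 25))
  expect_equal(zscore_to_slope(5, 0.3, 1000), oracle)
  expect_equal(zscore_to_slope(5, 0.3, 1000), 0.2410, tolerance = 1e-4)
  expect_equal(sign(zscore_to_slope(-2, 0.1, 50)), -1)
  expect_error(zscore_to_slope(1, 1.2, 10), "frequency")
})

test_that("replication requires significance and matching direction", {
  disc <- data.frame(key = c("k1", "k2", "k3"), slope = c(1, 1, 1))
  repl <- data.frame(key = c("k1", "k2", "k3"),
                     effect = c(0.5, -0.5, 0.5),
                     p = c(0.001, 0.001, 0.9))
  out <- replication_check(disc, repl)
  out <- out[order(out$key), ]
  expect_equal(out$replicated, c(TRUE, FALSE, FALSE))
})

test_that("TAD-windowed QTL mapping finds planted signals end to end", {
  set.seed(55)
  n <- 150
  gm <- simulate_genotypes(cohort_config(n_samples = n, n_variants = 40,
                                         maf_range = c(0.2, 0.5), seed = 3))
  tads <- data.frame(chrom = "chr1", start = c(0L, 20500L),
                     end = c(20500L, 40500L), name = c("tadA", "tadB"))
  y <- 0.8 * gm$dosage[, 5] + stats::rnorm(n)
  pheno <- matrix(y, 1, n, dimnames = list("gene1", gm$samples))
  tp <- data.frame(trait = "gene1", chrom = "chr1", pos = 1000L)
  rec <- map_qtls(pheno, gm, tp, tads, n_perm = 200, seed = 2)
  expect_true(all(rec$tad == "tadA"))
  expect_true(rec$significant[rec$variant == "var00005"])
  # a trait anchored outside any TAD is skipped with a warning
  tp_out <- data.frame(trait = "gene1", chrom = "chr1", pos = 999999L)
  expect_warning(out <- map_qtls(pheno, gm, tp_out, tads, n_perm = 200),
                 "no containing TAD")
  expect_equal(nrow(out), 0)
})
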