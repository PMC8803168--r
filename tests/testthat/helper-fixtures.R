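# Fixture builders shared across test files; everything is generated in
# code so the suite carries no binary data.

# A tiny two-chromosome genome as named character sequences.
make_genome <- function(seed = 1, len = 3000L) {
  set.seed(seed)
  list(chr1 = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
       chr2 = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
}

# Plant a given string at a 0-based offset of a chromosome.
plant_seq <- function(genome, chrom, at, what) {
  s <- genome[[chrom]]
  substr(s, at + 1L, at + nchar(what)) <- what
  genome[[chrom]] <- s
  genome
}

# Three-exon plus-strand transcript on chr1 with configurable middle
# exon width.
make_tx3 <- function(id = "tx1", strand = "+", mid_width = 120L,
                     biotype = "lncRNA") {
  e1 <- c(100L, 200L)
  e2 <- c(300L, 300L + mid_width)
  e3 <- c(700L, 800L)
  transcript_model(id, "chr1", strand, rbind(e1, e2, e3), biotype)
}

# Write GTF lines (1-based inclusive) for a set of exon tuples.
write_gtf_fixture <- function(path, rows) {
  # rows: data.frame chrom, start1, end1, strand, tx, biotype
  lines <- sprintf(
    paste0("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"g_%s\"; ",
           "transcript_id \"%s\"; gene_biotype \"%s\";"),
    rows$chrom, rows$start1, rows$end1, rows$strand, rows$tx, rows$tx,
    rows$biotype)
  writeLines(lines, path)
  path
}

# Minimal VCF text fixture.
write_vcf_fixture <- function(path, body_rows, samples = c("S1", "S2")) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_rows), path)
  path
}

# Random intron cluster counts for PSI oracle tests.
random_cluster_counts <- function(n_introns, n_samples, lambda = 20) {
  matrix(stats::rpois(n_introns * n_samples, lambda), nrow = n_introns)
}

# Pairwise alignment with an exactly known mismatch fraction.
make_aln_with_p <- function(n_sites, n_mismatch) {
  s1 <- strrep("A", n_sites)
  s2 <- paste0(strrep("C", n_mismatch), strrep("A", n_sites - n_mismatch))
  pairwise_alignment(s1, s2)
}

# Exhaustive two-tailed Fisher p for a 2x2 table by hypergeometric
# summation with choose() arithmetic (independent of stats::fisher.test).
fisher_exact_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  dens <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), 0)
  p_obs <- dens[support == tab[1, 1]]
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}
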