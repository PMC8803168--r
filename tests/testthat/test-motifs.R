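test_that("motif sets carry validated hexamers", {
  u1 <- motif_set("U1")
  expect_setequal(u1$hexamers, c("GGTAAG", "GGTGAG", "GTGAGT"))
  ese <- motif_set("ESE238")
  expect_length(ese$hexamers, 238)
  ese54 <- motif_set("ESE54")
  expect_length(ese54$hexamers, 54)
  expect_true(all(ese54$hexamers %in% ese$hexamers))
  expect_error(motif_set("U1", hexamers = c("ACGTA")), "6-mers")
  expect_error(motif_set("U1", hexamers = c("ACGTAX")), "6-mers")
})

test_that("ESE windows come only from internal exons > 100 nt", {
  genome <- make_genome()
  # middle exon exactly 100 nt -> excluded (strict inequality)
  tx100 <- make_tx3(mid_width = 100L)
  expect_length(extract_windows(tx100, genome, "ESE"), 0)
  # middle exon 120 nt -> two windows, effective length 45 each
  tx120 <- make_tx3(mid_width = 120L)
  ws <- extract_windows(tx120, genome, "ESE")
  expect_length(ws, 2)
  expect_equal(vapply(ws, function(w) w$effective_length, 0L), c(45L, 45L))
  expect_equal(vapply(ws, function(w) nchar(w$seq), 0L), c(50L, 50L))
  # two-exon transcript: no internal exon -> zero ESE, one U1 window
  tx2 <- transcript_model("t2", "chr1", "+",
                          rbind(c(100L, 300L), c(700L, 800L)), "lncRNA")
  expect_length(extract_windows(tx2, genome, "ESE"), 0)
  u1w <- extract_windows(tx2, genome, "U1")
  expect_length(u1w, 1)
  expect_equal(nchar(u1w[[1]]$seq), 9)
})

test_that("U1 windows span 3 exonic + 6 intronic nt at donors", {
  genome <- make_genome()
  tx <- transcript_model("t", "chr1", "+",
                         rbind(c(100L, 200L), c(300L, 400L)), "lncRNA")
  w <- extract_windows(tx, genome, "U1")[[1]]
  expect_equal(w$seq, elsplice:::subseq0(genome$chr1, 197, 206))
  # minus strand: donor is at the genomic start of the intron's right
  # neighbour; window reverse-complemented
  txm <- transcript_model("tm", "chr1", "-",
                          rbind(c(100L, 200L), c(300L, 400L)), "lncRNA")
  wm <- extract_windows(txm, genome, "U1")[[1]]
  expect_equal(wm$seq,
               elsplice:::revcomp(elsplice:::subseq0(genome$chr1, 294, 303)))
})

test_that("hexamer scanning counts every unmasked offset", {
  u1 <- motif_set("U1")
  win <- function(seq, masked = rep(FALSE, nchar(seq)))
    structure(list(seq = seq, masked = masked,
                   effective_length = sum(!masked)),
              class = "scan_window")
  expect_equal(scan_hexamers(win("GGTAAG"), u1)$count, 1)
  expect_equal(scan_hexamers(win("GGGTAAGG"), u1)$count, 1)
  # overlapping matches both count
  custom <- motif_set("U1", hexamers = c("AAAAAA"))
  expect_equal(scan_hexamers(win("AAAAAAA"), custom)$count, 2)
  # fully masked -> no matches, density 0
  m <- win("GGTAAG", masked = rep(TRUE, 6))
  expect_equal(scan_hexamers(m, u1), list(count = 0L, density = 0))
  # N never matches; bad alphabet errors
  expect_equal(scan_hexamers(win("GGTNAG"), u1)$count, 0)
  expect_error(scan_hexamers(win("GGTXAG"), u1), "alphabet|outside")
})

test_that("windows adjacent to the splice site are masked for ESE scans", {
  genome <- make_genome()
  motif <- "GGTAAG"
  # plant a motif inside the masked 5 nt of the acceptor-side window
  g <- plant_seq(genome, "chr1", 300L, motif)
  tx <- make_tx3(mid_width = 120L)
  ws <- extract_windows(tx, g, "ESE")
  acc <- ws[[which(vapply(ws, function(w) w$site, "") == "acceptor")]]
  expect_equal(scan_hexamers(acc, motif_set("U1"))$count, 0)
  # plant it beyond the mask -> counted
  g2 <- plant_seq(genome, "chr1", 310L, motif)
  ws2 <- extract_windows(tx, g2, "ESE")
  acc2 <- ws2[[which(vapply(ws2, function(w) w$site, "") == "acceptor")]]
  expect_equal(scan_hexamers(acc2, motif_set("U1"))$count, 1)
})

test_that("densities are strand-symmetric and additive over windows", {
  genome <- make_genome(seed = 5)
  txs <- list(make_tx3("a", "+", 140L), make_tx3("b", "-", 140L))
  ese <- motif_set("ESE238")
  d <- hexamer_density(txs, genome, ese)
  # reverse-complement the genome and flip strands: counts unchanged
  flipped_genome <- lapply(genome, function(s) elsplice:::revcomp(s))
  L <- nchar(genome$chr1)
  flip_tx <- function(tx) {
    ex <- tx$exons
    new_ex <- cbind(L - ex[, "end"], L - ex[, "start"])
    transcript_model(tx$id, tx$chrom,
                     if (tx$strand == "+") "-" else "+", new_ex, tx$biotype)
  }
  d_flip <- hexamer_density(lapply(txs, flip_tx), flipped_genome, ese)
  expect_equal(d$count, d_flip$count)
  expect_equal(d$density, d_flip$density)
})

test_that("GC profiles equal direct base counting", {
  # central position so both 500-nt-offset flanks fit in the contig
  tx <- transcript_model("gc1", "chr1", "+",
                         rbind(c(1300L, 1400L), c(1500L, 1620L),
                               c(1700L, 1800L)), "lncRNA")
  allg <- list(chr1 = strrep("G", 3000))
  expect_equal(unname(gc_profile(tx, allg)), rep(1, 4))
  acac <- list(chr1 = strrep("AC", 1500))
  expect_equal(unname(gc_profile(tx, acac)), rep(0.5, 4))

  genome <- make_genome(seed = 9)
  prof <- gc_profile(tx, genome)
  gc_count <- function(s) elsplice:::gc_fraction(s)
  chr <- genome$chr1
  expect_equal(prof[["first_exon"]],
               gc_count(substr(chr, 1301, 1400)))
  expect_equal(prof[["other_exons"]],
               gc_count(paste0(substr(chr, 1501, 1620),
                               substr(chr, 1701, 1800))))
  expect_equal(prof[["introns"]],
               gc_count(paste0(substr(chr, 1401, 1500),
                               substr(chr, 1621, 1700))))
  # flank = span-length windows 500 nt away on both sides, pooled
  expect_equal(prof[["flank"]],
               gc_count(paste0(substr(chr, 301, 800),
                               substr(chr, 2301, 2800))))
  # flank truncation at the contig edge warns
  wide <- transcript_model("w", "chr1",
                           "+", rbind(c(100L, 300L), c(2500L, 2900L)),
                           "lncRNA")
  expect_warning(gc_profile(wide, genome), "truncated")
})
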