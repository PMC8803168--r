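make_classification_fixture <- function() {
  enh <- data.frame(chrom = "chr1", start = c(1000L, 9000L),
                    end = c(1200L, 9100L))
  prom <- data.frame(chrom = "chr1", start = 5000L, end = 5200L)
  list(enhancers = enh, promoters = prom)
}

test_that("transcript classes follow the 500-bp TSS rule", {
  fx <- make_classification_fixture()
  # lncRNA TSS 499 nt upstream of enhancer edge -> elncRNA
  near <- transcript_model("lnc_near", "chr1", "-",
                           rbind(c(200L, 502L)), "lncRNA")  # TSS at 501
  # boundary: exactly 500 away is still within
  edge <- transcript_model("lnc_edge", "chr1", "+",
                           rbind(c(500L, 700L)), "lncRNA")  # TSS 500
  # 501 nt from everything -> unclassified
  far <- transcript_model("lnc_far", "chr1", "+",
                          rbind(c(1700L, 1900L)), "lncRNA")
  # protein-coding TSS inside promoter -> pcg
  pcg <- transcript_model("pcg1", "chr1", "+",
                          rbind(c(5100L, 5400L), c(5600L, 5800L)),
                          "protein_coding")
  # lncRNA near promoter only -> plncRNA
  plnc <- transcript_model("plnc1", "chr1", "+",
                           rbind(c(5300L, 5500L)), "lncRNA")
  out <- classify_transcripts(list(near, edge, far, pcg, plnc),
                              fx$enhancers, fx$promoters)
  cls <- setNames(out$transcripts$class, out$transcripts$id)
  expect_equal(cls[["lnc_near"]], "elncRNA")
  expect_equal(cls[["lnc_edge"]], "elncRNA")
  expect_equal(cls[["lnc_far"]], "unclassified")
  expect_equal(cls[["pcg1"]], "pcg")
  expect_equal(cls[["plnc1"]], "plncRNA")
  # enhancer with no assigned transcript -> eRNA class
  expect_equal(out$erna_enhancers$start, 9000L)
})

test_that("enhancer proximity takes precedence and chrom gaps warn", {
  fx <- make_classification_fixture()
  both <- transcript_model("lnc_both", "chr1", "+",
                           rbind(c(4900L, 5600L)), "lncRNA")
  enh2 <- rbind(fx$enhancers,
                data.frame(chrom = "chr1", start = 4600L, end = 4800L))
  out <- classify_transcripts(list(both), enh2, fx$promoters)
  expect_equal(out$transcripts$class, "elncRNA")

  off <- transcript_model("off", "chrZ", "+", rbind(c(1L, 10L)), "lncRNA")
  expect_warning(out2 <- classify_transcripts(list(off), fx$enhancers,
                                              fx$promoters),
                 "unannotated chromosome")
  expect_equal(out2$transcripts$class, "unclassified")
})

test_that("class labels are invariant to transcript input order", {
  fx <- make_classification_fixture()
  txs <- list(
    transcript_model("a", "chr1", "+", rbind(c(1100L, 1400L)), "lncRNA"),
    transcript_model("b", "chr1", "+", rbind(c(5100L, 5400L)), "lncRNA"),
    transcript_model("c", "chr1", "+", rbind(c(2500L, 2700L)), "lncRNA"))
  t1 <- classify_transcripts(txs, fx$enhancers, fx$promoters)$transcripts
  t2 <- classify_transcripts(rev(txs), fx$enhancers, fx$promoters)$transcripts
  expect_equal(table(t1$class), table(t2$class))
  expect_equal(t1[order(t1$id), ], t2[order(t2$id), ], ignore_attr = TRUE)
})

test_that("splice-site variants hit donor/acceptor dinucleotides only", {
  # plus strand: intron [200, 300); donor nt at 0-based 200,201 ->
  # 1-based positions 201,202; acceptor at 298,299 -> 299,300
  tx <- transcript_model("e1", "chr1", "+",
                         rbind(c(100L, 200L), c(300L, 400L)), "lncRNA")
  vars <- data.frame(id = c("v_don", "v_mid", "v_acc", "v_deep"),
                     chrom = "chr1", pos = c(202L, 205L, 300L, 250L))
  hits <- find_splice_site_variants(vars, list(tx))
  expect_setequal(hits$variant_id, c("v_don", "v_acc"))
  expect_equal(hits$site[hits$variant_id == "v_don"], "donor")
  expect_equal(hits$site[hits$variant_id == "v_acc"], "acceptor")
})

test_that("minus-strand donors sit at the genomic end of the intron", {
  tx <- transcript_model("e2", "chr1", "-",
                         rbind(c(100L, 200L), c(300L, 400L)), "lncRNA")
  # transcript runs right to left: donor dinucleotide = genomic 298,299
  vars <- data.frame(id = c("v_end", "v_start"), chrom = "chr1",
                     pos = c(300L, 201L))
  hits <- find_splice_site_variants(vars, list(tx))
  expect_equal(hits$site[hits$variant_id == "v_end"], "donor")
  expect_equal(hits$site[hits$variant_id == "v_start"], "acceptor")
})

test_that("splice-site flagging matches a brute-force boundary scan", {
  set.seed(42)
  txs <- lapply(1:5, function(i) {
    n_ex <- sample(2:4, 1)
    starts <- sort(sample(seq(100L, 5000L, by = 50L), n_ex))
    exons <- cbind(starts, starts + 30L)
    transcript_model(paste0("t", i), "chr1",
                     sample(c("+", "-"), 1), exons, "lncRNA")
  })
  vars <- data.frame(id = sprintf("v%03d", 1:300), chrom = "chr1",
                     pos = sample(1:5200, 300))
  hits <- find_splice_site_variants(vars, txs)
  # oracle: enumerate every intron boundary dinucleotide position
  expected <- 0L
  for (tx in txs) {
    introns <- elsplice:::transcript_introns(tx)
    for (i in seq_len(nrow(introns))) {
      at0 <- c(introns$start[i], introns$start[i] + 1L,
               introns$end[i] - 2L, introns$end[i] - 1L)
      expected <- expected + sum((vars$pos - 1L) %in% at0)
    }
  }
  expect_equal(nrow(hits), expected)
  # variants on transcript-free contigs are silently excluded
  vars2 <- data.frame(id = "x", chrom = "chrM", pos = 150L)
  expect_equal(nrow(find_splice_site_variants(vars2, txs)), 0)
})
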