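test_that("overlap counting honours coordinates, seqnames and strand rules", {
  q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 20), strand = "+")
  s_same <- GenomicRanges::GRanges("chr1", IRanges::IRanges(15, 25),
                                   strand = "+")
  s_opp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(15, 25),
                                  strand = "-")
  s_both <- GenomicRanges::GRanges("chr1", IRanges::IRanges(15, 25),
                                   strand = "*")
  expect_identical(count_overlaps(q, s_same, respect_strand = TRUE), 1L)
  expect_identical(count_overlaps(q, s_opp, respect_strand = TRUE), 0L)
  expect_identical(count_overlaps(q, s_opp, respect_strand = FALSE), 1L)
  # "both" is compatible with everything
  expect_identical(count_overlaps(q, s_both, respect_strand = TRUE), 1L)
  expect_identical(count_overlaps(s_both, s_opp, respect_strand = TRUE), 1L)
})

test_that("overlap engine equals the naive all-pairs scan on random intervals", {
  set.seed(31)
  q <- random_granges(200)
  s <- random_granges(2000)
  expect_identical(count_overlaps(q, s, respect_strand = FALSE),
                   naive_count_overlaps(q, s, respect_strand = FALSE))
  expect_identical(count_overlaps(q, s, respect_strand = TRUE),
                   naive_count_overlaps(q, s, respect_strand = TRUE))
  # ignoring strand can only add overlaps
  expect_true(all(count_overlaps(q, s, FALSE) >= count_overlaps(q, s, TRUE)))
  # flipping every strand leaves unstranded counting unchanged
  flip <- function(gr) {
    st <- as.character(BiocGenerics::strand(gr))
    BiocGenerics::strand(gr) <- ifelse(st == "+", "-",
                                       ifelse(st == "-", "+", "*"))
    gr
  }
  expect_identical(count_overlaps(flip(q), flip(s), FALSE),
                   count_overlaps(q, s, FALSE))
})

test_that("gene-anatomy features follow strand-aware coordinate arithmetic", {
  feats <- derive_gene_features(tiny_gff(), flank = 2000)
  # plus-strand gene at 0-based [5000,8000), exons [5000,5600) and [7000,8000)
  upA <- feats$upstream2kb[GenomicRanges::start(feats$upstream2kb) == 3001]
  expect_length(upA, 1)
  expect_identical(GenomicRanges::end(upA), 5000L)
  expect_identical(as.character(BiocGenerics::strand(upA)), "+")
  intrA <- feats$intron[as.character(BiocGenerics::strand(feats$intron)) == "+"]
  expect_identical(GenomicRanges::start(intrA), 5601L)
  expect_identical(GenomicRanges::end(intrA), 7000L)
  dnA <- feats$downstream2kb[
    as.character(BiocGenerics::strand(feats$downstream2kb)) == "+" &
      GenomicRanges::start(feats$downstream2kb) == 8001]
  expect_identical(GenomicRanges::end(dnA), 10000L)

  # minus-strand gene [20000,24000): upstream lies ABOVE the gene end
  upB <- feats$upstream2kb[
    as.character(BiocGenerics::strand(feats$upstream2kb)) == "-"]
  expect_identical(GenomicRanges::start(upB), 24001L)
  expect_identical(GenomicRanges::end(upB), 26000L)
  dnB <- feats$downstream2kb[
    as.character(BiocGenerics::strand(feats$downstream2kb)) == "-"]
  expect_identical(GenomicRanges::end(dnB), 20000L)

  # single-exon gene contributes no intron; intron count is 2 genes' worth
  expect_length(feats$intron, 2)
  expect_length(feats$exon, 5)
})

test_that("exons and introns tile each transcript without gaps or overlaps", {
  cfg <- simulation_config(seed = 5, n_sequences = 1,
                           sequence_length = 200000, n_genes = 12,
                           n_peaks = 10)
  sim <- simulate_medip(cfg, file.path(tempdir(), "featsim"))
  gff <- rtracklayer::import(sim$files[["annotation"]], format = "gff3")
  feats <- derive_gene_features(gff)
  genes <- gff[gff$type == "gene"]
  for (g in seq_along(genes)) {
    gr <- genes[g]
    ex <- feats$exon[IRanges::overlapsAny(feats$exon, gr)]
    intr <- feats$intron[IRanges::overlapsAny(feats$intron, gr)]
    expect_identical(sum(GenomicRanges::width(ex)) +
                       sum(GenomicRanges::width(intr)),
                     GenomicRanges::width(gr))
    cov <- GenomicRanges::coverage(c(GenomicRanges::granges(ex),
                                     GenomicRanges::granges(intr)))
    expect_true(all(S4Vectors::runValue(cov[gr][[1]]) == 1))
  }
})

test_that("splice windows sit at intron boundaries in transcription orientation", {
  ss <- derive_splice_sites(tiny_gff(), half_width = 100)
  # plus-strand intron 0-based [5600,7000): donor at its low coordinate
  dplus <- ss$donor[as.character(BiocGenerics::strand(ss$donor)) == "+"]
  expect_identical(unname(dplus$site), 5601L)
  expect_identical(GenomicRanges::start(dplus), 5501L)
  expect_identical(GenomicRanges::end(dplus), 5701L)
  aplus <- ss$acceptor[as.character(BiocGenerics::strand(ss$acceptor)) == "+"]
  expect_identical(unname(aplus$site), 7000L)

  # minus-strand intron [21000,23000): donor at the HIGHER coordinate
  dminus <- ss$donor[as.character(BiocGenerics::strand(ss$donor)) == "-"]
  aminus <- ss$acceptor[as.character(BiocGenerics::strand(ss$acceptor)) == "-"]
  expect_true(dplus$site < aplus$site)
  expect_true(dminus$site > aminus$site)
})

test_that("junctions shared by isoforms collapse to one window", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t5000\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1001\t5000\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t1001\t1500\t.\t+\t.\tID=t1.e1;Parent=t1",
    "chr1\ttest\texon\t3001\t5000\t.\t+\t.\tID=t1.e2;Parent=t1",
    "chr1\ttest\tmRNA\t1001\t5000\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\ttest\texon\t1001\t1500\t.\t+\t.\tID=t2.e1;Parent=t2",
    "chr1\ttest\texon\t3001\t4000\t.\t+\t.\tID=t2.e2;Parent=t2"
  ), gff)
  ss <- derive_splice_sites(gff)
  expect_length(ss$donor, 1)   # same donor in both isoforms
  expect_length(ss$acceptor, 1)
})

test_that("splice asymmetry test recovers balance, bias and the closed form", {
  win <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = seq(1000, by = 5000, length.out = 100),
                             width = 201),
    strand = rep(c("+", "-"), 50))
  centre <- GenomicRanges::start(win) + 100

  # balanced: all peaks plus-stranded against alternating window strands,
  # so half the overlaps are sense and half antisense
  pk_bal <- peak_table(
    "chr1", start = centre - 50, end = centre + 50,
    strand_class = rep("plus", 100))
  res <- splice_asymmetry(pk_bal, win, win[0])
  expect_identical(res$sense[res$site_type == "donor"], 50L)
  expect_identical(res$antisense[res$site_type == "donor"], 50L)
  expect_gt(res$p.value[res$site_type == "donor"], 0.9)
  # zero overlaps on the acceptor side: p undefined
  expect_true(is.na(res$p.value[res$site_type == "acceptor"]))

  # all antisense: direction recovered with overwhelming significance
  pk_anti <- peak_table(
    "chr1", start = centre - 50, end = centre + 50,
    strand_class = ifelse(as.character(
      BiocGenerics::strand(win)) == "+", "minus", "plus"))
  res2 <- splice_asymmetry(pk_anti, win, win)
  expect_identical(res2$sense, c(0L, 0L))
  expect_lt(res2$p.value[1], 1e-4)

  # 0 sense vs 10 antisense equals the continuity-corrected proportion test
  pk10 <- peak_table(
    "chr1", start = centre[1:10] - 50, end = centre[1:10] + 50,
    strand_class = ifelse(as.character(
      BiocGenerics::strand(win[1:10])) == "+", "minus", "plus"))
  res3 <- splice_asymmetry(pk10, win[1:10], win[0])
  x2 <- (abs(0 - 5) - 0.5)^2 / (10 * 0.25)
  expect_equal(res3$p.value[res3$site_type == "donor"],
               stats::pchisq(x2, df = 1, lower.tail = FALSE))
})
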