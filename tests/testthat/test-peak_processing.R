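test_that("peak reader auto-detects BED and narrowPeak dialects", {
  np <- tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t500\tp1\t0\t.\t5.2\t10.1\t8.3\t200", np)
  pk <- read_peaks(np)
  expect_length(pk, 1)
  expect_identical(as.character(GenomicRanges::seqnames(pk)), "chr1")
  expect_identical(GenomicRanges::start(pk), 101L)  # 0-based 100 preserved
  expect_identical(GenomicRanges::end(pk), 500L)
  expect_identical(pk$name, "p1")

  bed3 <- tempfile(fileext = ".bed")
  writeLines(c("track name=x", "scaf1\t0\t250"), bed3)
  pk3 <- read_peaks(bed3)
  expect_identical(GenomicRanges::start(pk3), 1L)
  expect_identical(GenomicRanges::end(pk3), 250L)
  expect_identical(pk3$name, "peak_1")

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t30\t30"), bad)
  expect_error(read_peaks(bad), "line 2")
})

test_that("strand-split counting tallies overlapping first mates per peak", {
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(start = 101, end = 200),
                                  name = "p1")
  aln <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(151, 151, 151, 121, 121, 500),
                     end = c(190, 190, 190, 180, 180, 540)),
    strand = c("+", "+", "+", "-", "-", "+"))
  cs <- count_strands(peaks, aln)
  expect_identical(cs$y_plus, 3L)
  expect_identical(cs$y_minus, 2L)
  expect_equal(cs$theta, 0.6)
  expect_identical(cs$start, 100L)  # back on 0-based in the report

  far <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(start = 5000, end = 5100))
  expect_identical(count_strands(far, aln)$y_total, 0L)

  off <- GenomicRanges::GRanges("chrX",
                                IRanges::IRanges(start = 1, end = 100))
  expect_warning(cs0 <- count_strands(off, aln), "absent")
  expect_identical(cs0$y_total, 0L)
  expect_error(count_strands(off, aln, missing_seqnames = "error"), "absent")
})

test_that("counting equals the all-pairs scan and ignores record order", {
  set.seed(11)
  peaks <- random_granges(50, strands = "*")
  peaks$name <- sprintf("p%d", 1:50)
  aln <- random_granges(5000, strands = c("+", "-"), max_width = 80)
  cs <- count_strands(peaks, aln)
  expect_identical(cs$y_plus, naive_count_overlaps(
    peaks, aln[BiocGenerics::strand(aln) == "+"]))
  expect_identical(cs$y_minus, naive_count_overlaps(
    peaks, aln[BiocGenerics::strand(aln) == "-"]))
  shuffled <- aln[sample(length(aln))]
  expect_identical(count_strands(peaks, shuffled), cs)
})

test_that("swapping every alignment strand flips plus and minus calls", {
  set.seed(12)
  peaks <- random_granges(40, strands = "*", max_width = 500)
  peaks$name <- sprintf("p%d", 1:40)
  aln <- random_granges(4000, strands = c("+", "-"), max_width = 80)
  flipped <- aln
  BiocGenerics::strand(flipped) <-
    ifelse(as.character(BiocGenerics::strand(aln)) == "+", "-", "+")
  c1 <- classify_all(count_strands(peaks, aln))
  c2 <- classify_all(count_strands(peaks, flipped))
  expect_identical(unname(c1$tally["plus"]), unname(c2$tally["minus"]))
  expect_identical(unname(c1$tally["minus"]), unname(c2$tally["plus"]))
  expect_identical(unname(c1$tally["both"]), unname(c2$tally["both"]))
})

test_that("batch classification returns the tally partition and fractions", {
  counts <- data.frame(y_plus = c(60L, 0L, 40L, 5L),
                       y_minus = c(40L, 0L, 2L, 40L))
  calls <- classify_all(counts)
  expect_identical(as.character(calls$peaks$strand_class),
                   c("both", "unclassified", "plus", "minus"))
  expect_identical(sum(calls$tally), nrow(counts))
  expect_equal(calls$single_stranded_fraction, 2 / 3)

  zero <- classify_all(data.frame(y_plus = c(0L, 0L), y_minus = c(0L, 0L)))
  expect_identical(unname(zero$tally["unclassified"]), 2L)
  expect_true(is.na(zero$single_stranded_fraction))
})

test_that("high-depth asymmetric truth is recovered at the planted rate", {
  set.seed(21)
  n <- 400
  asym <- runif(n) < 0.8
  y_plus <- ifelse(asym, rpois(n, 60), rpois(n, 60))
  y_minus <- ifelse(asym, rpois(n, 1), rpois(n, 60))
  calls <- classify_all(data.frame(y_plus = y_plus, y_minus = y_minus))
  expect_equal(calls$single_stranded_fraction, 0.8, tolerance = 0.05)
})

test_that("width bias test matches the textbook Pearson statistic", {
  # identical class proportions in every width group: independence exact
  pk <- peak_table(
    seqnames = "chr1",
    start = seq(0, by = 1000, length.out = 60),
    end = seq(0, by = 1000, length.out = 60) +
      rep(c(100, 100, 500, 500, 900, 900), 10),
    strand_class = rep(c("plus", "minus"), 30))
  wb <- width_bias_test(pk, quantile_bounds = c(1 / 3, 2 / 3))
  expect_equal(wb$statistic, 0, tolerance = 1e-12)
  expect_equal(wb$p.value, 1)

  # hand-built table checked against sum((O-E)^2/E)
  widths <- rep(c(100, 500, 900), times = c(20, 20, 20))
  classes <- c(rep("plus", 12), rep("minus", 5), rep("both", 3),
               rep("plus", 6), rep("minus", 10), rep("both", 4),
               rep("plus", 4), rep("minus", 6), rep("both", 10))
  pk2 <- peak_table("chr1", start = seq_along(widths) * 2000,
                    end = seq_along(widths) * 2000 + widths,
                    strand_class = classes)
  wb2 <- width_bias_test(pk2, quantile_bounds = c(1 / 3, 2 / 3))
  O <- as.matrix(wb2$table)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(wb2$statistic, sum((O - E)^2 / E))
  expect_equal(wb2$p.value,
               stats::pchisq(wb2$statistic, wb2$df, lower.tail = FALSE))

  # a single represented class cannot deviate from independence
  pk3 <- peak_table("chr1", start = seq(0, by = 1000, length.out = 30),
                    end = seq(0, by = 1000, length.out = 30) +
                      rep(c(100, 500, 900), 10),
                    strand_class = "plus")
  expect_equal(width_bias_test(
    pk3, quantile_bounds = c(1 / 3, 2 / 3))$statistic, 0)
})

test_that("stranded track export round-trips and matches a per-base pileup", {
  aln <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(101, 131, 131, 171, 401 + 0:29),
                     end = c(150, 180, 180, 220, 450 + 0:29)),
    strand = c("+", "+", "-", "+", rep("-", 30)))
  peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(101, 401), end = c(300, 500)),
    name = c("pA", "pB"))
  calls <- classify_all(count_strands(peaks, aln))
  prefix <- file.path(tempdir(), "tracks_test")
  files <- write_stranded_tracks(calls, prefix, alignments = aln)
  expect_true(all(file.exists(files)))

  # BED round-trip preserves the intervals exactly
  back <- read_peaks(paste0(prefix, "_peaks.bed"))
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(peaks))
  expect_identical(GenomicRanges::end(back), GenomicRanges::end(peaks))

  # a minus-class peak carries "-" in the BED strand field
  bed <- read.table(paste0(prefix, "_peaks.bed"), sep = "\t")
  expect_identical(bed$V6[bed$V4 == "pB"], "-")

  # plus-strand bedgraph equals a per-base pileup of forward first mates
  bg <- read.table(paste0(prefix, "_plus.bedgraph"), sep = "\t",
                   col.names = c("chr", "start", "end", "score"))
  pile <- integer(1000)
  for (i in which(as.character(BiocGenerics::strand(aln)) == "+")) {
    span <- GenomicRanges::start(aln)[i]:GenomicRanges::end(aln)[i]
    pile[span] <- pile[span] + 1L
  }
  for (r in seq_len(nrow(bg))) {
    bases <- (bg$start[r] + 1):bg$end[r]
    expect_true(all(pile[bases] == bg$score[r]))
  }
  expect_equal(sum(as.numeric(bg$score) * (bg$end - bg$start)), sum(pile))
})
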