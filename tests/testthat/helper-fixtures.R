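# Shared fixtures and independent oracles, all built in code at test time.

# Build a BAM from hand-written SAM records.
# records: character vector of alignment lines (tab-separated SAM fields).
make_bam <- function(records, seqlengths = c(chr1 = 100000)) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   unname(seqlengths)))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(hdr, records), sam)
  dest <- tempfile()
  Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE)
}

# One SAM alignment line. pos is 1-based; len gives a <len>M cigar.
sam_rec <- function(qname, flag, rname = "chr1", pos = 1, mapq = 60,
                    len = 50) {
  seq <- strrep("A", len)
  paste(qname, flag, rname, pos, mapq, paste0(len, "M"), "*", 0, 0,
        seq, strrep("I", len), sep = "\t")
}

# SAM flags for common cases
FLAG_FIRST_FWD <- 0x1 + 0x2 + 0x20 + 0x40     # 99
FLAG_FIRST_REV <- 0x1 + 0x2 + 0x10 + 0x40     # 83
FLAG_SECOND_FWD <- 0x1 + 0x2 + 0x20 + 0x80    # 163
FLAG_FIRST_FWD_DUP <- FLAG_FIRST_FWD + 0x400
FLAG_FIRST_FWD_IMPROPER <- 0x1 + 0x40         # paired, not proper

# GFF3 with a plus-strand two-exon gene, a minus-strand two-exon gene and a
# single-exon gene; the coordinate layout of the plus gene is the canonical
# hand-checkable example (0-based gene [5000,8000), exons [5000,5600) and
# [7000,8000)).
tiny_gff <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t5001\t8000\t.\t+\t.\tID=gA",
    "chr1\ttest\tmRNA\t5001\t8000\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\ttest\texon\t5001\t5600\t.\t+\t.\tID=gA.t1.e1;Parent=gA.t1",
    "chr1\ttest\texon\t7001\t8000\t.\t+\t.\tID=gA.t1.e2;Parent=gA.t1",
    "chr1\ttest\tgene\t20001\t24000\t.\t-\t.\tID=gB",
    "chr1\ttest\tmRNA\t20001\t24000\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\ttest\texon\t20001\t21000\t.\t-\t.\tID=gB.t1.e1;Parent=gB.t1",
    "chr1\ttest\texon\t23001\t24000\t.\t-\t.\tID=gB.t1.e2;Parent=gB.t1",
    "chr1\ttest\tgene\t40001\t41000\t.\t+\t.\tID=gC",
    "chr1\ttest\tmRNA\t40001\t41000\t.\t+\t.\tID=gC.t1;Parent=gC",
    "chr1\ttest\texon\t40001\t41000\t.\t+\t.\tID=gC.t1.e1;Parent=gC.t1"
  ), path)
  path
}

# Brute-force likelihood-set classifier: evaluates the Poisson log-likelihood
# at every candidate rate from first principles (explicit log-gamma formula,
# no shared code with the implementation) and intersects the thresholded sets.
brute_classify <- function(y_plus, y_minus, alpha = 0.1) {
  logl <- function(y, lam) {
    ifelse(lam == 0, ifelse(y == 0, 0, -Inf),
           y * log(lam) - lam - lgamma(y + 1))
  }
  cand <- min(y_plus, y_minus):max(y_plus, y_minus)
  lp <- logl(y_plus, cand)
  lm <- logl(y_minus, cand)
  ls_plus <- cand[lp - max(lp) >= log(alpha)]
  ls_minus <- cand[lm - max(lm) >= log(alpha)]
  inter <- intersect(ls_plus, ls_minus)
  class_ <- if (length(inter) > 0) "both" else
    if (y_plus > y_minus) "plus" else "minus"
  list(ls_plus = ls_plus, ls_minus = ls_minus, class = class_)
}

# Naive all-pairs strand-aware overlap counter over GRanges.
naive_count_overlaps <- function(query, subject, respect_strand = FALSE) {
  qs <- as.character(GenomicRanges::seqnames(query))
  ss <- as.character(GenomicRanges::seqnames(subject))
  qstr <- as.character(BiocGenerics::strand(query))
  sstr <- as.character(BiocGenerics::strand(subject))
  q1 <- GenomicRanges::start(query); q2 <- GenomicRanges::end(query)
  s1 <- GenomicRanges::start(subject); s2 <- GenomicRanges::end(subject)
  compatible <- function(a, b) a == "*" || b == "*" || a == b
  vapply(seq_along(query), function(i) {
    n <- 0L
    for (j in seq_along(subject)) {
      if (qs[i] != ss[j]) next
      if (q1[i] > s2[j] || q2[i] < s1[j]) next
      if (respect_strand && !compatible(qstr[i], sstr[j])) next
      n <- n + 1L
    }
    n
  }, integer(1))
}

# Random stranded GRanges on a couple of sequences.
random_granges <- function(n, seqnames = c("chr1", "chr2"), max_pos = 10000,
                           max_width = 300, strands = c("+", "-", "*")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  GenomicRanges::GRanges(
    seqnames = sample(seqnames, n, replace = TRUE),
    ranges = IRanges::IRanges(start = start,
                              width = sample.int(max_width, n,
                                                 replace = TRUE)),
    strand = sample(strands, n, replace = TRUE)
  )
}

# Minimal strand_calls-like peak table for downstream analyses.
peak_table <- function(seqnames, start, end, strand_class,
                       peak_id = sprintf("p%d", seq_along(start))) {
  data.frame(peak_id = peak_id, seqnames = seqnames, start = start,
             end = end, width = end - start,
             strand_class = factor(strand_class,
                                   levels = c("plus", "minus", "both",
                                              "unclassified")),
             stringsAsFactors = FALSE)
}
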