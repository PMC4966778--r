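#' Load filtered first-mate alignments from a SAM/BAM file
#'
#' In a strand-preserving MeDIP-Seq library only the FIRST mate of each pair
#' is sequenced from the adaptor retained on the immuno-captured strand, so
#' only first mates carry the methylated-strand signal: a forward alignment
#' means plus-strand methylation, a reverse-complement alignment means
#' minus-strand methylation. This reader keeps primary, mapped, first-in-pair
#' records with mapping quality at or above \code{min_mapq} (default 10) and,
#' by default, drops records carrying the PCR/optical duplicate flag
#' (duplicate marking is consumed from the flag, not performed here).
#' Secondary and supplementary alignments are always excluded.
#'
#' @param alignment_file Path to a coordinate-sorted BAM (or SAM, converted
#'   on the fly) with paired-end flags set.
#' @param min_mapq Minimum mapping quality to keep; default 10.
#' @param drop_duplicates Drop flag-marked duplicates; default \code{TRUE}.
#' @param proper_pairs_only Keep only reads in proper pairs; default
#'   \code{FALSE} (any mapped first mate passing the other filters is kept).
#' @return A \code{GRanges} of the retained first-mate alignment spans
#'   (0-based half-open coordinates are used in all text output; the
#'   \code{GRanges} itself follows the usual 1-based convention), strand
#'   \code{+} or \code{-}, with metadata columns \code{mapq}. The attribute
#'   \code{"filter_summary"} is a named integer vector with the records read,
#'   kept, and discarded by reason.
#' @export
load_first_mates <- function(alignment_file, min_mapq = 10,
                             drop_duplicates = TRUE,
                             proper_pairs_only = FALSE) {
  if (!file.exists(alignment_file))
    stop("alignment file not found: ", alignment_file)
  bam <- .as_bam(alignment_file)

  p <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "cigar", "mapq", "strand"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n_read <- length(res$flag)

  if (n_read == 0L) {
    gr <- GenomicRanges::GRanges(seqinfo = .bam_seqinfo(bam))
    S4Vectors::mcols(gr)$mapq <- integer(0)
    attr(gr, "filter_summary") <- c(read = 0L, kept = 0L,
                                    not_first_mate = 0L, low_mapq = 0L,
                                    duplicate = 0L, improper_pair = 0L)
    return(gr)
  }

  flag <- res$flag
  paired <- bitwAnd(flag, 0x1L) > 0L
  if (!any(paired))
    stop("no paired-end records found: this tool requires paired-end ",
         "alignments with first-in-pair flags (single-end data cannot ",
         "carry the first-mate strand signal)")
  first <- paired & bitwAnd(flag, 0x40L) > 0L
  dup <- bitwAnd(flag, 0x400L) > 0L
  proper <- bitwAnd(flag, 0x2L) > 0L
  mapq_ok <- !is.na(res$mapq) & res$mapq >= min_mapq

  # filters applied in a fixed precedence so each discard has one reason
  drop_not_first <- !first
  drop_mapq <- first & !mapq_ok
  drop_dup <- if (drop_duplicates) first & mapq_ok & dup else rep(FALSE, n_read)
  drop_improper <- if (proper_pairs_only)
    first & mapq_ok & !drop_dup & !proper else rep(FALSE, n_read)
  keep <- first & mapq_ok & !drop_dup & !drop_improper

  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[keep])
  gr <- GenomicRanges::GRanges(
    seqnames = droplevels(res$rname[keep]),
    ranges = IRanges::IRanges(start = res$pos[keep],
                              width = width),
    strand = res$strand[keep]
  )
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(.bam_seqinfo(bam))
  GenomeInfoDb::seqinfo(gr) <- .bam_seqinfo(bam)
  S4Vectors::mcols(gr)$mapq <- res$mapq[keep]
  attr(gr, "filter_summary") <- c(
    read = n_read,
    kept = sum(keep),
    not_first_mate = sum(drop_not_first),
    low_mapq = sum(drop_mapq),
    duplicate = sum(drop_dup),
    improper_pair = sum(drop_improper)
  )
  gr
}

.as_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = TRUE)
  } else {
    path
  }
}

.bam_seqinfo <- function(bam) {
  h <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  GenomeInfoDb::Seqinfo(seqnames = names(h), seqlengths = unname(h))
}

#' Per-cycle base frequencies of a FASTQ file
#'
#' Tallies A, C, G, T and N at every read position (sequencing cycle). In a
#' random genomic library the per-cycle C and G counts track each other; a
#' MeDIP-enriched strand-preserving library shows a C:G disparity in the
#' first-mate file because the immuno-capture selects the 5mC-carrying
#' strand. The per-cycle C/G ratio is therefore a quick library QC.
#'
#' @param fastq_file Path to a FASTQ file (plain or gzip).
#' @return An object of class \code{"base_freq_matrix"}: list with
#'   \code{counts} (cycles x bases integer matrix, columns A, C, G, T, N),
#'   \code{n_reads}, and \code{cg_ratio} (per-cycle C count / G count,
#'   \code{NaN} where both are 0).
#' @export
base_frequency_per_cycle <- function(fastq_file) {
  if (!file.exists(fastq_file))
    stop("FASTQ file not found: ", fastq_file)
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq_file, format = "fastq"),
    error = function(e) stop("malformed FASTQ: ", conditionMessage(e))
  )
  bases <- c("A", "C", "G", "T", "N")
  if (length(reads) == 0L) {
    counts <- matrix(0L, nrow = 0, ncol = 5, dimnames = list(NULL, bases))
    return(structure(list(counts = counts, n_reads = 0L,
                          cg_ratio = numeric(0)),
                     class = "base_freq_matrix"))
  }
  cm <- Biostrings::consensusMatrix(reads)
  n_cycles <- ncol(cm)
  counts <- matrix(0L, nrow = n_cycles, ncol = 5,
                   dimnames = list(NULL, bases))
  for (b in bases)
    if (b %in% rownames(cm)) counts[, b] <- as.integer(cm[b, ])
  # ambiguity codes other than N are counted as N
  other <- setdiff(rownames(cm), c(bases, "-", "+", "."))
  if (length(other))
    counts[, "N"] <- counts[, "N"] +
      as.integer(round(colSums(cm[other, , drop = FALSE])))
  structure(list(
    counts = counts,
    n_reads = length(reads),
    cg_ratio = counts[, "C"] / counts[, "G"]
  ), class = "base_freq_matrix")
}

#' @export
print.base_freq_matrix <- function(x, ...) {
  cat("Per-cycle base frequencies:", x$n_reads, "reads,",
      nrow(x$counts), "cycles\n")
  if (nrow(x$counts)) {
    cat(sprintf("  mean C/G ratio: %.3f (1 expected for a random library)\n",
                mean(x$cg_ratio[is.finite(x$cg_ratio)])))
  }
  invisible(x)
}
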