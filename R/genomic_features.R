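#' Strand-aware overlap counting
#'
#' For each query interval, counts the subject intervals with the same
#' sequence name, at least 1 bp of coordinate overlap and — when
#' \code{respect_strand} — a compatible strand pairing: \code{*} (both) is
#' compatible with every strand, while \code{+} and \code{-} are compatible
#' only with themselves or \code{*}.
#'
#' @param query,subject \code{GRanges}.
#' @param respect_strand Require strand compatibility; default \code{FALSE}.
#' @return Integer vector of length \code{length(query)}.
#' @export
count_overlaps <- function(query, subject, respect_strand = FALSE) {
  shared <- union(GenomeInfoDb::seqlevels(query),
                  GenomeInfoDb::seqlevels(subject))
  GenomeInfoDb::seqlevels(query) <- shared
  GenomeInfoDb::seqlevels(subject) <- shared
  unname(GenomicRanges::countOverlaps(query, subject,
                                      ignore.strand = !respect_strand))
}

.read_gff3 <- function(annotation) {
  if (methods::is(annotation, "GRanges")) return(annotation)
  if (!file.exists(annotation))
    stop("annotation file not found: ", annotation)
  rtracklayer::import(annotation, format = "gff3")
}

# exon GRanges grouped by transcript; transcripts inherit the gene strand
.exons_by_transcript <- function(gff) {
  ex <- gff[gff$type == "exon"]
  if (length(ex) == 0L) stop("annotation has no exon records")
  parent <- as.character(S4Vectors::unstrsplit(ex$Parent, sep = ","))
  S4Vectors::split(ex, parent)
}

.introns_by_transcript <- function(gff) {
  exl <- .exons_by_transcript(gff)
  lv <- GenomeInfoDb::seqlevels(gff)
  res <- lapply(names(exl), function(tx) {
    ex <- BiocGenerics::sort(exl[[tx]])
    if (length(ex) < 2L) return(NULL)
    s <- GenomicRanges::end(ex)[-length(ex)] + 1L
    e <- GenomicRanges::start(ex)[-1L] - 1L
    keep <- s <= e
    if (!any(keep)) return(NULL)
    gr <- GenomicRanges::GRanges(
      seqnames = as.character(GenomicRanges::seqnames(ex))[1],
      ranges = IRanges::IRanges(start = s[keep], end = e[keep]),
      strand = as.character(BiocGenerics::strand(ex))[1],
      transcript = tx
    )
    GenomeInfoDb::seqlevels(gr) <- lv
    gr
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L)
    GenomicRanges::GRanges()
  else
    unlist(methods::as(res, "GRangesList"))
}

#' Derive gene-anatomy feature sets from GFF3 annotation
#'
#' Produces the four classic gene-body feature sets used for
#' feature-normalised methylation profiles: \code{upstream2kb} (the
#' \code{flank} bp upstream of each gene's 5' end, on the gene's strand —
#' coordinates above the gene end for minus-strand genes),
#' \code{exon} and \code{intron} (per transcript, with introns computed as
#' the gaps between consecutive exons and identical intervals shared by
#' isoforms deduplicated, never flattened across gene models), and
#' \code{downstream2kb} (the flank past the 3' end). Flanks are clipped at
#' sequence boundaries when sequence lengths are known. Gene records without
#' a strand are skipped with a warning.
#'
#' @param annotation Path to a GFF3 file (or an already-imported
#'   \code{GRanges} of GFF3 records with a \code{type} column).
#' @param flank Flank width in bp; default 2000.
#' @return Named list of \code{GRanges}: \code{upstream2kb}, \code{exon},
#'   \code{intron}, \code{downstream2kb}. Each carries the gene/transcript
#'   strand.
#' @export
derive_gene_features <- function(annotation, flank = 2000) {
  gff <- .read_gff3(annotation)
  genes <- gff[gff$type == "gene"]
  if (length(genes) == 0L) stop("annotation has no gene records")
  unstranded <- as.character(BiocGenerics::strand(genes)) == "*"
  if (any(unstranded)) {
    warning(sum(unstranded), " gene record(s) without strand skipped")
    genes <- genes[!unstranded]
  }
  up <- GenomicRanges::flank(genes, width = flank, start = TRUE)
  dn <- GenomicRanges::flank(genes, width = flank, start = FALSE)
  clip <- function(gr) {
    gr <- GenomicRanges::restrict(gr, start = 1L)
    if (!any(is.na(GenomeInfoDb::seqlengths(gr))))
      gr <- GenomicRanges::trim(gr)
    gr[GenomicRanges::width(gr) > 0]
  }
  ex <- gff[gff$type == "exon"]
  ex <- ex[!as.character(BiocGenerics::strand(ex)) == "*"]
  intr <- .introns_by_transcript(gff)
  dedupe <- function(gr) {
    if (length(gr) == 0L) return(granges_clean(gr))
    key <- paste(GenomicRanges::seqnames(gr), GenomicRanges::start(gr),
                 GenomicRanges::end(gr), BiocGenerics::strand(gr))
    granges_clean(gr[!duplicated(key)])
  }
  granges_clean <- function(gr) {
    S4Vectors::mcols(gr) <- NULL
    names(gr) <- NULL
    gr
  }
  list(
    upstream2kb = granges_clean(clip(up)),
    exon = dedupe(ex),
    intron = dedupe(intr),
    downstream2kb = granges_clean(clip(dn))
  )
}

#' Derive splice donor and acceptor windows
#'
#' The donor site of an intron is its 5' end in transcription orientation
#' (the exon-to-intron boundary); the acceptor is its 3' end (intron-to-exon).
#' For a minus-strand intron the donor therefore sits at the HIGHER genomic
#' coordinate. Each junction gets one window of \code{half_width} bp either
#' side of the boundary base, carrying the transcript's strand; junctions
#' shared by isoforms are deduplicated by (sequence, position, strand).
#'
#' @param annotation GFF3 path or imported \code{GRanges}.
#' @param half_width Window half-width in bp; default 100.
#' @return List with \code{GRanges} elements \code{donor} and
#'   \code{acceptor}; each has a \code{site} metadata column with the
#'   boundary coordinate.
#' @export
derive_splice_sites <- function(annotation, half_width = 100) {
  gff <- .read_gff3(annotation)
  intr <- .introns_by_transcript(gff)
  mk <- function(pos, chr, str) {
    gr <- GenomicRanges::GRanges(
      seqnames = chr,
      ranges = IRanges::IRanges(start = pmax(1L, pos - as.integer(half_width)),
                                end = pos + as.integer(half_width)),
      strand = str, site = pos
    )
    key <- paste(chr, pos, str)
    gr[!duplicated(key)]
  }
  if (length(intr) == 0L) {
    empty <- GenomicRanges::GRanges()
    return(list(donor = empty, acceptor = empty))
  }
  chr <- as.character(GenomicRanges::seqnames(intr))
  str <- as.character(BiocGenerics::strand(intr))
  s <- GenomicRanges::start(intr)
  e <- GenomicRanges::end(intr)
  donor_pos <- ifelse(str == "+", s, e)
  accept_pos <- ifelse(str == "+", e, s)
  list(donor = mk(as.integer(donor_pos), chr, str),
       acceptor = mk(as.integer(accept_pos), chr, str))
}

# GRanges of classified peaks; classes: which strand_class values to keep
.calls_granges <- function(calls, classes = c("plus", "minus")) {
  pk <- if (inherits(calls, "strand_calls")) calls$peaks else calls
  stopifnot(all(c("seqnames", "start", "end", "strand_class") %in% names(pk)))
  pk <- pk[pk$strand_class %in% classes, , drop = FALSE]
  strand_chr <- c(plus = "+", minus = "-", both = "*", unclassified = "*")
  GenomicRanges::GRanges(
    seqnames = pk$seqnames,
    ranges = IRanges::IRanges(start = pk$start + 1L, end = pk$end),
    strand = strand_chr[as.character(pk$strand_class)],
    peak_id = pk$peak_id
  )
}

#' Sense/antisense asymmetry of single-stranded methylation at splice sites
#'
#' For donor and acceptor windows separately, every overlap between a
#' single-stranded peak (plus- or minus-class only) and a window is labelled
#' sense when the peak's strand equals the window's (the strand carrying the
#' annotated feature) and antisense otherwise. The null hypothesis that
#' single-stranded methylation falls equally on either side is tested with a
#' two-tailed one-sample proportion test (with continuity correction) per
#' site type.
#'
#' @param calls A \code{"strand_calls"} object (or its peak table).
#' @param donor,acceptor Window \code{GRanges} from
#'   \code{\link{derive_splice_sites}}.
#' @return Object of class \code{"splice_asymmetry"}: data.frame with one
#'   row per site type and columns \code{site_type}, \code{sense},
#'   \code{antisense}, \code{prop_sense}, \code{prop_antisense},
#'   \code{p.value} (\code{NA} when there are no overlaps).
#' @export
splice_asymmetry <- function(calls, donor, acceptor) {
  peaks <- .calls_granges(calls, classes = c("plus", "minus"))
  tally <- function(windows) {
    if (length(windows) == 0L || length(peaks) == 0L)
      return(c(sense = 0L, antisense = 0L))
    shared <- union(GenomeInfoDb::seqlevels(windows),
                    GenomeInfoDb::seqlevels(peaks))
    GenomeInfoDb::seqlevels(windows) <- shared
    pk <- peaks
    GenomeInfoDb::seqlevels(pk) <- shared
    hits <- GenomicRanges::findOverlaps(windows, pk, ignore.strand = TRUE)
    ws <- as.character(BiocGenerics::strand(windows))[S4Vectors::queryHits(hits)]
    ps <- as.character(BiocGenerics::strand(pk))[S4Vectors::subjectHits(hits)]
    c(sense = sum(ws == ps), antisense = sum(ws != ps))
  }
  rows <- lapply(list(donor = donor, acceptor = acceptor), tally)
  df <- do.call(rbind, lapply(names(rows), function(st) {
    n <- rows[[st]]
    total <- sum(n)
    p <- if (total > 0L)
      stats::prop.test(n["sense"], total, p = 0.5,
                       alternative = "two.sided")$p.value
    else NA_real_
    data.frame(site_type = st,
               sense = unname(n["sense"]),
               antisense = unname(n["antisense"]),
               prop_sense = if (total > 0) unname(n["sense"]) / total else NA,
               prop_antisense = if (total > 0)
                 unname(n["antisense"]) / total else NA,
               p.value = p,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  structure(df, class = c("splice_asymmetry", "data.frame"))
}

#' @export
print.splice_asymmetry <- function(x, ...) {
  cat("Single-stranded methylation at splice junctions (sense vs antisense)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-9s sense %d (%.1f%%) | antisense %d (%.1f%%) | p = %s\n",
                x$site_type[i], x$sense[i], 100 * x$prop_sense[i],
                x$antisense[i], 100 * x$prop_antisense[i],
                ifelse(is.na(x$p.value[i]), "NA (no overlaps)",
                       format(x$p.value[i], digits = 3))))
  }
  invisible(x)
}
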