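#' Read peak regions from BED or narrowPeak
#'
#' Auto-detects the dialect by column count: 3+ column BED or 10-column
#' narrowPeak (BED6+4). Input coordinates are 0-based half-open and are
#' preserved; internally they are held as a 1-based \code{GRanges}. Peaks
#' without a name column are named \code{peak_<i>} in file order.
#'
#' @param peak_file Path to a BED3/BED6/narrowPeak file.
#' @return \code{GRanges} with metadata columns \code{name} and \code{score}
#'   (NA when absent from the file).
#' @export
read_peaks <- function(peak_file) {
  if (!file.exists(peak_file))
    stop("peak file not found: ", peak_file)
  lines <- readLines(peak_file)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(lines)
  body <- lines[!skip]
  lineno <- which(!skip)
  if (length(body) == 0L)
    stop("no peak records in ", peak_file)
  tab <- utils::read.table(text = body, sep = "", header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  nc <- ncol(tab)
  if (nc < 3L)
    stop("need at least 3 BED columns, found ", nc)
  start <- suppressWarnings(as.numeric(tab[[2]]))
  end <- suppressWarnings(as.numeric(tab[[3]]))
  bad <- is.na(start) | is.na(end) | start >= end
  if (any(bad))
    stop("malformed peak interval (start >= end or non-numeric) at line ",
         lineno[which(bad)[1]], " of ", peak_file)
  name <- if (nc >= 4L) tab[[4]] else sprintf("peak_%d", seq_along(start))
  score <- if (nc >= 5L) suppressWarnings(as.numeric(tab[[5]])) else
    rep(NA_real_, length(start))
  gr <- GenomicRanges::GRanges(
    seqnames = tab[[1]],
    ranges = IRanges::IRanges(start = start + 1, end = end),
    name = name, score = score
  )
  names(gr) <- name
  gr
}

#' Count first-mate reads per peak, split by strand
#'
#' For each peak, \code{y_plus} and \code{y_minus} are the numbers of
#' filtered first-mate alignments on the forward and reverse strand whose
#' span overlaps the peak interval by at least 1 bp (a read overlapping two
#' peaks is counted in both). \code{theta = y_plus / y_total} is the observed
#' plus-strand fraction, \code{NA} for empty peaks.
#'
#' @param peaks \code{GRanges} of peak regions (from \code{\link{read_peaks}}).
#' @param alignments \code{GRanges} of first-mate alignments (from
#'   \code{\link{load_first_mates}}), strand \code{+}/\code{-}.
#' @param missing_seqnames \code{"warn"} (default; peaks on sequences absent
#'   from the alignment set get zero counts) or \code{"error"}.
#' @return \code{data.frame} with one row per peak: \code{peak_id},
#'   \code{seqnames}, \code{start}, \code{end} (0-based half-open),
#'   \code{width}, \code{y_plus}, \code{y_minus}, \code{y_total},
#'   \code{theta}.
#' @export
count_strands <- function(peaks, alignments,
                          missing_seqnames = c("warn", "error")) {
  missing_seqnames <- match.arg(missing_seqnames)
  aln_levels <- GenomeInfoDb::seqlevels(alignments)
  absent <- setdiff(unique(as.character(GenomicRanges::seqnames(peaks))),
                    aln_levels)
  if (length(absent)) {
    msg <- paste0("peak sequence(s) absent from alignments: ",
                  paste(absent, collapse = ", "))
    if (missing_seqnames == "error") stop(msg)
    warning(msg, "; reporting zero counts there")
  }
  shared <- union(GenomeInfoDb::seqlevels(peaks), aln_levels)
  q <- peaks
  s <- alignments
  GenomeInfoDb::seqlevels(q) <- shared
  GenomeInfoDb::seqlevels(s) <- shared
  plus <- s[BiocGenerics::strand(s) == "+"]
  minus <- s[BiocGenerics::strand(s) == "-"]
  y_plus <- GenomicRanges::countOverlaps(q, plus, ignore.strand = TRUE)
  y_minus <- GenomicRanges::countOverlaps(q, minus, ignore.strand = TRUE)
  y_total <- y_plus + y_minus
  nm <- if (!is.null(peaks$name)) peaks$name else
    sprintf("peak_%d", seq_along(peaks))
  data.frame(
    peak_id = nm,
    seqnames = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    width = GenomicRanges::width(peaks),
    y_plus = unname(y_plus),
    y_minus = unname(y_minus),
    y_total = unname(y_total),
    theta = ifelse(y_total > 0, y_plus / y_total, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Classify every peak in a strand-count table
#'
#' Applies \code{\link{classify_peak}} to each row of a
#' \code{\link{count_strands}} table and collects the calls, the class tally
#' and the single-stranded fraction into a \code{"strand_calls"} object.
#'
#' @param counts \code{data.frame} from \code{\link{count_strands}} (any
#'   data.frame with \code{y_plus} and \code{y_minus} columns works; peak
#'   coordinates, when present, are carried through for track export).
#' @param alpha Likelihood-ratio cutoff, default 0.1.
#' @param min_depth Minimum total first-mate depth; peaks below it are
#'   reported \code{"unclassified"}, not dropped. Default 0.
#' @return Object of class \code{"strand_calls"}: list with \code{peaks}
#'   (the input table plus \code{strand_class}, \code{low_depth},
#'   likelihood-set bounds \code{ls_plus_min/max}, \code{ls_minus_min/max},
#'   and \code{n_shared} intersection size), \code{tally} (named counts
#'   \code{plus}, \code{minus}, \code{both}, \code{unclassified}),
#'   \code{single_stranded_fraction} (among classified peaks), \code{alpha},
#'   \code{min_depth}.
#' @export
classify_all <- function(counts, alpha = 0.1, min_depth = 0) {
  stopifnot(is.data.frame(counts),
            all(c("y_plus", "y_minus") %in% names(counts)))
  n <- nrow(counts)
  ids <- if ("peak_id" %in% names(counts)) counts$peak_id else
    sprintf("peak_%d", seq_len(n))
  cls <- character(n)
  low <- logical(n)
  lpmin <- lpmax <- lmmin <- lmmax <- nshared <- integer(n)
  for (i in seq_len(n)) {
    r <- classify_peak(counts$y_plus[i], counts$y_minus[i],
                       alpha = alpha, min_depth = min_depth,
                       peak_id = ids[i])
    cls[i] <- r$strand_class
    low[i] <- r$low_depth_flag
    lpmin[i] <- min(r$ls_plus); lpmax[i] <- max(r$ls_plus)
    lmmin[i] <- min(r$ls_minus); lmmax[i] <- max(r$ls_minus)
    nshared[i] <- length(r$intersection)
  }
  out <- counts
  out$peak_id <- ids
  out$strand_class <- factor(cls, levels = c("plus", "minus", "both",
                                             "unclassified"))
  out$low_depth <- low
  out$ls_plus_min <- lpmin; out$ls_plus_max <- lpmax
  out$ls_minus_min <- lmmin; out$ls_minus_max <- lmmax
  out$n_shared <- nshared
  tally <- table(out$strand_class)
  tally <- stats::setNames(as.integer(tally), names(tally))
  n_classified <- sum(tally[c("plus", "minus", "both")])
  structure(list(
    peaks = out,
    tally = tally,
    single_stranded_fraction =
      if (n_classified > 0) unname((tally["plus"] + tally["minus"]) /
                                     n_classified) else NA_real_,
    alpha = alpha,
    min_depth = min_depth
  ), class = "strand_calls")
}

#' Strand-classify MeDIP-Seq peaks from alignments
#'
#' The end-to-end pipeline: load filtered first-mate alignments, count them
#' per peak by strand, and run the likelihood-set classifier on every peak.
#'
#' @param alignment_file BAM/SAM of paired-end MeDIP-Seq alignments.
#' @param peak_file BED/narrowPeak of peak regions, or a \code{GRanges}.
#' @param alpha Likelihood-ratio cutoff, default 0.1.
#' @param min_depth Minimum first-mate depth for a confident call; default 12.
#' @param ... Passed to \code{\link{load_first_mates}} (\code{min_mapq},
#'   \code{drop_duplicates}, \code{proper_pairs_only}).
#' @return A \code{"strand_calls"} object (see \code{\link{classify_all}})
#'   with the alignment filter summary attached as attribute
#'   \code{"filter_summary"}.
#' @examples
#' \dontrun{
#' calls <- call_strands("sample.bam", "peaks.narrowPeak")
#' summary(calls)
#' }
#' @export
call_strands <- function(alignment_file, peak_file, alpha = 0.1,
                         min_depth = 12, ...) {
  aln <- load_first_mates(alignment_file, ...)
  peaks <- if (methods::is(peak_file, "GRanges")) peak_file else
    read_peaks(peak_file)
  counts <- count_strands(peaks, aln)
  calls <- classify_all(counts, alpha = alpha, min_depth = min_depth)
  attr(calls, "filter_summary") <- attr(aln, "filter_summary")
  calls
}

#' @export
print.strand_calls <- function(x, ...) {
  cat("Strand-classified methylation peaks\n")
  cat(sprintf("  %d peaks, alpha = %g, min depth = %d\n",
              nrow(x$peaks), x$alpha, x$min_depth))
  cat(sprintf("  plus %d | minus %d | both %d | unclassified %d\n",
              x$tally["plus"], x$tally["minus"], x$tally["both"],
              x$tally["unclassified"]))
  if (!is.na(x$single_stranded_fraction))
    cat(sprintf("  single-stranded fraction (of classified): %.1f%%\n",
                100 * x$single_stranded_fraction))
  invisible(x)
}

#' @method summary strand_calls
#' @export
summary.strand_calls <- function(object, ...) {
  print(object)
  cl <- object$peaks$strand_class
  ok <- cl != "unclassified"
  if (any(ok)) {
    cat("  depth by class (median y_total):\n")
    med <- tapply(object$peaks$y_total[ok], droplevels(cl[ok]), stats::median)
    for (k in names(med))
      cat(sprintf("    %-6s %g\n", k, med[k]))
  }
  fs <- attr(object, "filter_summary")
  if (!is.null(fs)) {
    cat("  alignment filter: ")
    cat(paste(names(fs), fs, sep = "=", collapse = ", "), "\n")
  }
  invisible(object)
}

#' @method as.data.frame strand_calls
#' @export
as.data.frame.strand_calls <- function(x, ...) x$peaks

#' Plot per-strand read depth of classified peaks
#'
#' Scatter of minus- against plus-strand first-mate depth, one point per
#' peak, coloured by call. Single-stranded calls occupy the off-diagonal
#' wedges with well-defined linear boundaries; double-stranded calls hug the
#' diagonal.
#'
#' @param x A \code{"strand_calls"} object.
#' @param ... Passed to \code{plot}.
#' @method plot strand_calls
#' @export
plot.strand_calls <- function(x, ...) {
  pk <- x$peaks
  cols <- c(plus = "grey10", minus = "grey45", both = "grey75",
            unclassified = "grey90")
  graphics::plot(pk$y_plus, pk$y_minus,
                 col = cols[as.character(pk$strand_class)], pch = 16,
                 xlab = "first-mate depth, plus strand",
                 ylab = "first-mate depth, minus strand", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Test class composition against peak width
#'
#' Wide peaks could plausibly mix single- and double-stranded methylation.
#' Peaks are split into width groups at the given quantiles (the default
#' 50/95 boundaries give groups holding 50, 45 and 5 per cent of the peaks),
#' classes are cross-tabulated against groups, and a Pearson chi-squared test
#' of independence is run. Unclassified peaks are excluded.
#'
#' @param calls A \code{"strand_calls"} object whose peak table has a
#'   \code{width} column, or such a data.frame.
#' @param quantile_bounds Interior width quantiles delimiting the groups;
#'   default \code{c(0.50, 0.95)} (three groups).
#' @return List of class \code{"width_bias_test"}: \code{table} (group x
#'   class contingency table), \code{statistic}, \code{df}, \code{p.value},
#'   \code{expected}, and \code{low_expected} (TRUE when any expected cell
#'   is below 1, attached as a warning on the result rather than thrown).
#' @export
width_bias_test <- function(calls, quantile_bounds = c(0.50, 0.95)) {
  pk <- if (inherits(calls, "strand_calls")) calls$peaks else calls
  stopifnot(all(c("width", "strand_class") %in% names(pk)))
  pk <- pk[pk$strand_class != "unclassified", , drop = FALSE]
  if (length(unique(pk$width)) < length(quantile_bounds) + 1L)
    stop("need at least ", length(quantile_bounds) + 1L,
         " distinct peak widths")
  qs <- stats::quantile(pk$width, probs = quantile_bounds)
  brk <- unique(c(-Inf, qs, Inf))
  grp <- cut(pk$width, breaks = brk,
             labels = sprintf("group_%d", seq_len(length(brk) - 1L)))
  tab <- table(width_group = grp, class = droplevels(pk$strand_class))
  ht <- suppressWarnings(stats::chisq.test(tab))
  structure(list(
    table = tab,
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = ht$p.value,
    expected = ht$expected,
    low_expected = any(ht$expected < 1)
  ), class = "width_bias_test")
}

#' @export
print.width_bias_test <- function(x, ...) {
  cat("Peak width vs strand class (Pearson chi-squared independence test)\n")
  print(x$table)
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  if (x$low_expected)
    cat("  warning: some expected cell counts < 1\n")
  invisible(x)
}

#' Write stranded peak and coverage tracks
#'
#' Writes, under a common prefix: \code{<prefix>_peaks.bed}, a BED6 of the
#' peaks with the strand column set per class (\code{+}, \code{-}, or
#' \code{.} for double-stranded/unclassified) and score = total first-mate
#' depth; \code{<prefix>_report.tsv}, the full per-peak report (counts,
#' theta, class, likelihood-set bounds); and, when \code{alignments} is
#' given, \code{<prefix>_plus.bedgraph} / \code{<prefix>_minus.bedgraph}
#' per-strand first-mate coverage tracks.
#'
#' @param calls A \code{"strand_calls"} object with peak coordinates.
#' @param out_prefix Output path prefix.
#' @param alignments Optional first-mate \code{GRanges} for the coverage
#'   tracks.
#' @return Invisibly, the character vector of files written.
#' @export
write_stranded_tracks <- function(calls, out_prefix, alignments = NULL) {
  stopifnot(inherits(calls, "strand_calls"))
  pk <- calls$peaks
  if (!all(c("seqnames", "start", "end") %in% names(pk)))
    stop("peak table lacks coordinates; classify counts from count_strands()")
  if (nrow(pk) == 0L) stop("no peaks to write")
  strand_chr <- c(plus = "+", minus = "-", both = "*", unclassified = "*")
  gr <- GenomicRanges::GRanges(
    seqnames = pk$seqnames,
    ranges = IRanges::IRanges(start = pk$start + 1L, end = pk$end),
    strand = strand_chr[as.character(pk$strand_class)]
  )
  gr$name <- pk$peak_id
  gr$score <- pk$y_total
  files <- character(0)
  bed <- paste0(out_prefix, "_peaks.bed")
  rtracklayer::export(gr, bed, format = "BED")
  files <- c(files, bed)

  tsv <- paste0(out_prefix, "_report.tsv")
  utils::write.table(pk, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, tsv)

  if (!is.null(alignments)) {
    for (s in c("+", "-")) {
      cov <- GenomicRanges::coverage(
        alignments[BiocGenerics::strand(alignments) == s])
      cg <- methods::as(cov, "GRanges")
      cg <- cg[cg$score > 0]
      f <- paste0(out_prefix, if (s == "+") "_plus" else "_minus",
                  ".bedgraph")
      rtracklayer::export(cg, f, format = "bedGraph")
      files <- c(files, f)
    }
  }
  invisible(files)
}
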