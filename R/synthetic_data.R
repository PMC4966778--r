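#' Configuration for the strand-preserving MeDIP simulator
#'
#' Bundles and validates every knob of \code{\link{simulate_medip}}. The
#' defaults describe a small but realistic strand-preserving MeDIP library
#' over a toy genome: two 500 kb scaffolds, 80 multi-exon genes, 100
#' non-overlapping peaks of 260-600 bp (median near the ~430 bp typical of
#' MACS2-called methylation windows), a per-strand Poisson depth of 50
#' first-mate reads on each methylated strand, 2 per cent cross-contamination
#' on the unrepresented strand of single-stranded peaks, and 1 background
#' read per kb.
#'
#' @param seed Integer seed; every random draw comes from this one stream.
#' @param n_sequences Number of scaffolds.
#' @param sequence_length Length of each scaffold (bp).
#' @param n_genes Number of genes (multi-exon, one transcript each).
#' @param exons_per_gene Integer range \code{c(min, max)} of exons per gene.
#' @param n_peaks Number of methylation peaks to place.
#' @param class_fractions Numeric \code{c(plus, minus, both)} truth-class
#'   fractions, summing to 1.
#' @param depth_mean Per-strand Poisson mean first-mate depth on each
#'   methylated strand of a peak.
#' @param epsilon Cross-contamination: the unrepresented strand of a
#'   single-stranded peak receives Poisson(\code{epsilon * depth_mean})
#'   reads (0 gives the clean idealisation).
#' @param background_rate Background first-mate reads per kb, scattered
#'   uniformly over the genome on random strands.
#' @param read_length Read length (bp).
#' @param peak_width Peak width range \code{c(min, max)} in bp; each peak's
#'   width is drawn uniformly from it (a single value gives fixed-width
#'   peaks). The default 260-600 bp gives a median near the ~430 bp typical
#'   of MACS2 methylation windows.
#' @param genic_fraction Fraction of peaks hosted inside genes; genic
#'   single-stranded peaks are centred on a splice junction of their host.
#' @param antisense_bias Probability that a genic single-stranded peak lies
#'   antisense to its host gene; 0.5 is strand-neutral.
#' @return Validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(seed,
                              n_sequences = 2,
                              sequence_length = 500000,
                              n_genes = 80,
                              exons_per_gene = c(2, 6),
                              n_peaks = 100,
                              class_fractions = c(plus = 0.4, minus = 0.4,
                                                  both = 0.2),
                              depth_mean = 50,
                              epsilon = 0.02,
                              background_rate = 1,
                              read_length = 50,
                              peak_width = c(260, 600),
                              genic_fraction = 0.6,
                              antisense_bias = 0.5) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_sequences >= 1, sequence_length > 0, n_genes >= 1,
            length(exons_per_gene) == 2L, exons_per_gene[1] >= 1,
            exons_per_gene[2] >= exons_per_gene[1],
            n_peaks >= 1, length(class_fractions) == 3L,
            depth_mean > 0, epsilon >= 0, background_rate >= 0,
            read_length > 0, length(peak_width) %in% c(1L, 2L),
            all(peak_width >= read_length),
            genic_fraction >= 0, genic_fraction <= 1,
              antisense_bias >= 0, antisense_bias <= 1)
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("'class_fractions' must sum to 1")
  structure(list(
    seed = as.integer(seed), n_sequences = as.integer(n_sequences),
    sequence_length = as.integer(sequence_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    n_peaks = as.integer(n_peaks),
    class_fractions = stats::setNames(as.numeric(class_fractions),
                                      c("plus", "minus", "both")),
    depth_mean = depth_mean, epsilon = epsilon,
    background_rate = background_rate,
    read_length = as.integer(read_length),
    peak_width = as.integer(rep(peak_width, length.out = 2L)),
    genic_fraction = genic_fraction,
    antisense_bias = antisense_bias
  ), class = "simulation_config")
}

#' Simulate a strand-preserving MeDIP-Seq dataset with known truth
#'
#' Generates, fully reproducibly from \code{config$seed}, a bundle emulating
#' the three methylation scenarios of a strand-preserving MeDIP library:
#' peaks with 5mC on both strands, on the plus strand only, or on the minus
#' strand only. Reads are emitted as already-aligned, coordinate-sorted
#' paired-end records (the tool consumes alignments, so the aligner is
#' outside the simulated surface): each peak draws
#' Poisson(\code{depth_mean}) first mates on each methylated strand and
#' Poisson(\code{epsilon * depth_mean}) on an unmethylated strand, placed
#' uniformly within the peak; background first mates are scattered uniformly
#' genome-wide. Peak genome sequence is composition-planted so that the
#' methylated strand is C-rich, which makes the library's per-cycle C:G
#' disparity visible to \code{\link{base_frequency_per_cycle}} on the
#' first-mate FASTQ. A truth table records every peak's class, drawn
#' per-strand counts, host gene and sense/antisense orientation, and a
#' stranded single-base 5mC call table consistent with each peak's class is
#' produced for concordance analyses.
#'
#' Randomness is drawn from one stream in a fixed order: scaffold sequence,
#' gene placement/structure, peak classes and placement, composition
#' planting, read counts and positions, background reads, 5mC calls.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param out_dir Output directory (created if needed).
#' @return List of class \code{"medip_simulation"}: \code{files} (named
#'   paths: \code{genome}, \code{annotation}, \code{truth}, \code{bam},
#'   \code{peaks}, \code{calls}, \code{fastq}), \code{truth} (data.frame),
#'   \code{n_background} (background first mates drawn), \code{config}.
#' @export
simulate_medip <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  rl <- config$read_length

  ## 1. genome ---------------------------------------------------------
  seqnames <- sprintf("scaffold_%d", seq_len(config$n_sequences))
  genome <- lapply(seqnames, function(s)
    sample(c("A", "C", "G", "T"), config$sequence_length, replace = TRUE))
  names(genome) <- seqnames

  ## 2. genes ----------------------------------------------------------
  genes <- .place_genes(config, seqnames)

  ## 3. peaks: classes, hosts, placement -------------------------------
  classes <- sample(c("plus", "minus", "both"), config$n_peaks,
                    replace = TRUE, prob = config$class_fractions)
  peaks <- .place_peaks(config, classes, genes, seqnames)

  ## 4. composition planting: methylated strand C-rich inside peaks ----
  for (i in seq_len(nrow(peaks))) {
    span <- (peaks$start[i] + 1L):peaks$end[i]   # 1-based genome index
    probs <- switch(peaks$class[i],
      plus = c(A = .20, C = .45, G = .10, T = .25),   # plus strand C-rich
      minus = c(A = .25, C = .10, G = .45, T = .20),  # minus strand C-rich
      both = c(A = .20, C = .30, G = .30, T = .20))
    genome[[peaks$seqnames[i]]][span] <-
      sample(names(probs), length(span), replace = TRUE, prob = probs)
  }

  ## 5. reads ----------------------------------------------------------
  reads <- .draw_peak_reads(config, peaks)
  peaks$y_plus_true <- reads$y_plus
  peaks$y_minus_true <- reads$y_minus

  ## 6. background -----------------------------------------------------
  total_kb <- config$n_sequences * config$sequence_length / 1000
  n_bg <- stats::rpois(1, config$background_rate * total_kb)
  bg <- if (n_bg > 0) data.frame(
    seqnames = sample(seqnames, n_bg, replace = TRUE,
                      prob = rep(config$sequence_length, length(seqnames))),
    start = NA_integer_,
    strand = sample(c("+", "-"), n_bg, replace = TRUE),
    stringsAsFactors = FALSE
  ) else data.frame(seqnames = character(0), start = integer(0),
                    strand = character(0))
  if (n_bg > 0)
    bg$start <- vapply(seq_len(n_bg), function(i)
      sample.int(config$sequence_length - rl, 1L) - 1L, integer(1))
  all_reads <- rbind(reads$table, bg)

  ## 7. stranded single-base calls -------------------------------------
  calls <- .draw_methyl_calls(peaks)

  ## 8. write files ----------------------------------------------------
  files <- .write_bundle(genome, genes, peaks, all_reads, calls,
                         config, out_dir)
  truth <- data.frame(
    peak_id = peaks$peak_id, seqnames = peaks$seqnames,
    start = peaks$start, end = peaks$end, class = peaks$class,
    y_plus_true = peaks$y_plus_true, y_minus_true = peaks$y_minus_true,
    host_gene = peaks$host_gene, orientation = peaks$orientation,
    stringsAsFactors = FALSE
  )
  utils::write.table(truth, files["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  structure(list(files = files, truth = truth, n_background = n_bg,
                 config = config),
            class = "medip_simulation")
}

#' @export
print.medip_simulation <- function(x, ...) {
  cat("Simulated strand-preserving MeDIP dataset\n")
  cat(sprintf("  %d peaks (%s), seed %d\n", nrow(x$truth),
              paste(names(table(x$truth$class)), table(x$truth$class),
                    sep = "=", collapse = ", "),
              x$config$seed))
  cat("  files:", paste(basename(x$files), collapse = ", "), "\n")
  invisible(x)
}

# non-overlapping gene placement with multi-exon structure
.place_genes <- function(config, seqnames) {
  n_exons <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
                    config$n_genes, replace = TRUE)
  scaffold <- rep(seqnames, length.out = config$n_genes)
  rows <- vector("list", config$n_genes)
  cursor <- stats::setNames(rep(3000L, length(seqnames)), seqnames)
  for (g in seq_len(config$n_genes)) {
    sc <- scaffold[g]
    exon_len <- sample(150:400, n_exons[g], replace = TRUE)
    intron_len <- if (n_exons[g] > 1)
      sample(500:1500, n_exons[g] - 1L, replace = TRUE) else integer(0)
    gap <- sample(2000:5000, 1L)
    gstart <- cursor[sc] + gap             # 0-based
    glen <- sum(exon_len) + sum(intron_len)
    if (gstart + glen > config$sequence_length - 3000L)
      stop("cannot place ", config$n_genes, " genes in ",
           config$n_sequences, " x ", config$sequence_length,
           " bp; increase sequence_length or n_sequences")
    starts <- gstart + cumsum(c(0L, exon_len[-n_exons[g]] + intron_len))
    rows[[g]] <- data.frame(
      gene_id = sprintf("gene_%d", g), seqnames = sc,
      start = gstart, end = gstart + glen,
      strand = sample(c("+", "-"), 1L),
      exon_starts = I(list(starts)),
      exon_ends = I(list(starts + exon_len)),
      stringsAsFactors = FALSE
    )
    cursor[sc] <- gstart + glen
  }
  do.call(rbind, rows)
}

# splice junction positions (0-based boundary coordinates) of one gene
.gene_junctions <- function(gene) {
  es <- gene$exon_starts[[1]]
  ee <- gene$exon_ends[[1]]
  k <- length(es)
  if (k < 2L) return(integer(0))
  sort(c(ee[-k], es[-1L]))   # intron starts (exon ends) + intron ends
}

.place_peaks <- function(config, classes, genes, seqnames) {
  n <- config$n_peaks
  pwr <- config$peak_width
  widths <- if (pwr[1] == pwr[2]) rep(pwr[1], n) else
    pwr[1] + vapply(seq_len(n), function(i)
      sample.int(pwr[2] - pwr[1] + 1L, 1L) - 1L, integer(1))
  genic <- stats::runif(n) < config$genic_fraction
  occupied <- lapply(seqnames, function(s) cbind(start = integer(0),
                                                 end = integer(0)))
  names(occupied) <- seqnames
  clash <- function(sc, s, e)
    any(occupied[[sc]][, "start"] < e & occupied[[sc]][, "end"] > s)
  out <- data.frame(peak_id = sprintf("peak_%d", seq_len(n)),
                    seqnames = NA_character_, start = NA_integer_,
                    end = NA_integer_, class = classes,
                    strand = NA_character_, host_gene = NA_character_,
                    orientation = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    placed <- FALSE
    # a peak's strand IS its truth class; for genic single-stranded peaks
    # the sense/antisense orientation is realised by choosing a host gene
    # of the compatible strand
    ps <- switch(classes[i], plus = "+", minus = "-", both = "*")
    for (try in seq_len(500L)) {
      pw <- widths[i]
      half <- pw %/% 2L
      anti <- NA
      if (genic[i]) {
        if (classes[i] == "both") {
          g <- genes[sample.int(nrow(genes), 1L), ]
          centre <- g$start + sample.int(max(1L, g$end - g$start), 1L)
        } else {
          anti <- stats::runif(1) < config$antisense_bias
          gs_needed <- if (anti) setdiff(c("+", "-"), ps) else ps
          cand <- which(genes$strand == gs_needed)
          if (length(cand) == 0L) next
          g <- genes[cand[sample.int(length(cand), 1L)], ]
          j <- .gene_junctions(g)
          if (length(j) == 0L) next
          centre <- j[sample.int(length(j), 1L)]
        }
        sc <- g$seqnames
      } else {
        sc <- sample(seqnames, 1L,
                     prob = rep(config$sequence_length, length(seqnames)))
        centre <- sample.int(config$sequence_length - pw, 1L) + half
      }
      s <- centre - half
      e <- s + pw
      if (s < 0L || e > config$sequence_length) next
      if (clash(sc, s, e)) next
      occupied[[sc]] <- rbind(occupied[[sc]], c(start = s, end = e))
      out$seqnames[i] <- sc
      out$start[i] <- as.integer(s)
      out$end[i] <- as.integer(e)
      out$strand[i] <- ps
      if (genic[i]) {
        out$host_gene[i] <- g$gene_id
        if (classes[i] != "both")
          out$orientation[i] <- if (anti) "antisense" else "sense"
      }
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place peak ", i, " without overlap; ",
           "increase sequence_length / n_sequences or reduce n_peaks")
  }
  out
}

.draw_peak_reads <- function(config, peaks) {
  rl <- config$read_length
  n <- nrow(peaks)
  y_plus <- integer(n)
  y_minus <- integer(n)
  tabs <- vector("list", n)
  for (i in seq_len(n)) {
    lam_plus <- switch(peaks$class[i],
                       both = config$depth_mean,
                       plus = config$depth_mean,
                       minus = config$epsilon * config$depth_mean)
    lam_minus <- switch(peaks$class[i],
                        both = config$depth_mean,
                        minus = config$depth_mean,
                        plus = config$epsilon * config$depth_mean)
    y_plus[i] <- stats::rpois(1, lam_plus)
    y_minus[i] <- stats::rpois(1, lam_minus)
    k <- y_plus[i] + y_minus[i]
    if (k == 0L) { tabs[[i]] <- NULL; next }
    span <- peaks$end[i] - peaks$start[i] - rl
    tabs[[i]] <- data.frame(
      seqnames = peaks$seqnames[i],
      start = peaks$start[i] + sample.int(span, k, replace = TRUE) - 1L,
      strand = rep(c("+", "-"), c(y_plus[i], y_minus[i])),
      stringsAsFactors = FALSE
    )
  }
  list(y_plus = y_plus, y_minus = y_minus,
       table = do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))]))
}

.draw_methyl_calls <- function(peaks) {
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    k <- 2L + stats::rpois(1, 8)
    pos <- peaks$start[i] + sample.int(peaks$end[i] - peaks$start[i], k,
                                       replace = TRUE) - 1L
    if (peaks$class[i] == "both") {
      strand <- rep(c("+", "-"), length.out = k)
      context <- rep("CG", k)
    } else {
      strand <- rep(if (peaks$class[i] == "plus") "+" else "-", k)
      context <- sample(c("CG", "CHG", "CHH"), k, replace = TRUE,
                        prob = c(0.2, 0.2, 0.6))
    }
    data.frame(seqname = peaks$seqnames[i], position = pos,
               strand = strand, context = context,
               supporting_reads = 3L + stats::rpois(k, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), character(1)))
}

.write_bundle <- function(genome, genes, peaks, reads, calls, config,
                          out_dir) {
  rl <- config$read_length
  f <- function(name) file.path(out_dir, name)
  files <- c(genome = f("genome.fasta"), annotation = f("annotation.gff3"),
             truth = f("truth.tsv"), bam = f("alignments.bam"),
             peaks = f("peaks.bed"), calls = f("calls.tsv"),
             fastq = f("reads_1.fastq"))

  ## FASTA
  dss <- Biostrings::DNAStringSet(vapply(genome, paste, character(1),
                                         collapse = ""))
  names(dss) <- names(genome)
  Biostrings::writeXStringSet(dss, files["genome"], width = 70L)

  ## GFF3 (1-based inclusive)
  gff <- c("##gff-version 3")
  for (g in seq_len(nrow(genes))) {
    gn <- genes[g, ]
    tx <- paste0(gn$gene_id, ".t1")
    gff <- c(gff,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              gn$seqnames, gn$start + 1L, gn$end, gn$strand, gn$gene_id),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              gn$seqnames, gn$start + 1L, gn$end, gn$strand, tx, gn$gene_id))
    es <- gn$exon_starts[[1]]; ee <- gn$exon_ends[[1]]
    gff <- c(gff, sprintf(
      "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
      gn$seqnames, es + 1L, ee, gn$strand, tx, seq_along(es), tx))
  }
  writeLines(gff, files["annotation"])

  ## peaks BED (0-based half-open)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.", peaks$seqnames, peaks$start,
                     peaks$end, peaks$peak_id), files["peaks"])

  ## calls TSV
  utils::write.table(calls, files["calls"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## SAM -> sorted BAM (+index); proper pairs, first mate carries signal
  ord <- order(reads$seqnames, reads$start)
  reads <- reads[ord, , drop = FALSE]
  n <- nrow(reads)
  seqlen <- vapply(genome, length, integer(1))
  refseq <- function(sc, s0, len) {
    paste(genome[[sc]][(s0 + 1L):(s0 + len)], collapse = "")
  }
  qual <- strrep("I", rl)
  sam <- character(0)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), seqlen))
  recs <- vector("list", n)
  fq <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- reads$seqnames[i]
    s0 <- reads$start[i]
    plus <- reads$strand[i] == "+"
    mate0 <- if (plus) min(s0 + rl, seqlen[sc] - rl) else max(0L, s0 - rl)
    seq1 <- refseq(sc, s0, rl)
    seq2 <- refseq(sc, mate0, rl)
    qn <- sprintf("read_%07d", i)
    tlen <- if (plus) (mate0 + rl - s0) else -(s0 + rl - mate0)
    recs[[i]] <- c(
      paste(qn, if (plus) 99L else 83L, sc, s0 + 1L, 60L,
            paste0(rl, "M"), "=", mate0 + 1L, tlen, seq1, qual,
            sep = "\t"),
      paste(qn, if (plus) 147L else 163L, sc, mate0 + 1L, 60L,
            paste0(rl, "M"), "=", s0 + 1L, -tlen, seq2, qual,
            sep = "\t"))
    fq[[i]] <- c(paste0("@", qn, "/1"),
                 if (plus) seq1 else .revcomp(seq1),
                 "+", qual)
  }
  # mates are written next to their firsts; sort once more by position
  body <- unlist(recs)
  pos <- as.integer(sub("^[^\t]+\t[^\t]+\t[^\t]+\t([0-9]+)\t.*", "\\1", body))
  rname <- sub("^[^\t]+\t[^\t]+\t([^\t]+)\t.*", "\\1", body)
  sam_path <- f("alignments.sam")
  writeLines(c(hdr, body[order(match(rname, names(genome)), pos)]), sam_path)
  Rsamtools::asBam(sam_path, destination = sub("\\.bam$", "", files["bam"]),
                   overwrite = TRUE, indexDestination = TRUE)
  unlink(sam_path)

  writeLines(unlist(fq), files["fastq"])
  files
}
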