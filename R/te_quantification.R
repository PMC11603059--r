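#' Read and write the tabular read-alignment exchange format
#'
#' The canonical alignment exchange format is a 7-column TSV with header
#' `read_id, contig_id, aln_start, aln_end, read_length, aligned_bases,
#' matches`; coordinates are 0-based half-open on the contig,
#' `aligned_bases` is the number of read bases aligned to the reference and
#' `matches` the subset of those identical to it. SAM input is supported
#' through [read_alignment_sam()].
#'
#' @param file Path to the TSV.
#' @return Data frame of class `read_alignment`.
#' @export
read_alignment_tsv <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("read_id", "contig_id", "aln_start", "aln_end",
            "read_length", "aligned_bases", "matches")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("alignment table is missing columns: ", paste(miss, collapse = ", "))
  }
  validate_alignments(x[need])
}

#' @rdname read_alignment_tsv
#' @param alignments A `read_alignment` data frame.
#' @export
write_alignment_tsv <- function(alignments, file) {
  utils::write.table(as.data.frame(alignments), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

validate_alignments <- function(x) {
  bad <- which(x$aligned_bases <= 0 | x$aligned_bases > x$read_length |
                 x$matches > x$aligned_bases | x$matches < 0 |
                 (x$aln_end - x$aln_start) < 1)
  if (length(bad)) {
    stop(sprintf("invalid alignment record(s) at row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  class(x) <- c("read_alignment", "data.frame")
  x
}

#' Read alignments from a SAM file
#'
#' Imports mapped records of a SAM file via Rsamtools/GenomicAlignments
#' (converting to BAM in a temporary directory). `aligned_bases` is the
#' number of read bases in M/=/X CIGAR operations, `read_length` the query
#' width including soft clips, and `matches` is derived from the `NM` tag
#' as `aligned_bases - NM` (floored at 0), which is exact for gap-free
#' alignments. Secondary and unmapped records are skipped.
#'
#' @param file Path to a SAM file.
#' @return Data frame of class `read_alignment`.
#' @export
read_alignment_sam <- function(file) {
  for (pkg in c("Rsamtools", "GenomicAlignments")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("package '", pkg, "' is required to read SAM input")
    }
  }
  bam <- Rsamtools::asBam(file, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "qwidth"), tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  cig <- GenomicAlignments::cigar(ga)
  aligned <- GenomicAlignments::cigarOpTable(cig)
  aligned_bases <- rowSums(aligned[, c("M", "=", "X"), drop = FALSE])
  read_length <- S4Vectors::mcols(ga)$qwidth +
    aligned[, "H"]  # hard clips removed from SEQ but part of the read
  nm <- S4Vectors::mcols(ga)$NM
  nm[is.na(nm)] <- 0
  x <- data.frame(
    read_id = S4Vectors::mcols(ga)$qname,
    contig_id = as.character(GenomicAlignments::seqnames(ga)),
    aln_start = BiocGenerics::start(ga) - 1,
    aln_end = BiocGenerics::end(ga),
    read_length = read_length,
    aligned_bases = aligned_bases,
    matches = pmax(aligned_bases - nm, 0),
    stringsAsFactors = FALSE
  )
  validate_alignments(x)
}

#' Mapping-quality filter: length fraction and similarity fraction
#'
#' Keeps alignments with `aligned_bases / read_length >= length_fraction`
#' and `matches / aligned_bases >= similarity_fraction` (both cutoffs
#' inclusive; defaults 0.80 and 0.80). Multi-mapped reads are then reduced
#' to a single record per read id -- the one with the most matching bases,
#' ties resolved by input order.
#'
#' @param alignments A `read_alignment` data frame.
#' @param length_fraction,similarity_fraction Proportions in (0, 1].
#' @return Filtered `read_alignment` with one row per retained read.
#' @export
filter_alignments <- function(alignments, length_fraction = 0.80,
                              similarity_fraction = 0.80) {
  for (f in c(length_fraction, similarity_fraction)) {
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f > 1) {
      stop("length_fraction and similarity_fraction must lie in (0, 1]")
    }
  }
  x <- as.data.frame(alignments)
  if (nrow(x) == 0L) return(validate_alignments(x))
  x$.ord <- seq_len(nrow(x))
  keep <- (x$aligned_bases / x$read_length) >= length_fraction &
    (x$matches / x$aligned_bases) >= similarity_fraction
  x <- x[keep, , drop = FALSE]
  if (nrow(x) > 1L) {
    ord <- order(-x$matches, x$.ord)    # best match per read, ties first
    x <- x[ord, , drop = FALSE]
    x <- x[!duplicated(x$read_id), , drop = FALSE]
    x <- x[order(x$.ord), , drop = FALSE]
  }
  x$.ord <- NULL
  rownames(x) <- NULL
  validate_alignments(x)
}

#' Assign filtered reads to non-overlapping TE entries
#'
#' A read counts toward the unique TE entry that covers at least
#' `min_overlap_fraction` of its aligned interval; if two entries reach the
#' fraction at exactly the threshold the one with the larger overlap (then
#' the first in annotation order) wins. Reads reaching no entry contribute
#' only to the mapped-read total downstream. Annotations must already be
#' redundancy-filtered: intra-contig overlaps raise an error.
#'
#' @param alignments A `read_alignment` data frame (already filtered).
#' @param annotations A `te_annotation` free of intra-contig overlaps.
#' @param min_overlap_fraction Minimum fraction of the read's aligned
#'   interval covered by the entry (default 0.5).
#' @return Integer vector of per-entry read counts, parallel to the rows of
#'   `annotations`; attribute `n_assigned` gives the total assigned reads.
#' @export
assign_reads_to_te <- function(alignments, annotations,
                               min_overlap_fraction = 0.5) {
  x <- as.data.frame(alignments)
  a <- as.data.frame(annotations)
  if (nrow(a) > 0L) {
    for (ctg in unique(a$contig_id)) {
      sel <- a$contig_id == ctg
      ir <- IRanges::IRanges(start = a$start[sel] + 1, end = a$end[sel])
      if (length(IRanges::reduce(ir, min.gapwidth = 0L)) != sum(sel)) {
        stop("annotations contain intra-contig overlaps on '", ctg,
             "'; run filter_redundancy() first")
      }
    }
  }
  counts <- integer(nrow(a))
  if (nrow(x) == 0L || nrow(a) == 0L) {
    attr(counts, "n_assigned") <- 0L
    return(counts)
  }
  ctg_levels <- union(unique(x$contig_id), unique(a$contig_id))
  # offset each contig into a disjoint coordinate block so one findOverlaps
  # call covers all contigs
  span <- max(c(x$aln_end, a$end)) + 1
  off <- (match(x$contig_id, ctg_levels) - 1) * span
  off_a <- (match(a$contig_id, ctg_levels) - 1) * span
  qr <- IRanges::IRanges(start = x$aln_start + 1 + off, end = x$aln_end + off)
  sr <- IRanges::IRanges(start = a$start + 1 + off_a, end = a$end + off_a)
  hits <- IRanges::findOverlaps(qr, sr)
  if (length(hits) > 0L) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(qr[qh], sr[sh]))
    frac <- ov / IRanges::width(qr[qh])
    ok <- frac >= min_overlap_fraction
    qh <- qh[ok]; sh <- sh[ok]; ov <- ov[ok]
    if (length(qh) > 0L) {
      ord <- order(qh, -ov, sh)
      qh <- qh[ord]; sh <- sh[ord]
      best <- !duplicated(qh)
      tab <- table(factor(sh[best], levels = seq_len(nrow(a))))
      counts <- as.integer(tab)
      attr(counts, "n_assigned") <- sum(best)
      return(counts)
    }
  }
  attr(counts, "n_assigned") <- 0L
  counts
}

#' Per-sample TE expression profile by class and LTR superfamily
#'
#' Sums per-entry read counts within TE class and within LTR superfamily
#' and expresses each as a percentage of the total number of reads mapped
#' to the assembly in that sample, which makes profiles comparable across
#' stages and conditions with different sequencing depths.
#'
#' @param entry_counts Integer vector of per-entry read counts from
#'   [assign_reads_to_te()].
#' @param classifications Data frame from [classify_te()], parallel to
#'   `entry_counts` (or a `te_annotation`, classified on the fly).
#' @param total_mapped_reads Total reads mapped to the assembly in the
#'   sample (must be >= the sum of `entry_counts`).
#' @param sample_id Sample label carried into the profile.
#' @return An object of class `te_profile`: a list with `sample_id`,
#'   `total_mapped_reads`, named count vectors `counts` (per TE class) and
#'   `ltr_counts` (per LTR superfamily), and matching `percentages` /
#'   `ltr_percentages`.
#' @export
aggregate_profile <- function(entry_counts, classifications,
                              total_mapped_reads, sample_id = "sample") {
  if (!is.null(classifications$repeat_class_family) &&
      is.null(classifications$te_class)) {
    classifications <- classify_te(classifications$repeat_class_family)
  }
  stopifnot(length(entry_counts) == nrow(classifications))
  if (!is.numeric(total_mapped_reads) || total_mapped_reads <= 0) {
    stop("total_mapped_reads must be positive (no denominator otherwise)")
  }
  if (sum(entry_counts) > total_mapped_reads) {
    stop("sum of per-entry counts exceeds total_mapped_reads")
  }
  if (any(classifications$te_class == "NotTE" & entry_counts > 0)) {
    stop("NotTE entries must not carry read counts")
  }
  cls <- factor(classifications$te_class, levels = te_classes())
  counts <- tapply(entry_counts, cls, sum, default = 0L)
  counts <- stats::setNames(as.integer(counts), te_classes())
  is_ltr <- classifications$te_class == "LTR"
  sf <- factor(classifications$ltr_superfamily[is_ltr],
               levels = ltr_superfamilies())
  ltr_counts <- tapply(entry_counts[is_ltr], sf, sum, default = 0L)
  ltr_counts <- stats::setNames(as.integer(ltr_counts), ltr_superfamilies())
  structure(list(
    sample_id = sample_id,
    total_mapped_reads = total_mapped_reads,
    counts = counts,
    ltr_counts = ltr_counts,
    percentages = 100 * counts / total_mapped_reads,
    ltr_percentages = 100 * ltr_counts / total_mapped_reads
  ), class = "te_profile")
}

#' @export
print.te_profile <- function(x, ...) {
  cat("TE expression profile for sample '", x$sample_id, "' (",
      format(x$total_mapped_reads, big.mark = ","), " mapped reads)\n",
      sep = "")
  print(round(x$percentages, 3))
  invisible(x)
}

#' Tidy one or more TE profiles into a long table
#'
#' @param profiles A `te_profile` or list of them.
#' @return Data frame with columns `sample`, `level` (`class` or
#'   `ltr_superfamily`), `name`, `count`, `percent`.
#' @export
profile_table <- function(profiles) {
  if (inherits(profiles, "te_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    rbind(
      data.frame(sample = p$sample_id, level = "class",
                 name = names(p$counts), count = as.integer(p$counts),
                 percent = as.numeric(p$percentages),
                 stringsAsFactors = FALSE),
      data.frame(sample = p$sample_id, level = "ltr_superfamily",
                 name = names(p$ltr_counts),
                 count = as.integer(p$ltr_counts),
                 percent = as.numeric(p$ltr_percentages),
                 stringsAsFactors = FALSE)
    )
  }))
}

#' Quantify one sample end-to-end
#'
#' Convenience wrapper: mapping-quality filter, read-to-entry assignment
#' and profile aggregation in one call. The mapped-read total is the number
#' of distinct reads surviving [filter_alignments()].
#'
#' @inheritParams filter_alignments
#' @inheritParams assign_reads_to_te
#' @param sample_id Sample label.
#' @return A `te_profile`; attribute `entry_counts` holds the per-entry
#'   counts.
#' @export
quantify_sample <- function(alignments, annotations, sample_id = "sample",
                            length_fraction = 0.80,
                            similarity_fraction = 0.80,
                            min_overlap_fraction = 0.5) {
  flt <- filter_alignments(alignments, length_fraction, similarity_fraction)
  counts <- assign_reads_to_te(flt, annotations, min_overlap_fraction)
  prof <- aggregate_profile(counts, annotations, nrow(flt), sample_id)
  attr(prof, "entry_counts") <- counts
  prof
}
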