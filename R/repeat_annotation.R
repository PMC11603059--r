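#' Parse a RepeatMasker `.out` annotation file
#'
#' Reads the standard whitespace-delimited RepeatMasker `.out` dialect (15
#' columns, optional 2--3 line header, optional trailing `*` marking an entry
#' that is overlapped by a higher-scoring match) into a `te_annotation`
#' data frame. File coordinates are 1-based inclusive and are converted to
#' 0-based half-open internally; parenthesized "left" columns are stored as
#' negative remainders (e.g. `(400)` becomes `-400`). The complement strand
#' symbol `C` is stored as `-`.
#'
#' @param file Path to a `.out` file, or a character vector of lines via
#'   `text`.
#' @param text Optional character vector of raw lines (used instead of
#'   `file`).
#' @return A data frame of class `te_annotation` with columns `contig_id`,
#'   `start`, `end` (0-based half-open), `strand`, `sw_score`,
#'   `pct_divergence`, `pct_deleted`, `pct_inserted`, `repeat_name`,
#'   `repeat_class_family`, `repeat_start`, `repeat_end`, `repeat_left`,
#'   `rm_id`, `overlap_flag`.
#' @examples
#' lines <- c(
#'   "463 1.3 0.6 1.7 contig_1 101 600 (400) + DR0001 LTR/ERV1 1 500 (0) 1"
#' )
#' ann <- parse_rm_out(text = lines)
#' ann$start  # 100: converted to 0-based
#' @export
parse_rm_out <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(is.character(file), length(file) == 1L)
    text <- readLines(file, warn = FALSE)
  }
  n <- length(text)
  is_data <- logical(n)
  for (i in seq_len(n)) {
    ln <- trimws(text[i])
    if (!nzchar(ln)) next
    first <- sub("\\s.*$", "", ln)
    # header lines of the standard .out preamble
    if (toupper(first) %in% c("SW", "SCORE", "BIT")) next
    is_data[i] <- TRUE
  }
  idx <- which(is_data)
  if (length(idx) == 0L) return(empty_te_annotation())

  recs <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- strsplit(trimws(text[i]), "\\s+")[[1]]
    if (length(f) < 14L) {
      stop(sprintf("parse error at line %d: expected >= 14 fields, found %d",
                   i, length(f)))
    }
    num <- function(s, what) {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) {
        stop(sprintf("parse error at line %d: non-numeric %s '%s'", i, what, s))
      }
      v
    }
    sw <- num(f[1], "score")
    qbeg <- num(f[6], "begin coordinate")
    qend <- num(f[7], "end coordinate")
    if (qend < qbeg) {
      stop(sprintf("parse error at line %d: end (%s) < start (%s)",
                   i, f[7], f[6]))
    }
    strand <- f[9]
    if (strand == "C") strand <- "-"
    if (!strand %in% c("+", "-")) {
      stop(sprintf("parse error at line %d: bad strand '%s'", i, f[9]))
    }
    paren <- function(s, what) {
      if (grepl("^\\(.*\\)$", s)) -num(sub("^\\((.*)\\)$", "\\1", s), what)
      else num(s, what)
    }
    overlap <- length(f) >= 16L && f[16] == "*" ||
      (length(f) == 15L && f[15] == "*")
    rm_id <- if (length(f) >= 15L && f[15] != "*") {
      as.integer(num(f[15], "ID"))
    } else NA_integer_
    recs[[k]] <- data.frame(
      contig_id = f[5],
      start = qbeg - 1, end = qend,
      strand = strand,
      sw_score = sw,
      pct_divergence = num(f[2], "divergence"),
      pct_deleted = num(f[3], "deletion percentage"),
      pct_inserted = num(f[4], "insertion percentage"),
      repeat_name = f[10],
      repeat_class_family = f[11],
      repeat_start = paren(f[12], "repeat begin"),
      repeat_end = paren(f[13], "repeat end"),
      repeat_left = paren(f[14], "repeat left"),
      rm_id = rm_id,
      overlap_flag = overlap,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("te_annotation", "data.frame")
  out
}

empty_te_annotation <- function() {
  out <- data.frame(
    contig_id = character(), start = numeric(), end = numeric(),
    strand = character(), sw_score = numeric(), pct_divergence = numeric(),
    pct_deleted = numeric(), pct_inserted = numeric(),
    repeat_name = character(), repeat_class_family = character(),
    repeat_start = numeric(), repeat_end = numeric(),
    repeat_left = numeric(), rm_id = integer(), overlap_flag = logical(),
    stringsAsFactors = FALSE
  )
  class(out) <- c("te_annotation", "data.frame")
  out
}

#' TE taxonomy: class and LTR superfamily from a RepeatMasker label
#'
#' Maps RepeatMasker `class/family` strings onto the TE taxonomy used
#' throughout the package: classes `DNA`, `LINE`, `SINE`, `LTR`, `Unclear`
#' and `NotTE`, plus, for LTR retroelements, the superfamilies `Copia`,
#' `DIRS`, `ERV1`, `ERV2`, `Gypsy`, `Pao`, `Ngaro` with everything else
#' collected as `LTR_other`. Non-TE annotation categories (simple repeats,
#' low complexity, satellites, structural RNAs, artefacts) map to `NotTE`
#' and are excluded from every profile downstream; rolling-circle
#' (`RC/Helitron`) elements count as DNA transposons; unrecognized labels
#' (including `Unknown`) map to `Unclear`. A trailing `?` (uncertain call)
#' is ignored. The function is total: any text yields a classification.
#'
#' @param repeat_class_family Character vector of RepeatMasker
#'   `class/family` labels, e.g. `"LTR/Gypsy"`.
#' @return Data frame with columns `te_class` and `ltr_superfamily`
#'   (`NA` unless `te_class == "LTR"`).
#' @examples
#' classify_te(c("LTR/Gypsy", "Unknown", "Simple_repeat", "RC/Helitron"))
#' @export
classify_te <- function(repeat_class_family) {
  x <- as.character(repeat_class_family)
  prefix <- toupper(sub("\\?$", "", sub("/.*$", "", x)))
  suffix <- ifelse(grepl("/", x), sub("^[^/]*/", "", x), "")
  suffix <- sub("\\?$", "", suffix)

  not_te <- c("SIMPLE_REPEAT", "LOW_COMPLEXITY", "SATELLITE", "RRNA", "TRNA",
              "SNRNA", "SCRNA", "SRPRNA", "ARTEFACT")
  te_class <- rep("Unclear", length(x))
  te_class[prefix == "DNA"] <- "DNA"
  te_class[prefix == "RC"] <- "DNA"
  te_class[prefix == "LINE"] <- "LINE"
  te_class[prefix == "SINE"] <- "SINE"
  te_class[prefix == "LTR"] <- "LTR"
  te_class[prefix %in% not_te] <- "NotTE"

  superfams <- c("Copia", "DIRS", "ERV1", "ERV2", "Gypsy", "Pao", "Ngaro")
  ltr_superfamily <- rep(NA_character_, length(x))
  is_ltr <- te_class == "LTR"
  m <- match(toupper(suffix[is_ltr]), toupper(superfams))
  ltr_superfamily[is_ltr] <- ifelse(is.na(m), "LTR_other", superfams[m])

  data.frame(te_class = te_class, ltr_superfamily = ltr_superfamily,
             stringsAsFactors = FALSE)
}

#' Canonical TE class and LTR superfamily level sets
#' @return Character vector of levels.
#' @export
te_classes <- function() c("DNA", "LINE", "SINE", "LTR", "Unclear")

#' @rdname te_classes
#' @export
ltr_superfamilies <- function() {
  c("Copia", "DIRS", "ERV1", "ERV2", "Gypsy", "Pao", "Ngaro", "LTR_other")
}

#' Redundancy filter for RepeatMasker annotations
#'
#' Reduces an annotation to a non-redundant set of TE entries in three
#' steps: (1) entries not classified as TEs (class `NotTE`) are removed;
#' (2) on each contig, entries whose intervals overlap by at least one base
#' are clustered (transitive closure) and exactly one entry per cluster is
#' kept -- the one with the highest Smith-Waterman score, ties broken by
#' larger match length, then smaller start, then input order; (3) surviving
#' entries whose match length on the contig is not strictly greater than
#' `min_length` are removed. The output is sorted by contig then start and
#' is guaranteed free of intra-contig overlaps.
#'
#' @param annotations A `te_annotation` data frame from [parse_rm_out()].
#' @param min_length Minimum match length in bp; entries with
#'   `end - start <= min_length` are dropped (strict `>` retained, so the
#'   default keeps only matches longer than 80 bp).
#' @param scope `"cluster"` (default) keeps the best entry per overlap
#'   cluster; `"contig"` keeps a single best entry per contig.
#' @return Filtered `te_annotation`, a subset of the input rows.
#' @export
filter_redundancy <- function(annotations, min_length = 80,
                              scope = c("cluster", "contig")) {
  scope <- match.arg(scope)
  stopifnot(is.numeric(min_length), length(min_length) == 1L,
            !is.na(min_length), min_length >= 0)
  x <- annotations
  if (nrow(x) == 0L) return(x)
  x$.idx <- seq_len(nrow(x))

  cls <- classify_te(x$repeat_class_family)$te_class
  x <- x[cls != "NotTE", , drop = FALSE]
  if (nrow(x) > 0L) {
    keep <- logical(nrow(x))
    for (ctg in unique(x$contig_id)) {
      sel <- which(x$contig_id == ctg)
      if (scope == "contig") {
        clust <- rep(1L, length(sel))
      } else {
        ir <- IRanges::IRanges(start = x$start[sel] + 1, end = x$end[sel])
        # min.gapwidth = 0: abutting entries share no base and stay apart
        red <- IRanges::reduce(ir, min.gapwidth = 0L)
        clust <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
      }
      len <- x$end[sel] - x$start[sel]
      ord <- order(-x$sw_score[sel], -len, x$start[sel], x$.idx[sel])
      best <- ord[!duplicated(clust[ord])]
      keep[sel[best]] <- TRUE
    }
    x <- x[keep, , drop = FALSE]
  }
  x <- x[(x$end - x$start) > min_length, , drop = FALSE]
  x <- x[order(x$contig_id, x$start), , drop = FALSE]
  x$.idx <- NULL
  rownames(x) <- NULL
  class(x) <- c("te_annotation", "data.frame")
  x
}

#' Write annotations back to RepeatMasker `.out` dialect
#'
#' Inverse of [parse_rm_out()]: internal 0-based half-open coordinates go
#' back to 1-based inclusive, negative remainders back to parentheses, and
#' the `-` strand back to the `C` symbol, so that re-parsing the written
#' file reproduces the input values exactly.
#'
#' @param annotations A `te_annotation` data frame.
#' @param file Output path.
#' @param header Write the standard 3-line `.out` header (default TRUE).
#' @export
write_rm_out <- function(annotations, file, header = TRUE) {
  x <- annotations
  fmt_left <- function(v) {
    ifelse(v < 0, sprintf("(%s)", format(-v, trim = TRUE, scientific = FALSE)),
           format(v, trim = TRUE, scientific = FALSE))
  }
  lines <- character(0)
  if (header) {
    lines <- c(
      "   SW   perc perc perc  query      position in query           matching       repeat              position in repeat",
      "score   div. del. ins.  sequence   begin end          (left)   repeat         class/family      begin  end    (left)   ID",
      ""
    )
  }
  if (nrow(x) > 0L) {
    # query-left is not retained internally; written as "(0)"
    rows <- vapply(seq_len(nrow(x)), function(i) {
      f <- c(
        format(x$sw_score[i], trim = TRUE, scientific = FALSE),
        x$pct_divergence[i], x$pct_deleted[i], x$pct_inserted[i],
        x$contig_id[i],
        format(x$start[i] + 1, trim = TRUE, scientific = FALSE),
        format(x$end[i], trim = TRUE, scientific = FALSE),
        "(0)",
        if (x$strand[i] == "-") "C" else "+",
        x$repeat_name[i], x$repeat_class_family[i],
        fmt_left(x$repeat_start[i]), fmt_left(x$repeat_end[i]),
        fmt_left(x$repeat_left[i]),
        if (is.na(x$rm_id[i])) NULL else as.character(x$rm_id[i]),
        if (isTRUE(x$overlap_flag[i])) "*" else NULL
      )
      paste(f, collapse = " ")
    }, character(1))
    lines <- c(lines, rows)
  }
  writeLines(lines, file)
  invisible(file)
}

#' Export annotations as a tab-separated table or BED6
#'
#' `write_annotation_table()` writes every `te_annotation` column plus the
#' derived `te_class` / `ltr_superfamily` with an explicit header;
#' `write_bed6()` writes the 0-based half-open BED6 representation
#' (name = repeat name, score = Smith-Waterman score capped at 1000).
#'
#' @param annotations A `te_annotation` data frame.
#' @param file Output path.
#' @export
write_annotation_table <- function(annotations, file) {
  x <- as.data.frame(annotations)
  x <- cbind(x, classify_te(x$repeat_class_family))
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_annotation_table
#' @export
write_bed6 <- function(annotations, file) {
  x <- annotations
  bed <- data.frame(
    chrom = x$contig_id,
    chromStart = format(x$start, trim = TRUE, scientific = FALSE),
    chromEnd = format(x$end, trim = TRUE, scientific = FALSE),
    name = x$repeat_name,
    score = pmin(round(x$sw_score), 1000),
    strand = x$strand,
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read an annotation table written by [write_annotation_table()]
#' @param file Path to the TSV.
#' @return A `te_annotation` data frame.
#' @export
read_annotation_table <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  x$te_class <- NULL
  x$ltr_superfamily <- NULL
  class(x) <- c("te_annotation", "data.frame")
  x
}
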