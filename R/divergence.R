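#' Count substitutions between a TE copy and its consensus
#'
#' Compares two equal-length aligned nucleotide strings column by column.
#' Columns containing a gap (`-`) or an `N` on either side are excluded
#' from the aligned-site count. Among differing columns, `A<->G` and
#' `C<->T` are transitions; every other differing pair is a transversion.
#'
#' @param copy_sequence,consensus_sequence Aligned strings of equal length
#'   over the alphabet `A,C,G,T,N,-` (case-insensitive).
#' @return List with `aligned_sites`, `transitions`, `transversions`, and
#'   the proportions `p = transitions/aligned_sites`,
#'   `q = transversions/aligned_sites`.
#' @examples
#' count_substitutions("AGCT", "GGCT")  # one transition, p = 0.25
#' @export
count_substitutions <- function(copy_sequence, consensus_sequence) {
  a <- toupper(as.character(copy_sequence))
  b <- toupper(as.character(consensus_sequence))
  if (nchar(a) != nchar(b)) {
    stop("aligned sequences differ in length (", nchar(a), " vs ",
         nchar(b), ")")
  }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- !(av %in% c("-", "N")) & !(bv %in% c("-", "N"))
  av <- av[ok]; bv <- bv[ok]
  aligned_sites <- length(av)
  if (aligned_sites == 0L) {
    stop("no ungapped, unambiguous aligned columns")
  }
  diff <- av != bv
  pair <- paste0(pmin(av[diff], bv[diff]), pmax(av[diff], bv[diff]))
  transitions <- sum(pair %in% c("AG", "CT"))
  transversions <- sum(diff) - transitions
  list(aligned_sites = aligned_sites,
       transitions = transitions,
       transversions = transversions,
       p = transitions / aligned_sites,
       q = transversions / aligned_sites)
}

#' Kimura 2-parameter distance
#'
#' Substitution-corrected divergence
#' `K = -1/2 * log((1 - 2p - q) * sqrt(1 - 2q))` with `p` the transition
#' and `q` the transversion proportion; the standard proxy for the age of a
#' TE copy relative to its family consensus. Outside the domain
#' (`1 - 2p - q <= 0` or `1 - 2q <= 0`) the divergence is saturated and
#' `NA` is returned; landscape builders count and report such records
#' rather than binning them.
#'
#' @param p,q Transition and transversion proportions (vectorized;
#'   `p >= 0`, `q >= 0`, `p + q <= 1`).
#' @return Numeric vector of distances in substitutions/site; `NA` where
#'   saturated.
#' @examples
#' kimura_k2p(0.1, 0.05)  # ~0.17018
#' @export
kimura_k2p <- function(p, q) {
  if (any(p < 0 | q < 0 | p + q > 1, na.rm = TRUE)) {
    stop("p and q must be non-negative with p + q <= 1")
  }
  n <- max(length(p), length(q))
  p <- rep_len(p, n); q <- rep_len(q, n)
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  k <- rep(NA_real_, n)
  ok <- w1 > 0 & w2 > 0
  k[ok] <- -0.5 * log(w1[ok] * sqrt(w2[ok]))
  k
}

#' K2P distance of an aligned copy/consensus pair
#'
#' @inheritParams count_substitutions
#' @return The K2P distance (`NA` if saturated).
#' @export
kimura_from_pair <- function(copy_sequence, consensus_sequence) {
  s <- count_substitutions(copy_sequence, consensus_sequence)
  kimura_k2p(s$p, s$q)
}

#' Read copy/consensus alignment pairs from aligned FASTA
#'
#' The file holds consecutive record pairs: the TE copy first, its family
#' consensus second, both gapped to equal length. The copy record id names
#' the entry.
#'
#' @param file Path to an aligned multi-FASTA.
#' @return Data frame with columns `entry_id`, `copy`, `consensus`.
#' @export
read_aligned_pairs <- function(file) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("package 'Biostrings' is required to read FASTA input")
  }
  seqs <- Biostrings::readBStringSet(file)
  if (length(seqs) %% 2L != 0L) {
    stop("aligned-pair FASTA must contain an even number of records")
  }
  i <- seq(1L, length(seqs), by = 2L)
  data.frame(
    entry_id = sub("\\s.*$", "", names(seqs)[i]),
    copy = as.character(seqs[i]),
    consensus = as.character(seqs[i + 1L]),
    stringsAsFactors = FALSE
  )
}

#' Build divergence (K2P) records for a set of aligned TE copies
#'
#' @param pairs Data frame from [read_aligned_pairs()].
#' @param classifications Data frame with `te_class` / `ltr_superfamily`
#'   rows parallel to `pairs` (e.g. from [classify_te()]).
#' @param weights Per-copy weight: aligned bp of the copy (default) or the
#'   number of reads assigned to the copy, for landscapes of the expressed
#'   fraction.
#' @return Data frame of class `kimura_records` with columns `entry_id`,
#'   `K`, `weight`, `te_class`, `ltr_superfamily`; saturated copies carry
#'   `K = NA`.
#' @export
divergence_records <- function(pairs, classifications, weights = NULL) {
  stopifnot(nrow(pairs) == nrow(classifications))
  n <- nrow(pairs)
  K <- numeric(n); sites <- numeric(n)
  for (i in seq_len(n)) {
    s <- count_substitutions(pairs$copy[i], pairs$consensus[i])
    sites[i] <- s$aligned_sites
    K[i] <- kimura_k2p(s$p, s$q)
  }
  if (is.null(weights)) weights <- sites
  out <- data.frame(
    entry_id = pairs$entry_id, K = K, weight = weights,
    te_class = classifications$te_class,
    ltr_superfamily = classifications$ltr_superfamily,
    stringsAsFactors = FALSE
  )
  class(out) <- c("kimura_records", "data.frame")
  out
}

#' Bin K2P divergences into a repeat landscape
#'
#' Places each record's divergence (in percent, `100 * K`) into
#' `[lo, lo + bin_width)` bins over `[0, 50)` and sums weights per
#' (bin, group). Records at or beyond 50% divergence fall into an explicit
#' overflow bin (`bin_lo = 50, bin_hi = Inf`) so that the binned weights
#' always conserve the total. Saturated records (`K = NA`) are excluded and
#' their count reported in the `saturated` attribute (with a warning when
#' nonzero).
#'
#' @param records A `kimura_records` data frame.
#' @param bin_width Bin width in percent divergence (default 1).
#' @param group_by Grouping column: `"ltr_superfamily"` or `"te_class"`.
#' @param normalization `"raw"` keeps summed weights only;
#'   `"percent_of_total"` adds a `percent` column on the total weight.
#' @return Data frame with columns `bin_lo`, `bin_hi`, `group`, `weight`
#'   (and `percent`); attributes `saturated` (excluded record count) and
#'   `total_weight`.
#' @export
build_landscape <- function(records, bin_width = 1,
                            group_by = c("ltr_superfamily", "te_class"),
                            normalization = c("percent_of_total", "raw")) {
  group_by <- match.arg(group_by)
  normalization <- match.arg(normalization)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("bin_width must be a positive number of percent divergence")
  }
  sat <- sum(is.na(records$K))
  if (sat > 0) {
    warning(sat, " saturated record(s) excluded from the landscape")
  }
  x <- records[!is.na(records$K), , drop = FALSE]
  if (nrow(x) == 0L) {
    stop("no records remain after saturation filtering")
  }
  div <- 100 * x$K
  lo <- floor(div / bin_width) * bin_width
  over <- lo >= 50
  lo[over] <- 50
  hi <- ifelse(over, Inf, lo + bin_width)
  grp <- as.character(x[[group_by]])
  grp[is.na(grp)] <- "NA"
  agg <- stats::aggregate(list(weight = x$weight),
                          by = list(bin_lo = lo, bin_hi = hi, group = grp),
                          FUN = sum)
  agg <- agg[order(agg$group, agg$bin_lo), , drop = FALSE]
  rownames(agg) <- NULL
  total <- sum(x$weight)
  if (normalization == "percent_of_total") {
    agg$percent <- 100 * agg$weight / total
  }
  attr(agg, "saturated") <- sat
  attr(agg, "total_weight") <- total
  agg
}

#' Write a landscape table as TSV
#' @param landscape Data frame from [build_landscape()].
#' @param file Output path.
#' @export
write_landscape_tsv <- function(landscape, file) {
  utils::write.table(landscape, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
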