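#' Transcripts per million from counts and transcript lengths
#'
#' Classic length-normalized TPM: per gene the read count is divided by the
#' transcript length, and per sample the resulting rates are rescaled to
#' sum to one million. No fragment-length correction is applied (effective
#' length = transcript length).
#'
#' @param counts Numeric gene x sample matrix (or data frame) of read
#'   counts; rownames are gene identifiers.
#' @param lengths Numeric vector of transcript lengths in bp, parallel to
#'   the rows of `counts` (or named by gene).
#' @return Matrix of TPM values, same dimensions as `counts`; each column
#'   sums to 1e6.
#' @examples
#' compute_tpm(cbind(s1 = c(10, 10)), lengths = c(1000, 2000))
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  stopifnot(length(lengths) == nrow(counts))
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("all transcript lengths must be positive")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  rates <- counts / lengths
  tot <- colSums(rates)
  zero <- tot == 0
  if (any(zero)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(rates, 2, tot, "/") * 1e6
}

#' Cross-sample scaling on a single-copy orthologue set
#'
#' TPM makes samples sum to the same total but leaves cross-stage
#' comparisons at the mercy of global composition shifts (e.g. maternal
#' transcript degradation). Rescaling every sample so that the cumulative
#' TPM of a conserved single-copy orthologue set is constant restores
#' comparability: `C_j` is the summed orthologue TPM of sample `j`, the
#' reference `R` is the mean of the `C_j` (or a named reference sample's
#' value), and sample `j` is multiplied by `s_j = R / C_j`.
#'
#' @param tpm Gene x sample TPM matrix with gene rownames.
#' @param orthologue_set Character vector of single-copy orthologue gene
#'   identifiers. Members absent from the matrix are reported via warning,
#'   never silently dropped.
#' @param reference `"mean"` (default) or the name of a reference sample.
#' @return List with `scaling_factors` (named numeric, one per sample) and
#'   `scaled_tpm` (the rescaled matrix).
#' @export
ortholog_scaling <- function(tpm, orthologue_set, reference = "mean") {
  tpm <- as.matrix(tpm)
  if (length(orthologue_set) == 0L) stop("orthologue set is empty")
  present <- orthologue_set %in% rownames(tpm)
  if (!all(present)) {
    warning(sum(!present), " orthologue id(s) absent from the matrix: ",
            paste(utils::head(orthologue_set[!present], 5), collapse = ", "))
  }
  set <- orthologue_set[present]
  if (length(set) == 0L) stop("no orthologue ids found in the matrix")
  C <- colSums(tpm[set, , drop = FALSE])
  if (any(C == 0)) {
    stop("zero cumulative orthologue expression in sample(s): ",
         paste(colnames(tpm)[C == 0], collapse = ", "))
  }
  R <- if (identical(reference, "mean")) {
    mean(C)
  } else {
    if (!reference %in% colnames(tpm)) {
      stop("reference sample '", reference, "' not found")
    }
    C[[reference]]
  }
  s <- R / C
  list(scaling_factors = s,
       scaled_tpm = sweep(tpm, 2, s, "*"))
}

#' Per-sample mean expression of a gene family
#'
#' Unweighted arithmetic mean of the (scaled) TPM values of the family
#' members in each sample -- used to summarize multi-gene families such as
#' the KRAB-like and FiNZ zinc-finger expansions as one trajectory.
#'
#' @param scaled_tpm Gene x sample matrix.
#' @param members Character vector of member gene identifiers.
#' @param name Family label attached to the result.
#' @return Named numeric vector (one mean per sample) with attribute
#'   `family`.
#' @export
family_mean_expression <- function(scaled_tpm, members, name = "family") {
  scaled_tpm <- as.matrix(scaled_tpm)
  present <- members %in% rownames(scaled_tpm)
  if (!all(present)) {
    warning(sum(!present), " family member(s) absent from the matrix: ",
            paste(utils::head(members[!present], 5), collapse = ", "))
  }
  members <- members[present]
  if (length(members) == 0L) {
    stop("family '", name, "' has no members in the matrix")
  }
  out <- colMeans(scaled_tpm[members, , drop = FALSE])
  attr(out, "family") <- name
  out
}

#' Read a gene count table (gene, length, one column per sample)
#' @param file Path to the TSV.
#' @return List with `counts` (matrix) and `lengths` (named vector).
#' @export
read_count_table <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene", "length") %in% names(x))) {
    stop("count table must have 'gene' and 'length' columns")
  }
  counts <- as.matrix(x[, setdiff(names(x), c("gene", "length")),
                        drop = FALSE])
  rownames(counts) <- x$gene
  list(counts = counts, lengths = stats::setNames(x$length, x$gene))
}

#' @rdname read_count_table
#' @param counts Gene x sample count matrix.
#' @param lengths Named transcript lengths.
#' @export
write_count_table <- function(counts, lengths, file) {
  x <- data.frame(gene = rownames(counts),
                  length = as.numeric(lengths[rownames(counts)]),
                  counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read gene-set files: one identifier per line, a `# name` header allowed
#' @param file Path.
#' @return Character vector of identifiers; attribute `name` if a header
#'   line was present.
#' @export
read_gene_set <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  nm <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    nm <- trimws(sub("^#+", "", lines[1]))
    lines <- lines[-1]
  }
  structure(lines, name = nm)
}
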