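# Brute-force reference implementations, deliberately independent of the
# package's interval machinery, plus small fixture builders.

make_annotation <- function(contig, start, end, score,
                            class_family = "LTR/Gypsy",
                            name = "rep", strand = "+") {
  n <- length(start)
  out <- data.frame(
    contig_id = rep_len(contig, n), start = start, end = end,
    strand = rep_len(strand, n), sw_score = rep_len(score, n),
    pct_divergence = 1.0, pct_deleted = 0, pct_inserted = 0,
    repeat_name = rep_len(name, n),
    repeat_class_family = rep_len(class_family, n),
    repeat_start = 1, repeat_end = end - start, repeat_left = 0,
    rm_id = seq_len(n), overlap_flag = FALSE, stringsAsFactors = FALSE
  )
  class(out) <- c("te_annotation", "data.frame")
  out
}

# exhaustive redundancy-filter oracle: explicit transitive-closure
# clustering by pairwise overlap, then the keep-rule applied directly
oracle_filter <- function(ann, min_length = 80) {
  keep_rows <- list()
  cls <- classify_te(ann$repeat_class_family)$te_class
  ann$.idx <- seq_len(nrow(ann))
  ann <- ann[cls != "NotTE", , drop = FALSE]
  for (ctg in unique(ann$contig_id)) {
    a <- ann[ann$contig_id == ctg, , drop = FALSE]
    n <- nrow(a)
    cluster <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (cluster[i] != cluster[j] &&
              a$start[i] < a$end[j] && a$start[j] < a$end[i]) {
          cluster[cluster == cluster[j]] <- cluster[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cl in unique(cluster)) {
      b <- a[cluster == cl, , drop = FALSE]
      len <- b$end - b$start
      ord <- order(-b$sw_score, -len, b$start, b$.idx)
      keep_rows[[length(keep_rows) + 1L]] <- b[ord[1], , drop = FALSE]
    }
  }
  out <- do.call(rbind, keep_rows)
  if (is.null(out)) return(ann[0, setdiff(names(ann), ".idx")])
  out <- out[(out$end - out$start) > min_length, , drop = FALSE]
  out <- out[order(out$contig_id, out$start), , drop = FALSE]
  out$.idx <- NULL
  rownames(out) <- NULL
  out
}

random_annotation_instance <- function() {
  n_ctg <- sample(1:3, 1)
  rows <- list()
  for (c_i in seq_len(n_ctg)) {
    n <- sample(1:12, 1)
    start <- sample(0:400, n, replace = TRUE)
    len <- sample(c(40, 60, 79, 80, 81, 100, 150, 200), n, replace = TRUE)
    rows[[c_i]] <- make_annotation(
      paste0("ctg", c_i), start, start + len,
      score = sample(c(100, 200, 300, 400), n, replace = TRUE),
      class_family = sample(
        c("LTR/Gypsy", "DNA/hAT", "LINE/L1", "Simple_repeat", "Unknown"),
        n, replace = TRUE)
    )
  }
  out <- do.call(rbind, rows)
  out$rm_id <- seq_len(nrow(out))
  class(out) <- c("te_annotation", "data.frame")
  out
}

# all-pairs read-to-entry assignment oracle
oracle_assign <- function(aln, ann, min_overlap_fraction = 0.5) {
  counts <- integer(nrow(ann))
  for (i in seq_len(nrow(aln))) {
    best <- 0L; best_ov <- -1
    for (j in seq_len(nrow(ann))) {
      if (aln$contig_id[i] != ann$contig_id[j]) next
      ov <- min(aln$aln_end[i], ann$end[j]) -
        max(aln$aln_start[i], ann$start[j])
      if (ov <= 0) next
      frac <- ov / (aln$aln_end[i] - aln$aln_start[i])
      if (frac >= min_overlap_fraction && ov > best_ov) {
        best <- j; best_ov <- ov
      }
    }
    if (best > 0L) counts[best] <- counts[best] + 1L
  }
  counts
}

make_alignments <- function(contig, start, end, read_length = end - start,
                            aligned = end - start, matches = aligned,
                            read_id = NULL) {
  n <- length(start)
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  out <- data.frame(
    read_id = read_id, contig_id = rep_len(contig, n),
    aln_start = start, aln_end = end,
    read_length = rep_len(read_length, n),
    aligned_bases = rep_len(aligned, n),
    matches = rep_len(matches, n), stringsAsFactors = FALSE
  )
  class(out) <- c("read_alignment", "data.frame")
  out
}

# naive statistics, straight from the defining formulas
naive_pearson <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, t = t, p = p)
}

naive_anova <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                     numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f <- (ss_b / (k - 1)) / (ss_w / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  list(F = f, df_between = k - 1, df_within = n - k, p = p)
}

# a small noise-free configuration used across tests
quiet_config <- function(seed = 1, nb_dispersion = 0,
                         low_quality_fraction = 0, ...) {
  simulation_config(
    seed = seed, total_reads = 5000,
    genes = list(n_heterochromatin = 10, n_nurd = 15, n_trim33 = 1,
                 n_krab_like = 8, n_finz = 10, n_orthologues = 120,
                 n_background = 150),
    nb_dispersion = nb_dispersion,
    low_quality_fraction = low_quality_fraction, ...
  )
}
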