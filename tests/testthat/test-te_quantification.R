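test_that("length/similarity cutoffs are inclusive at the boundary", {
  aln <- make_alignments("c1", c(0, 0, 0), c(100, 100, 100),
                         read_length = 100,
                         aligned = c(79, 80, 80),
                         matches = c(79, 68, 63))
  out <- filter_alignments(aln)
  # 79/100 fails the length fraction; 80/100 with 68/80 = 0.85 passes;
  # 63/80 = 0.7875 fails the similarity fraction
  expect_equal(out$read_id, "r002")
  expect_equal(nrow(filter_alignments(aln[0, ])), 0L)
})

test_that("multi-mapped reads collapse to their best placement", {
  aln <- make_alignments("c1", c(0, 10, 20), c(100, 110, 120),
                         read_length = 100, aligned = 100,
                         matches = c(90, 95, 95),
                         read_id = c("r1", "r1", "r1"))
  out <- filter_alignments(aln)
  expect_equal(nrow(out), 1L)
  expect_equal(out$matches, 95)
  expect_equal(out$aln_start, 10)  # tie between rows 2 and 3 -> first
})

test_that("fraction parameters outside (0,1] are rejected", {
  aln <- make_alignments("c1", 0, 100)
  expect_error(filter_alignments(aln, length_fraction = 0), "\\(0, 1\\]")
  expect_error(filter_alignments(aln, similarity_fraction = 1.2), "\\(0, 1\\]")
})

test_that("reads are assigned by covered fraction of their interval", {
  ann <- make_annotation("contig_1", 100, 600, score = 400)
  inside <- make_alignments("contig_1", 150, 250)
  half <- make_alignments("contig_1", 550, 650)
  below <- make_alignments("contig_1", 551, 651)
  off_te <- make_alignments("contig_2", 0, 100)
  expect_equal(as.integer(assign_reads_to_te(inside, ann)), 1L)
  expect_equal(as.integer(assign_reads_to_te(half, ann)), 1L)   # 50/100 = 0.5
  expect_equal(as.integer(assign_reads_to_te(below, ann)), 0L)  # 49/100
  counts <- assign_reads_to_te(off_te, ann)
  expect_equal(as.integer(counts), 0L)
  expect_equal(attr(counts, "n_assigned"), 0L)
})

test_that("overlapping annotations are rejected as a precondition", {
  ann <- make_annotation("c1", c(0, 100), c(200, 300), score = c(1, 2))
  aln <- make_alignments("c1", 0, 100)
  expect_error(assign_reads_to_te(aln, ann), "intra-contig overlaps")
})

test_that("assignment matches a brute-force all-pairs scan", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      ann <- filter_redundancy(random_annotation_instance(), min_length = 40)
      if (nrow(ann) == 0) next
      n <- sample(50:200, 1)
      ctg <- sample(unique(ann$contig_id), n, replace = TRUE)
      st <- sample(0:550, n, replace = TRUE)
      len <- sample(c(50, 75, 100), n, replace = TRUE)
      aln <- make_alignments(ctg, st, st + len, read_length = len)
      got <- assign_reads_to_te(aln, ann)
      want <- oracle_assign(aln, ann)
      expect_equal(as.integer(got), want)
    }
  })
})

test_that("profiles aggregate counts into percentages of mapped reads", {
  cls <- data.frame(
    te_class = c("LTR", "LTR", "LINE"),
    ltr_superfamily = c("ERV1", "Gypsy", NA),
    stringsAsFactors = FALSE
  )
  prof <- aggregate_profile(c(30L, 20L, 30L), cls, 1000, "s1")
  expect_equal(prof$percentages[["LTR"]], 5.0)
  expect_equal(prof$percentages[["LINE"]], 3.0)
  expect_equal(prof$ltr_percentages[["ERV1"]], 3.0)
  expect_equal(prof$ltr_percentages[["Gypsy"]], 2.0)
  expect_equal(sum(prof$ltr_counts), prof$counts[["LTR"]])

  zero <- aggregate_profile(c(0L, 0L, 0L), cls, 1000)
  expect_true(all(zero$percentages == 0))
  expect_error(aggregate_profile(c(1L, 0L, 0L), cls, 0), "denominator")
  expect_error(aggregate_profile(c(900L, 200L, 0L), cls, 1000), "exceeds")
})

test_that("percentages are scale-invariant and superfamilies sum to LTR", {
  withr::with_seed(19, {
    for (rep in 1:20) {
      n <- 12
      cls <- data.frame(
        te_class = sample(te_classes(), n, replace = TRUE),
        stringsAsFactors = FALSE
      )
      cls$ltr_superfamily <- ifelse(
        cls$te_class == "LTR",
        sample(ltr_superfamilies(), n, replace = TRUE), NA)
      counts <- sample(0:50, n, replace = TRUE)
      total <- sum(counts) + sample(100:1000, 1)
      p1 <- aggregate_profile(counts, cls, total)
      p2 <- aggregate_profile(counts * 7L, cls, total * 7)
      expect_equal(p1$percentages, p2$percentages)
      expect_equal(sum(p1$ltr_percentages), p1$percentages[["LTR"]],
                   tolerance = 1e-9)
    }
  })
})

test_that("noise-free synthetic reads are recovered entry-exactly", {
  cfg <- quiet_config(seed = 5)
  te <- simulate_te_copies(cfg)
  es <- simulate_expression(cfg, te)
  ann <- filter_redundancy(te$annotation)
  s <- es$sample_sheet$sample[1]
  flt <- filter_alignments(es$alignments[[s]])
  counts <- assign_reads_to_te(flt, ann)
  want <- es$truth$entry_counts[s, ann$contig_id]
  expect_equal(as.integer(counts), as.integer(want))
})

test_that("SAM input round-trips into the alignment table", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  sam <- c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:contig_1\tLN:1000",
    "r1\t0\tcontig_1\t151\t60\t100M\t*\t0\t0\tGATTACA\t*\tNM:i:2",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r3\t0\tcontig_1\t11\t60\t20S80M\t*\t0\t0\tGATTACA\t*\tNM:i:0"
  )
  # SEQ is irrelevant to the interval fields; use CIGAR-consistent widths
  sam[3] <- sub("GATTACA", paste(rep("A", 100), collapse = ""), sam[3])
  sam[5] <- sub("GATTACA", paste(rep("A", 100), collapse = ""), sam[5])
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, f)
  aln <- read_alignment_sam(f)
  expect_equal(nrow(aln), 2L)           # unmapped read skipped
  expect_equal(aln$aln_start, c(150, 10))
  expect_equal(aln$aln_end, c(250, 90))
  expect_equal(aln$aligned_bases, c(100, 80))
  expect_equal(aln$matches, c(98, 80))
  expect_equal(aln$read_length, c(100, 100))
})
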