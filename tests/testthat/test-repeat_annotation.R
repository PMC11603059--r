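rm_header <- c(
  "   SW   perc perc perc  query     position in query    matching repeat",
  "score   div. del. ins.  sequence  begin end   (left)   repeat   class/family begin end (left) ID",
  ""
)

test_that("a standard .out row is parsed with coordinate conversion", {
  row <- "463 1.3 0.6 1.7 contig_1 101 600 (400) + DR0001 LTR/ERV1 1 500 (0) 1"
  ann <- parse_rm_out(text = c(rm_header, row))
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$contig_id, "contig_1")
  expect_equal(ann$start, 100)           # 1-based inclusive -> 0-based
  expect_equal(ann$end, 600)
  expect_equal(ann$sw_score, 463)
  expect_equal(ann$repeat_class_family, "LTR/ERV1")
  expect_equal(ann$repeat_left, 0)
  expect_equal(ann$rm_id, 1L)
  expect_false(ann$overlap_flag)
})

test_that("complement strand, negative remainders and the overlap star parse", {
  row <- "210 12.5 0.0 0.0 ctg 51 180 (20) C rep2 LINE/L1 (30) 700 571 7 *"
  ann <- parse_rm_out(text = row)
  expect_equal(ann$strand, "-")
  expect_equal(ann$repeat_start, -30)
  expect_true(ann$overlap_flag)
  expect_equal(ann$rm_id, 7L)
})

test_that("header-only input yields an empty annotation", {
  ann <- parse_rm_out(text = rm_header)
  expect_s3_class(ann, "te_annotation")
  expect_equal(nrow(ann), 0L)
})

test_that("malformed rows raise parse errors naming the line", {
  bad_begin <- "463 1.3 0.6 1.7 contig_1 abc 600 (400) + R LTR/ERV1 1 500 (0) 1"
  expect_error(parse_rm_out(text = c(rm_header, bad_begin)), "line 4")
  short_row <- "463 1.3 0.6 1.7 contig_1 101 600"
  expect_error(parse_rm_out(text = short_row), "14 fields")
  swapped <- "463 1.3 0.6 1.7 contig_1 700 600 (400) + R LTR/ERV1 1 500 (0) 1"
  expect_error(parse_rm_out(text = swapped), "end .* < start")
})

test_that("write_rm_out round-trips through the parser", {
  withr::with_seed(11, {
    ann <- random_annotation_instance()
  })
  ann$strand[1] <- "-"
  ann$overlap_flag[2] <- TRUE
  ann$repeat_start[1] <- -25
  f <- withr::local_tempfile(fileext = ".out")
  write_rm_out(ann, f)
  back <- parse_rm_out(f)
  for (col in setdiff(names(ann), "rm_id")) {
    expect_equal(back[[col]], ann[[col]], info = col)
  }
  expect_equal(back$rm_id, ann$rm_id)
})

test_that("classify_te maps labels onto the TE taxonomy", {
  got <- classify_te(c("LTR/Gypsy", "Unknown", "Simple_repeat",
                       "LTR/ERV1", "LTR/Pao", "LTR/Foo", "LTR",
                       "RC/Helitron", "DNA/hAT?", "SINE/tRNA",
                       "LINE/Rex-Babar", "rRNA", "Unspecified"))
  expect_equal(got$te_class,
               c("LTR", "Unclear", "NotTE", "LTR", "LTR", "LTR", "LTR",
                 "DNA", "DNA", "SINE", "LINE", "NotTE", "Unclear"))
  expect_equal(got$ltr_superfamily[1], "Gypsy")
  expect_equal(got$ltr_superfamily[6], "LTR_other")
  expect_equal(got$ltr_superfamily[7], "LTR_other")
  # superfamily defined exactly for LTR entries
  expect_true(all(is.na(got$ltr_superfamily) == (got$te_class != "LTR")))
})

test_that("classify_te is total and deterministic", {
  labels <- c("", "garbage", "ltr/gypsy?", "Satellite/acro", "tRNA",
              "DNA", "LINE/L2", "snRNA", "ARTEFACT", "scRNA", "srpRNA")
  a <- classify_te(labels)
  b <- classify_te(labels)
  expect_identical(a, b)
  expect_true(all(a$te_class %in% c(te_classes(), "NotTE")))
})

test_that("filter_redundancy keeps the best of two overlapping entries", {
  ann <- make_annotation("contig_1", c(100, 150), c(300, 350),
                         score = c(500, 300))
  out <- filter_redundancy(ann)
  expect_equal(nrow(out), 1L)
  expect_equal(out$sw_score, 500)
})

test_that("the length filter is strict: match_length 80 is removed", {
  ann <- make_annotation("c1", c(0, 500), c(80, 581), score = c(900, 100))
  out <- filter_redundancy(ann, min_length = 80)
  expect_equal(nrow(out), 1L)
  expect_equal(out$end - out$start, 81)
  expect_identical(nrow(filter_redundancy(ann[0, ])), 0L)
})

test_that("filter_redundancy matches the exhaustive oracle", {
  withr::with_seed(42, {
    for (rep in 1:300) {
      ann <- random_annotation_instance()
      got <- filter_redundancy(ann)
      want <- oracle_filter(ann)
      expect_equal(got$contig_id, want$contig_id)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$sw_score, want$sw_score)
      # survivors never overlap within a contig and exceed the cutoff
      expect_true(all(got$end - got$start > 80))
      if (nrow(got) > 1) {
        by_ctg <- split(got, got$contig_id)
        for (g in by_ctg) {
          if (nrow(g) > 1) {
            g <- g[order(g$start), ]
            expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
          }
        }
      }
    }
  })
})

test_that("filtered annotations export to BED6 and the annotation table", {
  ann <- make_annotation("c1", c(0, 500), c(200, 700), score = c(10, 20))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_annotation_table(ann, f1)
  back <- read_annotation_table(f1)
  expect_equal(back$start, ann$start)
  write_bed6(ann, f2)
  bed <- read.delim(f2, header = FALSE)
  expect_equal(bed$V2, c(0, 500))
  expect_equal(bed$V3, c(200, 700))
})
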