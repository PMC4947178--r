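test_that("vector angle: closed form, symmetry, scale invariance", {
  expect_equal(vector_angle(c(0, 2, 0, 18), c(0, 0, 0, 20)),
               acos(18 / sqrt(328)), tolerance = 1e-12)
  expect_identical(vector_angle(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(vector_angle(c(0, 4, 0, 36), c(0, 0, 0, 20)),
               vector_angle(c(0, 2, 0, 18), c(0, 0, 0, 20)), tolerance = 1e-12)
  expect_equal(vector_angle(c(1, 5, 0, 2), c(0, 3, 1, 9)),
               vector_angle(c(0, 3, 1, 9), c(1, 5, 0, 2)))
  expect_error(vector_angle(c(0, 0, 0, 0), c(1, 1, 1, 1)), "zero count")
})

test_that("read filter drops indel reads and read-end edits", {
  expect_false(filter_read(list(length = 100, indel = TRUE,
                                edit_positions = 50)))
  expect_false(filter_read(list(length = 100, indel = FALSE,
                                edit_positions = 1)))
  expect_false(filter_read(list(length = 100, indel = FALSE,
                                edit_positions = 99)))
  expect_true(filter_read(list(length = 100, indel = FALSE,
                               edit_positions = 50)))
  expect_true(filter_read(list(length = 100, indel = FALSE,
                               edit_positions = integer(0))))
})

test_that("site QC reports each failure code independently", {
  th <- detection_thresholds()
  mk <- function(strand, ref, A, T, G, C) {
    list(strand = strand, ref = ref, A = A, T = T, G = G, C = C)
  }
  clean_ko <- mk("+", "C", 0, 0, 0, 20)
  expect_identical(site_qc(mk("+", "C", 0, 1, 0, 3), clean_ko, th)$reasons,
                   c("coverage", "min_edited"))
  expect_identical(site_qc(mk("+", "C", 0, 1, 0, 18), clean_ko, th)$reasons,
                   "min_edited")
  expect_identical(site_qc(mk("+", "C", 0, 3, 3, 14), clean_ko, th)$reasons,
                   "multiple_transitions")
  expect_identical(
    site_qc(mk("+", "C", 0, 3, 0, 17), mk("+", "C", 0, 2, 0, 18), th)$reasons,
    "ko_signal")
  expect_true(site_qc(mk("+", "C", 0, 3, 0, 17), clean_ko, th)$pass)
  # minus strand: G -> A is the edit, G the reference
  expect_true(site_qc(mk("-", "G", 3, 0, 17, 0),
                      mk("-", "G", 0, 0, 20, 0), th)$pass)
})

test_that("threshold pair at coverage 20: admitted edited-read counts", {
  # brute-force enumeration against a pure-reference knockout
  th <- detection_thresholds()
  admitted <- Filter(function(x) {
    wt <- c(20 - x, x)  # (C, T) sub-vector
    x >= th$min_edited &&
      sqrt(sum(wt^2)) >= th$min_wt_norm &&
      vector_angle(wt, c(20, 0)) >= th$min_angle
  }, 0:20)
  # Euclidean magnitude rejects balanced mid-range vectors (norm < 15)
  expect_identical(as.integer(admitted), c(2:6, 14:20))
  # the angle criterion alone switches on at a 10% editing rate
  angle_ok <- Filter(function(x) {
    vector_angle(c(20 - x, x), c(20, 0)) >= th$min_angle
  }, 0:20)
  expect_identical(min(unlist(angle_ok)) / 20, 0.10)
})

test_that("toy two-site table: only the sufficiently edited site is called", {
  wt <- data.frame(chrom = "chr1", pos = c(100L, 200L), strand = "+",
                   ref = "C", A = 0L, T = c(2L, 1L), G = 0L, C = c(18L, 19L),
                   stringsAsFactors = FALSE)
  ko <- data.frame(chrom = "chr1", pos = c(100L, 200L), strand = "+",
                   ref = "C", A = 0L, T = 0L, G = 0L, C = 20L,
                   stringsAsFactors = FALSE)
  calls <- call_edits(wt, ko)
  expect_identical(calls$pos, 100L)
  expect_equal(calls$editing_rate, 2 / 20)
  expect_equal(calls$angle, acos(18 / sqrt(328)), tolerance = 1e-12)
})

test_that("splice-junction proximity: 3 bp excluded, 5 bp retained", {
  wt <- data.frame(chrom = "chr1", pos = c(97L, 105L), strand = "+",
                   ref = "C", A = 0L, T = 4L, G = 0L, C = 26L,
                   stringsAsFactors = FALSE)
  ko <- transform(wt, T = 0L, C = 30L)
  jx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 100))
  calls <- call_edits(wt, ko, excl = exclusion_tracks(splices = jx))
  expect_identical(calls$pos, 105L)
})

test_that("minus-strand G->A sites call identically to plus-strand C->T", {
  plus_wt <- data.frame(chrom = "chr1", pos = 50L, strand = "+", ref = "C",
                        A = 0L, T = 3L, G = 0L, C = 27L,
                        stringsAsFactors = FALSE)
  plus_ko <- transform(plus_wt, T = 0L, C = 30L)
  minus_wt <- data.frame(chrom = "chr1", pos = 50L, strand = "-", ref = "G",
                         A = 3L, T = 0L, G = 27L, C = 0L,
                         stringsAsFactors = FALSE)
  minus_ko <- transform(minus_wt, A = 0L, G = 30L)
  a <- call_edits(plus_wt, plus_ko)
  b <- call_edits(minus_wt, minus_ko)
  expect_equal(a$editing_rate, b$editing_rate)
  expect_equal(a$angle, b$angle)
  expect_equal(a$wt_norm, b$wt_norm)
})

test_that("the 50-site planted fixture is recovered exactly", {
  fx <- build_detect_fixture()
  expect_identical(nrow(fx$wt), 50L)
  calls <- call_edits(fx$wt, fx$ko, excl = fx$excl,
                      transcripts = fx$transcripts)
  expect_identical(sort(paste0(calls$chrom, ":", calls$pos)), fx$truth)
  # deterministic output order
  expect_identical(order(calls$chrom, calls$pos), seq_len(nrow(calls)))
  # transcript classification: 3 sites -> hyperedited, 1 -> site-specific
  cls <- classify_transcript(calls)
  expect_identical(cls$class[cls$transcript_id == "TxHyper"], "hyperedited")
  expect_identical(cls$class[cls$transcript_id == "TxSolo4"], "site-specific")
  expect_identical(cls$class[cls$transcript_id == "TxMinus"], "hyperedited")
})

test_that("malformed base-count tables are rejected with their line", {
  bad <- data.frame(chrom = "chr1", pos = 1L, strand = "+", ref = "C",
                    A = 0L, T = -1L, G = 0L, C = 5L, stringsAsFactors = FALSE)
  expect_error(call_edits(bad, bad), "line 2")
  noref <- data.frame(chrom = "chr1", pos = 1L, strand = "+", ref = "N",
                      A = 0L, T = 1L, G = 0L, C = 5L, stringsAsFactors = FALSE)
  expect_error(call_edits(noref, noref), "A/C/G/T")
})
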