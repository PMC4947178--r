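# 50-site synthetic detection fixture: planted true edits among decoys that
# each trip exactly one filter. Returns the wt/ko tables, exclusion tracks,
# transcript map and the planted truth (chrom:pos keys expected to be called).
build_detect_fixture <- function() {
  rows <- list()
  truth <- character(0)
  transcripts <- list()
  add <- function(chrom, pos, strand, ref, wt, ko, true_site = FALSE,
                  transcript = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, strand = strand, ref = ref,
      wA = wt[1], wT = wt[2], wG = wt[3], wC = wt[4],
      kA = ko[1], kT = ko[2], kG = ko[3], kC = ko[4],
      stringsAsFactors = FALSE)
    if (true_site) truth <<- c(truth, paste0(chrom, ":", pos))
    if (!is.na(transcript)) {
      transcripts[[length(transcripts) + 1L]] <<- data.frame(
        chrom = chrom, pos = pos, strand = strand,
        transcript_id = transcript, stringsAsFactors = FALSE)
    }
  }

  # counts are (A, T, G, C)
  # 10 true plus-strand C->T edits, coverage/edited varied but all passing
  for (i in 1:10) {
    pos <- 1000L + 100L * i
    total <- 20L + 4L * i               # comfortably above norm threshold
    edited <- max(2L, as.integer(round(0.15 * total)))  # ~15% editing
    add("chr1", pos, "+", "C", c(0, edited, 0, total - edited),
        c(0, 0, 0, total), true_site = TRUE,
        transcript = if (i <= 3) "TxHyper" else sprintf("TxSolo%d", i))
  }
  # 4 true minus-strand sites (genomic G->A)
  for (i in 1:4) {
    pos <- 5000L + 50L * i
    add("chr1", pos, "-", "G", c(4, 0, 26, 0), c(0, 0, 30, 0),
        true_site = TRUE, transcript = "TxMinus")
  }

  # decoys
  add("chr1", 7010, "+", "C", c(0, 1, 0, 3), c(0, 0, 0, 4))     # coverage < 5
  add("chr1", 7020, "+", "C", c(0, 1, 0, 29), c(0, 0, 0, 30))   # 1 edited read
  add("chr1", 7030, "+", "C", c(0, 3, 3, 24), c(0, 0, 0, 30))   # multi transition
  add("chr1", 7040, "+", "C", c(0, 3, 0, 27), c(0, 2, 0, 28))   # edit also in KO
  add("chr1", 7050, "+", "C", c(0, 2, 0, 10), c(0, 0, 0, 12))   # wt norm < 15
  add("chr1", 7060, "+", "C", c(0, 2, 0, 58), c(0, 0, 0, 60))   # angle < 0.11
  add("chr1", 7070, "+", "A", c(28, 3, 0, 0), c(30, 0, 0, 0))   # not a C site
  add("chr1", 7080, "+", "C", c(0, 4, 0, 26), c(0, 0, 0, 30))   # in dbSNP
  add("chr1", 7090, "+", "C", c(0, 4, 0, 26), c(0, 0, 0, 30))   # in repeat
  add("chr1", 7100, "+", "C", c(0, 4, 0, 26), c(0, 0, 0, 30))   # 3 bp from junction
  add("chr2", 8000, "+", "C", c(0, 4, 0, 26), c(0, 0, 0, 30),   # 5 bp clears it
      true_site = TRUE, transcript = "TxNearJx")

  # filler sites: unedited, should never appear
  for (i in 1:25) {
    add("chr2", 9000L + 10L * i, "+", "C", c(0, 0, 0, 30), c(0, 0, 0, 30))
  }

  tab <- do.call(rbind, rows)
  wt <- data.frame(chrom = tab$chrom, pos = tab$pos, strand = tab$strand,
                   ref = tab$ref, A = tab$wA, T = tab$wT, G = tab$wG,
                   C = tab$wC, stringsAsFactors = FALSE)
  ko <- data.frame(chrom = tab$chrom, pos = tab$pos, strand = tab$strand,
                   ref = tab$ref, A = tab$kA, T = tab$kT, G = tab$kG,
                   C = tab$kC, stringsAsFactors = FALSE)
  excl <- exclusion_tracks(
    snps = GenomicRanges::GRanges("chr1", IRanges::IRanges(7080, 7080)),
    splices = GenomicRanges::GRanges(c("chr1", "chr2"),
                                     IRanges::IRanges(c(7103, 8005),
                                                      c(7103, 8005))),
    repeats = GenomicRanges::GRanges("chr1", IRanges::IRanges(7085, 7095)))
  list(wt = wt, ko = ko, excl = excl,
       transcripts = do.call(rbind, transcripts), truth = sort(truth))
}
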