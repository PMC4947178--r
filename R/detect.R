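#' Detection thresholds for the bulk editing-site caller
#'
#' Defaults reproduce the stringent quality-control settings of the
#' wild-type versus knockout comparison: at least 5 reads covering a site,
#' at least 2 reads supporting the edit, wild-type base-count vector of
#' Euclidean magnitude at least 15, angle between wild-type and knockout
#' vectors at least 0.11 radians, and exclusion of sites within 4 bp of a
#' splice junction.
#'
#' @param min_coverage minimum wild-type reads covering the site.
#' @param min_edited minimum reads supporting the edit.
#' @param min_wt_norm minimum Euclidean norm of the wild-type vector.
#' @param min_angle minimum wild-type/knockout angle in radians.
#' @param splice_distance exclusion half-window around splice junctions (bp).
#' @return An object of class `detection_thresholds`.
#' @export
detection_thresholds <- function(min_coverage = 5, min_edited = 2,
                                 min_wt_norm = 15, min_angle = 0.11,
                                 splice_distance = 4) {
  vals <- c(min_coverage, min_edited, min_wt_norm, min_angle, splice_distance)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all thresholds must be nonnegative")
  }
  structure(list(min_coverage = min_coverage, min_edited = min_edited,
                 min_wt_norm = min_wt_norm, min_angle = min_angle,
                 splice_distance = splice_distance),
            class = "detection_thresholds")
}

#' Angle between two base-count vectors
#'
#' The arccosine of the normalized dot product of two per-site (A, T, G, C)
#' read-count vectors; invariant under positive scaling of either vector
#' and symmetric in its arguments. For nonnegative counts the angle lies in
#' `[0, pi/2]`.
#'
#' @param u,w nonnegative numeric count vectors of equal length (usually 4).
#' @return The angle in radians.
#' @export
#' @examples
#' vector_angle(c(0, 2, 0, 18), c(0, 0, 0, 20))  # ~0.1107
vector_angle <- function(u, w) {
  if (length(u) != length(w)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) stop("angle undefined for a zero count vector")
  acos(min(max(sum(u * w) / (nu * nw), -1), 1))
}

#' Read-level filter for edit-supporting reads
#'
#' A read abstraction is kept only if it contains no indel and no candidate
#' edit in its first or last two base pairs.
#'
#' @param read list with `length` (read length), `indel` (logical) and
#'   `edit_positions` (1-based offsets of candidate edits within the read;
#'   may be empty).
#' @return `TRUE` to keep the read, `FALSE` to drop it.
#' @export
#' @examples
#' filter_read(list(length = 100, indel = FALSE, edit_positions = 50))  # keep
#' filter_read(list(length = 100, indel = FALSE, edit_positions = 1))   # drop
filter_read <- function(read) {
  len <- read$length
  if (is.null(len) || len < 1) stop("read must have a defined length")
  if (isTRUE(read$indel)) return(FALSE)
  ep <- read$edit_positions
  if (length(ep) > 0 && any(ep <= 2 | ep > len - 2)) return(FALSE)
  TRUE
}

# edited / reference base symbols for a C-to-U site given the strand:
# plus-strand sites show C -> T on the genome, minus-strand sites G -> A
edit_bases <- function(strand) {
  if (strand == "+") c(ref = "C", alt = "T") else c(ref = "G", alt = "A")
}

# per-row base counts as a named A/T/G/C vector
row_counts <- function(row) {
  c(A = row[["A"]], T = row[["T"]], G = row[["G"]], C = row[["C"]])
}

#' Site-level quality control for one candidate editing site
#'
#' Applies the count-based filters to the wild-type/knockout base-count
#' pair at one coordinate: minimum wild-type coverage, minimum
#' edit-supporting reads, no second non-reference base with
#' `min_edited`-level support ("multiple transitions"), and no
#' edit-supporting reads in the knockout (only enzyme-dependent changes
#' are kept). Each failure is reported independently.
#'
#' @param wt,ko single-site rows: lists/one-row data.frames with `strand`,
#'   `ref`, and counts `A`, `T`, `G`, `C`.
#' @param th a [detection_thresholds()] object.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   failure codes among `coverage`, `min_edited`, `multiple_transitions`,
#'   `ko_signal`).
#' @export
site_qc <- function(wt, ko, th = detection_thresholds()) {
  if (!identical(wt$ref, ko$ref)) stop("ref base differs between samples")
  eb <- edit_bases(wt$strand)
  if (!identical(as.character(wt$ref), unname(eb["ref"]))) {
    return(list(pass = FALSE, reasons = "not_editable_ref"))
  }
  cw <- row_counts(wt)
  ck <- row_counts(ko)
  reasons <- character(0)
  if (sum(cw) < th$min_coverage) reasons <- c(reasons, "coverage")
  if (cw[[eb["alt"]]] < th$min_edited) reasons <- c(reasons, "min_edited")
  others <- setdiff(names(cw), eb)
  if (any(cw[others] >= th$min_edited)) {
    reasons <- c(reasons, "multiple_transitions")
  }
  if (ck[[eb["alt"]]] > 0) reasons <- c(reasons, "ko_signal")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Read a BED file of exclusion intervals
#'
#' @param path BED file (3+ columns, 0-based half-open).
#' @return A `GRanges` (1-based closed coordinates, converted by
#'   `rtracklayer`).
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Annotation tracks excluding candidate editing sites
#'
#' @param snps,splices,repeats each `NULL`, a BED file path, or a
#'   `GRanges`: known genomic SNPs, splice-junction positions, and
#'   simple/tandem repeat regions.
#' @return An object of class `exclusion_tracks`.
#' @export
exclusion_tracks <- function(snps = NULL, splices = NULL, repeats = NULL) {
  as_track <- function(x) {
    if (is.null(x)) return(GenomicRanges::GRanges())
    if (is.character(x)) x <- read_bed(x)
    if (!methods::is(x, "GRanges")) stop("tracks must be BED paths or GRanges")
    if (any(GenomicRanges::width(x) < 1)) stop("malformed interval (start >= end)")
    x
  }
  structure(list(snps = as_track(snps), splices = as_track(splices),
                 repeats = as_track(repeats)),
            class = "exclusion_tracks")
}

# validate a base-count table read from TSV or built in memory
check_base_table <- function(tab, what) {
  need <- c("chrom", "pos", "strand", "ref", "A", "T", "G", "C")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  }
  for (i in seq_len(nrow(tab))) {
    cnt <- unlist(tab[i, c("A", "T", "G", "C")])
    if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != floor(cnt))) {
      stop(sprintf("%s table line %d: base counts must be nonnegative integers",
                   what, i + 1L))
    }
    if (!tab$ref[i] %in% c("A", "C", "G", "T")) {
      stop(sprintf("%s table line %d: ref must be one of A/C/G/T", what, i + 1L))
    }
    if (!tab$strand[i] %in% c("+", "-")) {
      stop(sprintf("%s table line %d: strand must be + or -", what, i + 1L))
    }
  }
  tab$pos <- as.integer(tab$pos)
  tab
}

#' Read a per-site base-count table
#'
#' Tab-separated pileup summary with columns `chrom`, `pos` (1-based),
#' `strand`, `ref`, `A`, `T`, `G`, `C`; one file per sample. Lines
#' beginning with `#` are ignored.
#'
#' @param path TSV file path.
#' @return A validated `data.frame`.
#' @export
read_base_counts <- function(path) {
  tab <- tryCatch(
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                     conditionMessage(e))))
  check_base_table(tab, basename(path))
}

#' Call C-to-U editing sites from wild-type and knockout base counts
#'
#' The core detection statistic: sites passing [site_qc()] whose wild-type
#' base-count vector has Euclidean norm at least `min_wt_norm` and whose
#' angle to the knockout vector is at least `min_angle` radians are
#' retained, then filtered against SNP and repeat intervals and a
#' `splice_distance` window around splice junctions. Minus-strand sites are
#' handled as genomic G-to-A, the complement of the transcript's C-to-U.
#'
#' @param wt,ko base-count `data.frame`s (see [read_base_counts()])
#'   indexed by (`chrom`, `pos`, `strand`) on the same reference.
#' @param th a [detection_thresholds()] object.
#' @param excl an [exclusion_tracks()] object (optional).
#' @param transcripts optional `data.frame` with columns `chrom`, `pos`,
#'   `strand`, `transcript_id` assigning called sites to transcripts.
#' @return A `data.frame` ordered by (`chrom`, `pos`) with columns `chrom`,
#'   `pos`, `strand`, `ref`, `edited_reads`, `total_reads`, `editing_rate`
#'   (edited / (edited + reference) reads), `angle`, `wt_norm`, and, when
#'   `transcripts` is given, `transcript_id` and `class` (site-specific /
#'   hyperedited).
#' @export
call_edits <- function(wt, ko, th = detection_thresholds(),
                       excl = exclusion_tracks(), transcripts = NULL) {
  wt <- check_base_table(wt, "wild-type")
  ko <- check_base_table(ko, "knockout")
  key <- function(t) paste(t$chrom, t$pos, t$strand, sep = ":")
  ko_idx <- match(key(wt), key(ko))

  calls <- list()
  for (i in seq_len(nrow(wt))) {
    j <- ko_idx[i]
    if (is.na(j)) next
    w <- as.list(wt[i, ])
    k <- as.list(ko[j, ])
    qc <- site_qc(w, k, th)
    if (!qc$pass) next
    cw <- row_counts(w)
    ck <- row_counts(k)
    if (sqrt(sum(cw^2)) < th$min_wt_norm) next
    if (sum(ck) == 0) next
    ang <- vector_angle(cw, ck)
    if (ang < th$min_angle) next
    eb <- edit_bases(w$strand)
    edited <- cw[[eb["alt"]]]
    ref_reads <- cw[[eb["ref"]]]
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = w$chrom, pos = w$pos, strand = w$strand, ref = w$ref,
      edited_reads = edited, total_reads = sum(cw),
      editing_rate = edited / (edited + ref_reads),
      angle = ang, wt_norm = sqrt(sum(cw^2)),
      stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) do.call(rbind, calls) else data.frame(
    chrom = character(0), pos = integer(0), strand = character(0),
    ref = character(0), edited_reads = integer(0), total_reads = integer(0),
    editing_rate = numeric(0), angle = numeric(0), wt_norm = numeric(0),
    stringsAsFactors = FALSE)

  if (nrow(out) > 0 && inherits(excl, "exclusion_tracks")) {
    sites <- GenomicRanges::GRanges(out$chrom,
                                    IRanges::IRanges(out$pos, width = 1L))
    drop <- rep(FALSE, nrow(out))
    if (length(excl$snps)) {
      drop <- drop | GenomicRanges::countOverlaps(sites, excl$snps,
                                                  ignore.strand = TRUE) > 0
    }
    if (length(excl$repeats)) {
      drop <- drop | GenomicRanges::countOverlaps(sites, excl$repeats,
                                                  ignore.strand = TRUE) > 0
    }
    if (length(excl$splices)) {
      win <- suppressWarnings(excl$splices + th$splice_distance)
      drop <- drop | GenomicRanges::countOverlaps(sites, win,
                                                  ignore.strand = TRUE) > 0
    }
    out <- out[!drop, , drop = FALSE]
  }

  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(transcripts)) {
    tk <- paste(transcripts$chrom, transcripts$pos, transcripts$strand,
                sep = ":")
    out$transcript_id <- transcripts$transcript_id[match(key(out), tk)]
    cls <- classify_transcript(out)
    out$class <- cls$class[match(out$transcript_id, cls$transcript_id)]
  }
  out
}

#' Classify transcripts by number of called editing sites
#'
#' A transcript with exactly one called site is `site-specific`; one with
#' two or more distinct called sites is `hyperedited`; with none, `none`.
#'
#' @param calls a [call_edits()] result carrying a `transcript_id` column
#'   (rows with `NA` transcript are ignored), or any `data.frame` with one
#'   row per called site and a `transcript_id` column.
#' @return `data.frame` with columns `transcript_id`, `n_sites`, `class`.
#' @export
classify_transcript <- function(calls) {
  if (!"transcript_id" %in% names(calls)) {
    stop("calls must carry a transcript_id column")
  }
  ids <- calls$transcript_id[!is.na(calls$transcript_id)]
  tab <- table(ids)
  data.frame(transcript_id = names(tab),
             n_sites = as.integer(tab),
             class = ifelse(tab >= 2, "hyperedited",
                            ifelse(tab == 1, "site-specific", "none")),
             stringsAsFactors = FALSE)
}
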