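#' Load per-site single-cell counts and their cognate bulk pairs
#'
#' The single-cell table is TSV with columns `site_id`, `chrom`, `pos`
#' (1-based), `strand`, `cell_id`, `edited_reads`, `total_reads`; the
#' companion bulk table has `site_id`, `edited_reads`, `total_reads`.
#' Lines beginning with `#` are ignored. All counts are integrity-checked
#' and parse errors name the offending data row.
#'
#' @param cells_path path to the single-cell counts TSV.
#' @param bulk_path path to the bulk counts TSV.
#' @return Named list of [site_dataset()] objects, one per `site_id`.
#' @export
load_single_cell_counts <- function(cells_path, bulk_path) {
  cells <- read_checked_tsv(cells_path,
                            c("site_id", "chrom", "pos", "strand", "cell_id",
                              "edited_reads", "total_reads"))
  bulk <- read_checked_tsv(bulk_path,
                           c("site_id", "edited_reads", "total_reads"))
  check_counts_cols(cells, cells_path)
  check_counts_cols(bulk, bulk_path)

  out <- list()
  for (sid in unique(cells$site_id)) {
    sc <- cells[cells$site_id == sid, , drop = FALSE]
    bi <- which(bulk$site_id == sid)
    if (length(bi) == 0L) {
      stop(sprintf("site '%s' has no row in the bulk table %s", sid, bulk_path))
    }
    out[[sid]] <- site_dataset(
      sc$chrom[1L], sc$pos[1L], sc$strand[1L],
      cell_counts(sc$cell_id, sc$edited_reads, sc$total_reads),
      bulk_counts(bulk$edited_reads[bi[1L]], bulk$total_reads[bi[1L]]))
  }
  out
}

read_checked_tsv <- function(path, need) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  }
  tab
}

check_counts_cols <- function(tab, path) {
  for (col in c("edited_reads", "total_reads")) {
    bad <- which(!is.finite(tab[[col]]) | tab[[col]] < 0 |
                   tab[[col]] != floor(tab[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("%s row %d: %s must be a nonnegative integer",
                   path, bad[1L], col))
    }
  }
  bad <- which(tab$edited_reads > tab$total_reads)
  if (length(bad) > 0) {
    stop(sprintf("%s row %d: edited_reads exceeds total_reads", path, bad[1L]))
  }
  invisible(tab)
}

#' Write site data sets in the TSV dialect consumed by the CLI
#'
#' @param datasets named list of [site_dataset()] objects.
#' @param cells_path,bulk_path output TSV paths.
#' @param seed,config optional provenance recorded in header comments.
#' @return Invisibly, the two paths.
#' @export
write_single_cell_counts <- function(datasets, cells_path, bulk_path,
                                     seed = NULL, config = NULL) {
  rows <- do.call(rbind, lapply(names(datasets), function(sid) {
    d <- datasets[[sid]]
    data.frame(site_id = sid, chrom = d$site$chrom, pos = d$site$pos,
               strand = d$site$strand, cell_id = d$cells$cell_id,
               edited_reads = d$cells$x, total_reads = d$cells$n,
               stringsAsFactors = FALSE)
  }))
  brows <- do.call(rbind, lapply(names(datasets), function(sid) {
    d <- datasets[[sid]]
    data.frame(site_id = sid, edited_reads = d$bulk$x,
               total_reads = d$bulk$n, stringsAsFactors = FALSE)
  }))
  write_tsv_with_header(rows, cells_path, seed, config)
  write_tsv_with_header(brows, bulk_path, seed, config)
  invisible(c(cells_path, bulk_path))
}

#' One summary row for a fitted site posterior
#'
#' @param post a [run_sampler()] result.
#' @param site_id identifier to report.
#' @return One-row `data.frame` with `site_id`, `J`, `bulk_rate`, `v_mean`,
#'   `v_mode`, `hpd_lo`, `hpd_hi`, `excludes_zero`, `acceptance_rate`,
#'   `seed`.
#' @export
summarize_posterior <- function(post, site_id = "site") {
  stopifnot(inherits(post, "posterior_samples"))
  hpd <- hpd_interval(post$v)
  data.frame(site_id = site_id, J = ncol(post$p), bulk_rate = post$p_hat,
             v_mean = mean(post$v),
             v_mode = density_mode(post$v, upper = post$v_max),
             hpd_lo = hpd$lo, hpd_hi = hpd$hi,
             excludes_zero = excludes_zero(
               hpd, post$settings$excludes_zero_delta),
             acceptance_rate = post$acceptance_rate,
             seed = post$settings$seed, stringsAsFactors = FALSE)
}

#' Write per-site posterior summaries to TSV
#'
#' @param results `data.frame` of rows from [summarize_posterior()] (or a
#'   list of such rows, which are bound together).
#' @param path output TSV.
#' @param seed,config optional provenance recorded in header comments.
#' @return Invisibly, `path`.
#' @export
write_posterior_summary <- function(results, path, seed = NULL,
                                    config = NULL) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, results)
  }
  cols <- c("site_id", "J", "bulk_rate", "v_mean", "v_mode", "hpd_lo",
            "hpd_hi", "excludes_zero", "acceptance_rate", "seed")
  miss <- setdiff(cols, names(results))
  if (length(miss) > 0) {
    stop(sprintf("summary is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  write_tsv_with_header(results[, cols], path, seed, config)
  invisible(path)
}

# provenance header + table; deterministic bytes for identical inputs
write_tsv_with_header <- function(tab, path, seed = NULL, config = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# editvar %s", as.character(packageVersion("editvar"))),
             con)
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", as.integer(seed)), con)
  if (!is.null(config)) {
    writeLines(sprintf("# config_hash=%s", config_hash(config)), con)
  }
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Short stable hash of a configuration object
#'
#' 32-bit FNV-1a over the deparsed configuration, used to stamp output
#' files so that reruns with identical settings are recognizably identical.
#'
#' @param config any R object.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor touches only the low byte since b < 256
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b))
    # 32-bit modular multiply split into 16-bit halves to stay exact
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  paste0(format(as.hexmode(floor(h / 65536)), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}
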