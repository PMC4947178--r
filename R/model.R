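#' Per-cell read counts at one editable site
#'
#' Builds the single-cell observation table for one genomic site: for each
#' cell `j`, the number of edited reads `x` and the total number of mapped
#' reads `n` covering the site.
#'
#' @param cell_id character or integer vector of unique cell identifiers.
#' @param x integer vector, edited-read counts (one per cell).
#' @param n integer vector, total mapped-read counts (one per cell).
#'
#' @return A `data.frame` with columns `cell_id`, `x`, `n`.
#' @export
#' @examples
#' cell_counts(c("c1", "c2"), x = c(3, 0), n = c(20, 18))
cell_counts <- function(cell_id, x, n) {
  if (length(cell_id) != length(x) || length(x) != length(n)) {
    stop("cell_id, x and n must have equal length")
  }
  if (anyDuplicated(cell_id)) stop("cell_ids must be unique")
  x <- check_count(x, "x")
  n <- check_count(n, "n")
  if (any(x > n)) stop("edited reads x cannot exceed total reads n")
  data.frame(cell_id = as.character(cell_id), x = x, n = n,
             stringsAsFactors = FALSE)
}

#' Bulk read counts at one editable site
#'
#' @param x integer, edited-read count in the bulk sample.
#' @param n integer, total read count in the bulk sample (at least 1).
#'
#' @return An object of class `bulk_counts`.
#' @export
#' @examples
#' bulk_counts(23, 100)
bulk_counts <- function(x, n) {
  x <- check_count(x, "x")
  n <- check_count(n, "n")
  if (length(x) != 1L || length(n) != 1L) stop("bulk counts are scalars")
  if (n < 1L) stop("bulk total read count n must be >= 1")
  if (x > n) stop("edited reads x cannot exceed total reads n")
  structure(list(x = x, n = n), class = "bulk_counts")
}

#' One site's observations: single-cell counts plus the cognate bulk pair
#'
#' The unit of inference: `J` per-cell (edited, total) read-count pairs and
#' the bulk (edited, total) pair at the same genomic coordinate.
#'
#' @param chrom chromosome name.
#' @param pos 1-based genomic position (>= 1).
#' @param strand `"+"` or `"-"`.
#' @param cells a `data.frame` from [cell_counts()].
#' @param bulk a [bulk_counts()] object.
#'
#' @return An object of class `site_dataset` with elements `site`
#'   (chrom/pos/strand), `cells` and `bulk`.
#' @export
#' @examples
#' sd <- site_dataset("chr2", 122152902, "+",
#'                    cell_counts("c1", 5, 20), bulk_counts(23, 100))
#' sd
site_dataset <- function(chrom, pos, strand = "+", cells, bulk) {
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("pos must be a 1-based position >= 1")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!is.data.frame(cells) || !all(c("cell_id", "x", "n") %in% names(cells))) {
    stop("cells must be a data.frame from cell_counts()")
  }
  if (nrow(cells) < 1L) stop("need at least one cell (J >= 1)")
  if (!inherits(bulk, "bulk_counts")) stop("bulk must be a bulk_counts object")
  structure(list(site = list(chrom = as.character(chrom), pos = pos,
                             strand = strand),
                 cells = cells, bulk = bulk),
            class = "site_dataset")
}

#' @export
print.site_dataset <- function(x, ...) {
  cat(sprintf("site_dataset %s:%d(%s) with J = %d cells; bulk %d/%d edited\n",
              x$site$chrom, x$site$pos, x$site$strand, nrow(x$cells),
              x$bulk$x, x$bulk$n))
  invisible(x)
}

#' Bulk mean editing-rate estimator
#'
#' The bulk population is large, so the mean editing rate is estimated by
#' the plain ratio `x / n`. Rates of exactly 0 or 1 are flagged as
#' degenerate because they cannot serve directly as a beta mean.
#'
#' @param bulk a [bulk_counts()] object.
#'
#' @return The rate `x / n` with attribute `degenerate` (TRUE when the rate
#'   is exactly 0 or 1); see [is_degenerate_rate()].
#' @export
#' @examples
#' bulk_mean(bulk_counts(23, 100))  # 0.23
bulk_mean <- function(bulk) {
  if (!inherits(bulk, "bulk_counts")) stop("bulk must be a bulk_counts object")
  if (bulk$n == 0L) stop("bulk has zero reads; the mean rate is undefined")
  p <- bulk$x / bulk$n
  attr(p, "degenerate") <- (bulk$x == 0L || bulk$x == bulk$n)
  p
}

#' @rdname bulk_mean
#' @param rate a rate returned by [bulk_mean()].
#' @export
is_degenerate_rate <- function(rate) isTRUE(attr(rate, "degenerate"))

#' Clamp a bulk rate into the open unit interval
#'
#' A bulk estimate of exactly 0 or 1 is moved just inside (0, 1) before use
#' as a beta mean; the clamp `1 / (2 n)` follows the resolution of the data.
#'
#' @param p a rate in \[0, 1\].
#' @param n the bulk read count that produced it.
#' @return `p` restricted to `[1/(2n), 1 - 1/(2n)]`.
#' @export
clamp_rate <- function(p, n) {
  eps <- 1 / (2 * n)
  pmin(pmax(as.numeric(p), eps), 1 - eps)
}

#' Beta shape parameters from a mean/variance pair
#'
#' The model's beta layer is parametrized by its mean `m` and variance `v`;
#' this converts to the standard shapes via the precision
#' `s = m(1 - m)/v - 1`, giving `alpha = m s`, `beta = (1 - m) s`.
#'
#' @param m mean, strictly inside (0, 1).
#' @param v variance, strictly inside (0, m(1 - m)). `v = 0` is the
#'   point-mass base model and deliberately has no shape representation:
#'   callers must branch on it (an error of class `editvar_degenerate_beta`
#'   is signalled).
#'
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
#' @examples
#' beta_shapes(0.5, 1 / 12)  # Beta(1, 1)
beta_shapes <- function(m, v) {
  if (!is.finite(m) || m <= 0 || m >= 1) stop("mean m must lie in (0, 1)")
  if (!is.finite(v) || v < 0) stop("variance v must be >= 0")
  if (v == 0) {
    stop(structure(class = c("editvar_degenerate_beta", "error", "condition"),
                   list(message = "v = 0 is a point mass at m; no beta shapes exist",
                        call = sys.call(-1))))
  }
  bound <- m * (1 - m)
  # treat values within fp eps of the bound as the degenerate boundary
  if (v >= bound * (1 - 1e-12)) {
    stop(sprintf("variance v = %g is outside [0, m(1-m) = %g)", v, bound))
  }
  s <- bound / v - 1
  c(alpha = m * s, beta = (1 - m) * s)
}

#' Beta-binomial probability mass in the mean/variance parametrization
#'
#' Probability of `x` edited reads out of `n` when the per-cell editing rate
#' is beta-distributed with mean `m` and variance `v`. Computed in log space
#' through log-gamma functions so that read depths of hundreds do not
#' underflow. `v = 0` collapses to `Binomial(n, m)`.
#'
#' @param x integer vector of edited-read counts in `0..n`.
#' @param n integer total read count.
#' @param m beta mean in (0, 1).
#' @param v beta variance in `[0, m(1-m))`.
#' @param log return log probabilities?
#'
#' @return Numeric vector of (log) probabilities, one per element of `x`.
#' @export
#' @examples
#' dbetabinom(0:4, 4, m = 0.5, v = 1 / 12)  # uniform: all 0.2
dbetabinom <- function(x, n, m, v, log = FALSE) {
  if (any(x < 0 | x > n | x != floor(x))) stop("x must be integers in 0..n")
  if (v == 0) return(dbinom(x, n, m, log = log))
  sh <- beta_shapes(m, v)
  ll <- lchoose(n, x) + lbeta(x + sh[["alpha"]], n - x + sh[["beta"]]) -
    lbeta(sh[["alpha"]], sh[["beta"]])
  if (log) ll else exp(ll)
}

# shared count validation
check_count <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    stop(sprintf("%s must be nonnegative integers", what))
  }
  as.integer(x)
}
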