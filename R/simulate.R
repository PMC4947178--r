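#' Simulation recipe for artificial single-cell editing data
#'
#' Describes one artificial data set: `J` cells whose editing rates are
#' drawn from a mixture of rate intervals, read counts at a fixed (or
#' per-cell) coverage, and a cognate bulk sample aggregated from a large
#' emulated population.
#'
#' @param J number of cells (>= 1).
#' @param coverage reads per cell; scalar or length-`J` vector.
#' @param regions list of `c(lo, hi)` rate intervals with
#'   `0 <= lo < hi <= 1`.
#' @param weights region weights summing to 1 (default equal).
#' @param bulk_population number of cells emulated in the bulk aggregate
#'   (default 1e5, matching a bulk experiment of at least 1e5 cells).
#' @param bulk_reads total bulk read count (default 1e4, so bulk
#'   estimator noise is negligible against the region widths).
#' @param bulk_mean optional override: construct the bulk pair at this
#'   fixed mean rate instead of aggregating a drawn population (used by
#'   scenarios whose stated bulk mean is not the cell-mixture mean).
#' @param seed integer seed.
#'
#' @return An object of class `scenario_config`.
#' @export
#' @examples
#' scenario_config(J = 20, coverage = 20,
#'                 regions = list(c(0, 0.05), c(0.95, 1)), seed = 1)
scenario_config <- function(J, coverage, regions, weights = NULL,
                            bulk_population = 1e5, bulk_reads = 1e4,
                            bulk_mean = NULL, seed) {
  J <- as.integer(J)
  if (is.na(J) || J < 1L) stop("J must be an integer >= 1")
  if (length(coverage) == 1L) coverage <- rep(coverage, J)
  coverage <- check_count(coverage, "coverage")
  if (length(coverage) != J) stop("coverage must be scalar or length J")
  if (any(coverage < 1L)) stop("coverage must be >= 1 per cell")
  if (!is.list(regions) || length(regions) == 0L) {
    stop("regions must be a nonempty list of c(lo, hi) intervals")
  }
  reg <- do.call(rbind, lapply(regions, function(r) {
    if (length(r) != 2L || r[1] < 0 || r[2] > 1 || r[1] >= r[2]) {
      stop("each region must satisfy 0 <= lo < hi <= 1")
    }
    as.numeric(r)
  }))
  if (is.null(weights)) weights <- rep(1 / nrow(reg), nrow(reg))
  if (length(weights) != nrow(reg) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be nonnegative, one per region, summing to 1")
  }
  if (!is.null(bulk_mean) &&
      (!is.finite(bulk_mean) || bulk_mean <= 0 || bulk_mean >= 1)) {
    stop("bulk_mean override must lie in (0, 1)")
  }
  if (missing(seed)) stop("seed is required")
  structure(list(J = J, coverage = coverage, regions = reg,
                 weights = as.numeric(weights),
                 bulk_population = as.integer(bulk_population),
                 bulk_reads = as.integer(bulk_reads),
                 bulk_mean = bulk_mean, seed = as.integer(seed)),
            class = "scenario_config")
}

# region-mixture rate draws using the current RNG state
draw_rates <- function(config, k) {
  ridx <- sample.int(nrow(config$regions), k, replace = TRUE,
                     prob = config$weights)
  lo <- config$regions[ridx, 1L]
  hi <- config$regions[ridx, 2L]
  r <- runif(k, lo, hi)
  attr(r, "region") <- ridx
  attr(r, "region_bounds") <- config$regions
  r
}

#' Draw per-cell editing rates from the scenario's rate regions
#'
#' Each cell's rate is drawn by first choosing a region by weight, then
#' uniformly within it. Seeds the RNG from `config$seed`; inside
#' [simulate_scenario()] the unseeded internal draw is used instead so the
#' whole scenario is one stream.
#'
#' @param config a [scenario_config()].
#' @return Numeric vector of `J` rates with attribute `region` (the region
#'   index each rate was drawn from).
#' @export
sample_cell_rates <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  draw_rates(config, config$J)
}

#' Read counts realizing drawn editing rates at fixed coverage
#'
#' Edited-read counts are the deterministic rounding `x = round(p * n)`,
#' nudged by one read when rounding pushed the effective rate `x / n`
#' outside the region the rate was drawn from (when an integer ratio
#' inside the region exists). The artificial data fix the effective rates
#' inside the stated regions; the binomial layer is supplied by the model
#' during inference, not by the generator.
#'
#' @param rates rates from [sample_cell_rates()] (with its `region`
#'   attribute) or a plain numeric vector.
#' @param coverage reads per cell, scalar or one per rate.
#' @param regions region matrix (rows `lo, hi`); defaults to the attribute
#'   carried by `rates`.
#' @return A [cell_counts()] data.frame with cell ids `cell_1 ... cell_J`.
#' @export
counts_from_rates <- function(rates, coverage, regions = NULL) {
  J <- length(rates)
  if (length(coverage) == 1L) coverage <- rep(coverage, J)
  n <- check_count(coverage, "coverage")
  x <- as.integer(round(rates * n))
  x <- pmin(pmax(x, 0L), n)
  ridx <- attr(rates, "region")
  if (is.null(regions)) regions <- attr(rates, "region_bounds")
  if (!is.null(ridx) && !is.null(regions)) {
    lo <- regions[ridx, 1L]
    hi <- regions[ridx, 2L]
    eff <- x / n
    up <- eff < lo & (x + 1L) / n <= hi & x < n
    x[up] <- x[up] + 1L
    eff <- x / n
    down <- eff > hi & (x - 1L) / n >= lo & x > 0L
    x[down] <- x[down] - 1L
  }
  cell_counts(sprintf("cell_%d", seq_len(J)), x, n)
}

# internal: counts for a config using the rates' own region bounds
counts_for_config <- function(rates, config) {
  counts_from_rates(rates, config$coverage, regions = config$regions)
}

#' Aggregate a bulk sample for a scenario
#'
#' Emulates the bulk experiment as a draw of many individual transcript
#' copies from a large population: `bulk_population` per-cell rates are
#' drawn from the same regions, averaged into the population mean rate,
#' and the bulk edited-read count is a binomial draw of `bulk_reads` at
#' that mean. A `bulk_mean` override in the config substitutes the stated
#' mean for the aggregated one. Seeds from `config$seed`.
#'
#' @param config a [scenario_config()].
#' @return A [bulk_counts()] object.
#' @export
make_bulk <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  make_bulk_unseeded(config)
}

make_bulk_unseeded <- function(config) {
  m <- if (!is.null(config$bulk_mean)) {
    config$bulk_mean
  } else {
    mean(draw_rates(config, config$bulk_population))
  }
  bulk_counts(rbinom(1L, config$bulk_reads, m), config$bulk_reads)
}

#' Generate a full artificial site data set from a scenario
#'
#' Seeds once from `config$seed`, draws the `J` cell rates, realizes their
#' read counts, aggregates the bulk pair, and wraps everything as a
#' [site_dataset()] (at a placeholder coordinate `sim:1`).
#'
#' @param config a [scenario_config()].
#' @return A [site_dataset()] with attribute `true_rates`, the latent
#'   per-cell rates the counts were generated from.
#' @export
#' @examples
#' simulate_scenario(preset_scenarios(seed = 7)[["low-var"]])
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  rates <- draw_rates(config, config$J)
  cells <- counts_for_config(rates, config)
  bulk <- make_bulk_unseeded(config)
  out <- site_dataset("sim", 1L, "+", cells, bulk)
  attr(out, "true_rates") <- as.numeric(rates)
  out
}

#' Catalogue of preset simulation scenarios
#'
#' Named [scenario_config()]s covering the validation scenarios:
#' \describe{
#'   \item{high-var}{rates in 0--5\% and 95--100\%, J = 20, coverage 20:
#'     maximal cell-to-cell variance.}
#'   \item{low-var}{rates in 45--55\%, J = 20, coverage 20: essentially no
#'     variance around a 50\% bulk mean.}
#'   \item{cov100, cov50, cov20, cov10}{the high-variance regions at J = 20
#'     with per-cell coverage 100, 50, 20, 10 (coverage sweep).}
#'   \item{cells50, cells20, cells10, cells5}{the high-variance regions at
#'     coverage 20 with J = 50, 20, 10, 5 (cell-number sweep).}
#'   \item{phys-low}{rates uniform over 0--20\% (bulk mean 10\%).}
#'   \item{phys-mid}{rates uniform over 20--50\% (bulk mean 35\%).}
#'   \item{phys-bimodal-near}{rates from 5--15\% and 40--50\% with the bulk
#'     mean fixed inside the lower region (10\%).}
#'   \item{phys-bimodal-between}{same regions with the bulk mean fixed
#'     between them (35\%).}
#' }
#'
#' @param seed seed stored in every preset.
#' @return Named list of `scenario_config` objects.
#' @export
preset_scenarios <- function(seed = 1L) {
  hivar <- list(c(0, 0.05), c(0.95, 1))
  bim <- list(c(0.05, 0.15), c(0.40, 0.50))
  cfg <- function(...) scenario_config(..., seed = seed)
  out <- list(
    "high-var" = cfg(J = 20, coverage = 20, regions = hivar),
    "low-var"  = cfg(J = 20, coverage = 20, regions = list(c(0.45, 0.55))),
    "cov100"   = cfg(J = 20, coverage = 100, regions = hivar),
    "cov50"    = cfg(J = 20, coverage = 50, regions = hivar),
    "cov20"    = cfg(J = 20, coverage = 20, regions = hivar),
    "cov10"    = cfg(J = 20, coverage = 10, regions = hivar),
    "cells50"  = cfg(J = 50, coverage = 20, regions = hivar),
    "cells20"  = cfg(J = 20, coverage = 20, regions = hivar),
    "cells10"  = cfg(J = 10, coverage = 20, regions = hivar),
    "cells5"   = cfg(J = 5, coverage = 20, regions = hivar),
    "phys-low" = cfg(J = 20, coverage = 20, regions = list(c(0, 0.20))),
    "phys-mid" = cfg(J = 20, coverage = 20, regions = list(c(0.20, 0.50))),
    "phys-bimodal-near" = cfg(J = 20, coverage = 20, regions = bim,
                              bulk_mean = 0.10),
    "phys-bimodal-between" = cfg(J = 20, coverage = 20, regions = bim,
                                 bulk_mean = 0.35)
  )
  out
}
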