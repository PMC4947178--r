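#' Highest-posterior-density interval from MCMC draws
#'
#' Shortest contiguous interval containing at least `mass` of the draws:
#' the draws are sorted and a sliding window of `ceiling(mass * N)` draws
#' is scanned for minimum width. For unimodal posteriors this is the HPD
#' credible interval.
#'
#' @param draws numeric vector of posterior draws (at least 1).
#' @param mass target probability mass in (0, 1) (default 0.95).
#'
#' @return An object of class `hpd_interval`: list with `lo`, `hi`, `mass`.
#' @export
#' @examples
#' hpd_interval(rbeta(1e4, 2, 5))
hpd_interval <- function(draws, mass = 0.95) {
  if (length(draws) == 0L) stop("cannot compute an HPD interval of no draws")
  if (!is.finite(mass) || mass <= 0 || mass >= 1) {
    stop("mass must lie in (0, 1)")
  }
  s <- sort(draws)
  N <- length(s)
  n_keep <- ceiling(mass * N)
  if (n_keep >= N) {
    out <- list(lo = s[1L], hi = s[N], mass = mass)
  } else {
    i <- seq_len(N - n_keep + 1L)
    w <- s[i + n_keep - 1L] - s[i]
    j <- which.min(w)
    out <- list(lo = s[j], hi = s[j + n_keep - 1L], mass = mass)
  }
  structure(out, class = "hpd_interval")
}

#' @export
print.hpd_interval <- function(x, ...) {
  cat(sprintf("%.0f%% HPD interval: [%.6g, %.6g]\n", 100 * x$mass, x$lo, x$hi))
  invisible(x)
}

#' Does the variance HPD interval exclude zero?
#'
#' Sample-based intervals never literally contain 0, so "v = 0 is not in
#' the interval" is operationalized as the lower bound clearing a small
#' threshold `delta`.
#'
#' @param interval an [hpd_interval()] over the variance.
#' @param delta exclusion threshold on the variance scale (default 1e-3).
#' @return `TRUE` iff `interval$lo > delta`.
#' @export
excludes_zero <- function(interval, delta = 1e-3) {
  if (!inherits(interval, "hpd_interval")) stop("need an hpd_interval")
  interval$lo > delta
}

#' Posterior-predictive marginal editing-rate draws
#'
#' For each retained variance draw, one new rate is drawn from the beta
#' layer `Beta(mean = p_hat, variance = v)`: the predicted editing rate of
#' an unobserved cell from the same population. The histogram of these
#' draws is the marginal editing-rate distribution among cells.
#'
#' @param post a [run_sampler()] result.
#' @return Numeric vector of rates in \[0, 1\], one per variance draw.
#' @export
marginal_rate_draws <- function(post) {
  if (!inherits(post, "posterior_samples") || length(post$v) == 0L) {
    stop("post must be a nonempty posterior_samples object")
  }
  v <- post$v
  m <- post$p_hat
  s <- m * (1 - m) / v - 1
  out <- rbeta(length(v), m * s, (1 - m) * s)
  out[v < 1e-12 | s <= 0] <- m
  out
}

#' Beta-kernel density estimate on the unit interval
#'
#' Density estimation for rates with support exactly \[0, 1\]: each draw
#' `d_i` contributes a beta kernel `Beta(d_i/b + 1, (1 - d_i)/b + 1)` whose
#' mean is (up to O(b)) centred on the draw, so no mass leaks outside the
#' support and the boundary bias of a symmetric kernel is avoided.
#'
#' @param draws rates in \[0, 1\] (nonempty).
#' @param grid evaluation points in \[0, 1\] (default 512 equispaced).
#' @param bandwidth smoothing parameter `b`; default
#'   `max(1e-3, sd(draws) * N^(-2/5))`.
#'
#' @return An object of class `beta_kd`: list with `x` (grid), `y`
#'   (density values) and `bandwidth`.
#' @export
#' @examples
#' kd <- beta_kernel_density(rbeta(5000, 2, 2))
#' kd$x[which.max(kd$y)]  # near 0.5
beta_kernel_density <- function(draws,
                                grid = seq(0, 1, length.out = 512L),
                                bandwidth = NULL) {
  if (length(draws) == 0L) stop("no draws to estimate a density from")
  if (any(!is.finite(draws)) || any(draws < 0 | draws > 1)) {
    stop("draws must lie in [0, 1]")
  }
  if (is.null(bandwidth)) {
    s <- sd(draws)
    bandwidth <- max(1e-3, if (is.finite(s)) s * length(draws)^(-2 / 5) else 0)
  }
  a <- draws / bandwidth + 1
  b <- (1 - draws) / bandwidth + 1
  y <- vapply(grid, function(g) mean(dbeta(g, a, b)), numeric(1))
  structure(list(x = grid, y = y, bandwidth = bandwidth), class = "beta_kd")
}

#' Mode of a bounded sample via the beta-kernel density
#'
#' Rescales draws from `[0, upper]` to the unit interval, runs
#' [beta_kernel_density()] on a 512-point grid and returns the grid maximum
#' mapped back. Used for posterior modes of the variance and of per-cell
#' rates.
#'
#' @param draws numeric draws in `[0, upper]`.
#' @param upper support upper bound (default 1).
#' @return The mode estimate.
#' @export
density_mode <- function(draws, upper = 1) {
  if (upper <= 0) stop("upper must be positive")
  kd <- beta_kernel_density(pmin(pmax(draws / upper, 0), 1))
  kd$x[which.max(kd$y)] * upper
}
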