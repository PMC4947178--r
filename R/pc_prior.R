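#' Kullback-Leibler divergence of the flexible model from the base model
#'
#' KL divergence between the beta-binomial marginal with variance `v` and
#' the binomial base model (`v = 0`), both at mean rate `p` and a reference
#' read depth `n_ref`, computed as the exact finite sum over `x = 0..n_ref`.
#' The divergence is taken at the marginal (observable) level because at the
#' latent level the beta-vs-point-mass divergence is infinite for any
#' `v > 0`.
#'
#' At the upper boundary `v = p(1-p)` the beta layer degenerates to the
#' two-point mixture at rates 0 and 1, so the marginal puts mass `1 - p` on
#' `x = 0` and `p` on `x = n_ref`; the closed form for that case is used.
#'
#' @param v variance in `[0, p(1-p)]`.
#' @param p mean editing rate in (0, 1).
#' @param n_ref reference coverage (reads, >= 1).
#'
#' @return KL divergence in nats (>= 0). Vectorized over `v`.
#' @export
#' @examples
#' kl_editing_variance(0, p = 0.5, n_ref = 20)     # 0
#' kl_editing_variance(0.25, p = 0.5, n_ref = 20)  # 19 * log(2)
kl_editing_variance <- function(v, p, n_ref) {
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  n_ref <- as.integer(n_ref)
  if (is.na(n_ref) || n_ref < 1L) stop("n_ref must be an integer >= 1")
  vmax <- p * (1 - p)
  if (any(!is.finite(v)) || any(v < 0) || any(v > vmax + 1e-15)) {
    stop(sprintf("v must lie in [0, p(1-p) = %g]", vmax))
  }
  xs <- 0:n_ref
  lb <- dbinom(xs, n_ref, p, log = TRUE)
  one <- function(vv) {
    if (vv == 0) return(0)
    if (vv >= vmax) {
      # two-point mixture (1-p) at x = 0, p at x = n_ref
      return((1 - p) * (log(1 - p) - lb[1L]) + p * (log(p) - lb[n_ref + 1L]))
    }
    lq <- dbetabinom(xs, n_ref, p, vv, log = TRUE)
    # the sum can cancel to a tiny negative for v near 0; KL is >= 0
    max(sum(exp(lq) * (lq - lb)), 0)
  }
  vapply(v, one, numeric(1))
}

#' Complexity distance to the no-variability base model
#'
#' The penalized-complexity construction measures model complexity by
#' `d(v) = sqrt(2 KL(v))`, the unidirectional distance from the flexible
#' beta-binomial model to the binomial base model. `d(0) = 0` and `d` is
#' nondecreasing in `v`.
#'
#' @inheritParams kl_editing_variance
#' @return Distance(s) `d(v)` (dimensionless, >= 0). Vectorized over `v`.
#' @export
pc_distance <- function(v, p, n_ref) {
  sqrt(2 * kl_editing_variance(v, p, n_ref))
}

#' Penalized-complexity prior on the editing-rate variance
#'
#' Constructs the prior on `v` obtained by placing an exponential
#' distribution with rate `lambda` on the complexity distance
#' `d(v) = sqrt(2 KL(v))` and calibrating `lambda` so that the prior mass
#' above a user threshold `v_L` equals `tail_alpha`
#' (`P[v > v_L] = tail_alpha`). Because `d` is bounded on the bounded
#' variance support `[0, p(1-p)]`, the exponential is truncated to
#' `[0, d(v_max)]` and renormalized; the calibration equation
#' `(exp(-lambda d_L) - exp(-lambda d_max)) / (1 - exp(-lambda d_max)) =
#' tail_alpha` is solved by 1-D root finding and reduces to
#' `lambda = -log(tail_alpha) / d(v_L)` when truncation is negligible.
#'
#' @param p bulk mean editing rate in (0, 1) (clamp degenerate estimates
#'   first, see [clamp_rate()]).
#' @param n_ref reference coverage used in the KL computation; the default
#'   20 reads per cell matches the recommended per-site single-cell depth.
#'   May be set per site, e.g. to the median observed coverage.
#' @param v_L calibration threshold on the variance scale; the default
#'   0.142 is the conservative little-variability prior used throughout.
#' @param tail_alpha prior tail mass above `v_L` (default 0.01).
#'
#' @return An object of class `pc_prior` with fields `p`, `n_ref`, `v_L`,
#'   `tail_alpha`, `v_max`, `d_L`, `d_max`, `lambda`.
#' @export
#' @examples
#' pr <- pc_prior(p = 0.5)
#' pr$lambda * pr$d_L  # close to -log(0.01) since truncation is mild
pc_prior <- function(p, n_ref = 20L, v_L = 0.142, tail_alpha = 0.01) {
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (tail_alpha <= 0 || tail_alpha >= 1) stop("tail_alpha must lie in (0, 1)")
  vmax <- p * (1 - p)
  if (!is.finite(v_L) || v_L <= 0 || v_L >= vmax) {
    stop(sprintf("v_L must lie strictly inside (0, v_max = %g)", vmax))
  }
  d_L <- pc_distance(v_L, p, n_ref)
  d_max <- pc_distance(vmax, p, n_ref)
  if (d_L <= 0) stop("d(v_L) = 0; cannot calibrate the prior")
  # tail mass above d_L under the truncated exponential, minus the target
  g <- function(lam) {
    (exp(-lam * d_L) - exp(-lam * d_max)) / (1 - exp(-lam * d_max)) - tail_alpha
  }
  # as lambda -> 0 the tail mass tends to 1 - d_L/d_max; a root needs that
  # limit to exceed tail_alpha (g is decreasing in lambda)
  if (1 - d_L / d_max <= tail_alpha) {
    stop(sprintf(paste0("calibration failure: even a flat prior on d puts ",
                        "mass <= %g above v_L (d_L = %g, d_max = %g)"),
                 tail_alpha, d_L, d_max))
  }
  lam0 <- -log(tail_alpha) / d_L  # untruncated solution
  hi <- lam0
  while (g(hi) > 0) hi <- hi * 2
  lo <- lam0
  while (g(lo) < 0) lo <- lo / 2
  lambda <- uniroot(g, c(lo, hi), tol = 1e-12)$root
  structure(list(p = p, n_ref = as.integer(n_ref), v_L = v_L,
                 tail_alpha = tail_alpha, v_max = vmax,
                 d_L = d_L, d_max = d_max, lambda = lambda),
            class = "pc_prior")
}

#' @export
print.pc_prior <- function(x, ...) {
  cat(sprintf(paste0("PC prior on editing-rate variance\n",
                     "  p = %.4g, n_ref = %d, v_max = %.4g\n",
                     "  v_L = %.4g, tail_alpha = %.3g -> lambda = %.4g\n"),
              x$p, x$n_ref, x$v_max, x$v_L, x$tail_alpha, x$lambda))
  invisible(x)
}

#' Density of the penalized-complexity prior on the variance scale
#'
#' The truncated exponential on the distance `d` induces, by change of
#' variables, `f(v) = lambda exp(-lambda d(v)) d'(v) / (1 - exp(-lambda
#' d_max))` on `(0, v_max)`. The derivative `d'(v)` has no closed form and
#' is computed by a central finite difference whose step shrinks near the
#' support boundaries.
#'
#' @param v variance value(s) in (0, v_max); values outside the open
#'   support return density 0.
#' @param prior a calibrated [pc_prior()] object.
#' @param log return the log density?
#'
#' @return Density values per unit variance.
#' @export
pc_prior_density <- function(v, prior, log = FALSE) {
  if (!inherits(prior, "pc_prior") || is.null(prior$lambda)) {
    stop("prior must be a calibrated pc_prior object")
  }
  vmax <- prior$v_max
  lam <- prior$lambda
  norm <- 1 - exp(-lam * prior$d_max)
  one <- function(vv) {
    if (!is.finite(vv) || vv <= 0 || vv >= vmax) return(-Inf)
    h <- min(1e-5, vv / 10, (vmax - vv) / 10)
    d0 <- pc_distance(vv, prior$p, prior$n_ref)
    dp <- (pc_distance(vv + h, prior$p, prior$n_ref) -
             pc_distance(vv - h, prior$p, prior$n_ref)) / (2 * h)
    log(lam) - lam * d0 + log(max(dp, 0)) - log(norm)
  }
  ld <- vapply(v, one, numeric(1))
  if (log) ld else exp(ld)
}
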