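#' Sampler settings for per-site posterior inference
#'
#' @param seed integer seed (required); identical seed and settings yield
#'   bitwise-identical draws.
#' @param iterations total MCMC iterations (default 20000).
#' @param burn_in iterations discarded from the start (default 5000).
#' @param thin keep every `thin`-th post-burn-in draw (default 1).
#' @param step_size initial random-walk standard deviation for the
#'   variance update on the logit-transformed scale.
#' @param adapt_window during burn-in the step size is rescaled every
#'   `adapt_window` iterations towards a 0.25--0.45 acceptance rate.
#' @param excludes_zero_delta threshold below which an HPD lower bound is
#'   treated as touching `v = 0` (see [excludes_zero()]).
#' @param fix_v optional: freeze the variance at this value (in
#'   `(0, v_max)`) and skip its update; used to isolate the conjugate
#'   per-cell updates.
#'
#' @return An object of class `sampler_settings`.
#' @export
sampler_settings <- function(seed, iterations = 20000L, burn_in = 5000L,
                             thin = 1L, step_size = 0.8, adapt_window = 50L,
                             excludes_zero_delta = 1e-3, fix_v = NULL) {
  if (missing(seed)) stop("seed is required")
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in < 0L || iterations <= burn_in) {
    stop("need iterations > burn_in >= 0")
  }
  if (thin < 1L) stop("thin must be >= 1")
  if (!is.null(fix_v) && (!is.finite(fix_v) || fix_v <= 0)) {
    stop("fix_v must be a positive variance")
  }
  structure(list(seed = as.integer(seed), iterations = iterations,
                 burn_in = burn_in, thin = thin, step_size = step_size,
                 adapt_window = as.integer(adapt_window),
                 excludes_zero_delta = excludes_zero_delta, fix_v = fix_v),
            class = "sampler_settings")
}

#' Posterior sampling of editing-rate variance and per-cell rates
#'
#' Metropolis-within-Gibbs sampler for one site. Conditional on the
#' variance `v`, each per-cell rate is conjugate and drawn exactly:
#' `p_j | v, x_j ~ Beta(alpha(v) + x_j, beta(v) + n_j - x_j)` where
#' `(alpha, beta)` are the shapes of the beta layer with mean fixed at the
#' bulk estimate and variance `v`. Conditional on the rates, `v` is updated
#' by Gaussian random-walk Metropolis on the transformed scale
#' `u = logit(v / v_max)` (respecting the bounded support), with the target
#' `prod_j Beta(p_j; p_hat, v) * prior(v)`; the step size adapts during
#' burn-in towards a 0.25--0.45 acceptance rate and is frozen afterwards.
#'
#' Cells with `n_j = 0` are retained: they contribute no binomial
#' likelihood, so their rate is drawn from the beta layer itself.
#'
#' @param data a [site_dataset()].
#' @param prior a [pc_prior()] calibrated at `p = bulk_mean(data$bulk)`
#'   (clamped); built automatically with default settings when `NULL`.
#' @param settings a [sampler_settings()] object.
#'
#' @return An object of class `posterior_samples`: list with `v` (variance
#'   draws), `p` (draws x J matrix of per-cell rates), `acceptance_rate`
#'   of the variance update, `p_hat`, `v_max`, `settings`, `site`.
#' @export
#' @examples
#' sc <- simulate_scenario(scenario_config(
#'   J = 10, coverage = 20, regions = list(c(0, 0.05), c(0.95, 1)), seed = 1))
#' post <- run_sampler(sc, settings = sampler_settings(
#'   seed = 2, iterations = 2000, burn_in = 500))
#' hpd_interval(post$v)
run_sampler <- function(data, prior = NULL, settings) {
  if (!inherits(data, "site_dataset")) stop("data must be a site_dataset")
  if (!inherits(settings, "sampler_settings")) {
    stop("settings must come from sampler_settings()")
  }
  x <- data$cells$x
  n <- data$cells$n
  J <- length(x)
  if (all(n == 0L)) stop("no cell has any mapped reads; nothing to infer")
  p_hat <- clamp_rate(bulk_mean(data$bulk), data$bulk$n)
  fixed <- !is.null(settings$fix_v)
  if (!fixed && is.null(prior)) prior <- pc_prior(p_hat)
  v_max <- if (fixed) p_hat * (1 - p_hat) else prior$v_max
  if (fixed && settings$fix_v >= v_max) stop("fix_v must be < p_hat(1-p_hat)")

  set.seed(settings$seed)
  n_keep <- (settings$iterations - settings$burn_in) %/% settings$thin
  v_draws <- numeric(n_keep)
  p_draws <- matrix(NA_real_, n_keep, J,
                    dimnames = list(NULL, data$cells$cell_id))

  v <- if (fixed) settings$fix_v else {
    emp <- if (sum(n > 0) > 1) var(x[n > 0] / n[n > 0]) else 0
    if (!is.finite(emp) || emp <= 0) emp <- 0.05 * v_max
    min(max(emp, 1e-3 * v_max), 0.95 * v_max)
  }
  lstep <- log(settings$step_size)
  n_acc <- 0L; n_prop <- 0L; win_acc <- 0L; win_n <- 0L
  kept <- 0L

  # log of the v-conditional target given current rates pj
  log_target <- function(vv, pj) {
    sh <- beta_shapes(p_hat, vv)
    sum(dbeta(pj, sh[[1L]], sh[[2L]], log = TRUE)) +
      pc_prior_density(vv, prior, log = TRUE)
  }

  for (it in seq_len(settings$iterations)) {
    sh <- beta_shapes(p_hat, v)
    pj <- rbeta(J, sh[[1L]] + x, sh[[2L]] + n - x)
    pj <- pmin(pmax(pj, 1e-12), 1 - 1e-12)

    if (!fixed) {
      u <- log(v / (v_max - v))
      u_new <- u + exp(lstep) * rnorm(1)
      v_new <- v_max * plogis(u_new)
      # include the log-Jacobian log v + log(v_max - v) of v -> u
      la <- (log_target(v_new, pj) + log(v_new) + log(v_max - v_new)) -
        (log_target(v, pj) + log(v) + log(v_max - v))
      n_prop <- n_prop + 1L; win_n <- win_n + 1L
      if (is.finite(la) && log(runif(1)) < la) {
        v <- v_new
        n_acc <- n_acc + 1L; win_acc <- win_acc + 1L
      }
      if (it <= settings$burn_in && win_n >= settings$adapt_window) {
        rate <- win_acc / win_n
        if (rate < 0.25 || rate > 0.45) {
          lstep <- min(max(lstep + (rate - 0.35), -8), 4)
        }
        win_acc <- 0L; win_n <- 0L
      }
    }

    if (it > settings$burn_in &&
        (it - settings$burn_in) %% settings$thin == 0L) {
      kept <- kept + 1L
      v_draws[kept] <- v
      p_draws[kept, ] <- pj
    }
  }

  structure(list(v = v_draws[seq_len(kept)],
                 p = p_draws[seq_len(kept), , drop = FALSE],
                 acceptance_rate = if (n_prop > 0L) n_acc / n_prop else NA_real_,
                 p_hat = p_hat, v_max = v_max,
                 settings = settings, prior = prior, site = data$site),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  hpd <- hpd_interval(x$v)
  cat(sprintf(paste0("posterior_samples: %d draws, J = %d cells\n",
                     "  p_hat = %.4g; E[v] = %.4g; 95%% HPD(v) = ",
                     "[%.4g, %.4g]; acc = %.2f\n"),
              length(x$v), ncol(x$p), x$p_hat, mean(x$v),
              hpd$lo, hpd$hi,
              x$acceptance_rate))
  invisible(x)
}
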