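# R-level wrappers for the three Gibbs samplers, posterior summaries and
# autocorrelation diagnostics.  The sweep kernels live in src/samplers.cpp.

new_posterior_draws <- function(m, latent, model, lib, prior, config, clamps) {
  colnames(m) <- lib$gene_id
  structure(
    list(m = m, latent = latent, model = model, gene_id = lib$gene_id,
         prior = prior, config = config, clamps = clamps),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws (", toupper(x$model), "): ", nrow(x$m),
      " kept sweeps x ", ncol(x$m), " genes\n", sep = "")
  if (x$clamps > 0) cat("  clamped zero draws:", x$clamps, "\n")
  invisible(x)
}

init_m <- function(lib, alpha) {
  # corrected MLE with alpha-proportional mass substituted at zero counts
  w <- lib$t / lib$phi + alpha
  w / sum(w)
}

#' Dirichlet-Poisson-Binomial (DPB) Gibbs sampler
#'
#' Hierarchy: `t_i ~ Binomial(g_i, phi_i)`, `g_i ~ Poisson(N m_i)`,
#' `m ~ Dirichlet(alpha)`, `N ~ ceiling(Gamma(gamma_shape, gamma_scale))`.
#' Each sweep draws the latent pre-tagging counts
#' `g_i <- t_i + Poisson(N m_i (1 - phi_i))`, then `m <- Dirichlet(alpha + g)`,
#' then `N` from its Gamma conditional (shape `gamma_shape + sum(g)`, rate
#' `1/gamma_scale + 1`), taking the ceiling.  Returns thinned post-burn-in
#' draws of `m` and `N`.
#'
#' @param lib A [tag_library()].
#' @param prior A [prior_spec()].
#' @param config A [chain_config()].
#' @param keep_g Also retain the latent `g` draws (memory: kept x genes).
#' @return A `posterior_draws` object; `$latent$N` holds the population-size
#'   chain.
#' @export
run_dpb <- function(lib, prior = prior_spec(), config = chain_config(),
                    keep_g = FALSE) {
  stopifnot(inherits(lib, "tag_library"), inherits(prior, "prior_spec"),
            inherits(config, "chain_config"))
  alpha <- resolve_alpha(prior, lib$l)
  m0 <- init_m(lib, alpha)
  n0 <- ceiling(sum(lib$t / lib$phi))
  res <- dpb_gibbs_cpp(lib$t, lib$phi, alpha,
                       prior$gamma_shape, prior$gamma_scale,
                       config$n_iterations, config$burn_in, config$thin,
                       config$seed, m0, n0, keep_g)
  latent <- list(N = res$N)
  if (keep_g) latent$g <- res$g
  new_posterior_draws(res$m, latent, "dpb", lib, prior, config, res$clamps)
}

#' Dirichlet-Multinomial-Binomial (DMB) Gibbs sampler
#'
#' Hierarchy: `N ~ Poisson(lambda)`, `g | N ~ Multinomial(N, m)`,
#' `t_i ~ Binomial(g_i, phi_i)`, `m ~ Dirichlet(alpha)`.  Each sweep draws
#' the unconverted counts `u_i <- Poisson(lambda m_i (1 - phi_i))`, sets
#' `g = t + u` and draws `m <- Dirichlet(alpha + g)`.  By default `lambda`
#' is held fixed at `prior$lambda` (or `gamma_shape * gamma_scale` when
#' unset); with `prior$lambda_update = TRUE` it is resampled from its
#' Gamma conditional each sweep.  The observed data carry no information
#' about the population size in this model, so no `N` chain is returned.
#'
#' @inheritParams run_dpb
#' @param keep_u Also retain the per-gene unconverted-count draws.
#' @return A `posterior_draws` object; `$latent$lambda` and
#'   `$latent$u_total` hold the kept population-size values and total
#'   unconverted counts.
#' @export
run_dmb <- function(lib, prior = prior_spec(), config = chain_config(),
                    keep_u = FALSE) {
  stopifnot(inherits(lib, "tag_library"), inherits(prior, "prior_spec"),
            inherits(config, "chain_config"))
  alpha <- resolve_alpha(prior, lib$l)
  m0 <- init_m(lib, alpha)
  lambda0 <- if (is.null(prior$lambda)) {
    prior$gamma_shape * prior$gamma_scale
  } else {
    prior$lambda
  }
  res <- dmb_gibbs_cpp(lib$t, lib$phi, alpha, lambda0, prior$lambda_update,
                       prior$gamma_shape, prior$gamma_scale,
                       config$n_iterations, config$burn_in, config$thin,
                       config$seed, m0, keep_u)
  latent <- list(lambda = res$lambda, u_total = res$u_total)
  if (keep_u) latent$u <- res$u
  new_posterior_draws(res$m, latent, "dmb", lib, prior, config, res$clamps)
}

#' Missing-data (MD) Gibbs sampler
#'
#' Augments the observed counts with an unobserved category counting the
#' transcripts that were never converted to tags.  Each sweep draws the
#' augmented vector `(q, q0) ~ Dirichlet(t + alpha, r + 1)` over `l + 1`
#' categories, then `r ~ Poisson(mu q0)`.  The augmented coordinates live
#' on the tag-pool scale (`q_i` tracks `m_i phi_i`-type mass), so the kept
#' mRNA-proportion draws are the bias-corrected projection
#' `m_i = (q_i / phi_i) / sum_j (q_j / phi_j)`.  The raw augmented draws
#' are retained in `$latent$q` alongside `r` and `m0 = q0`.
#'
#' `mu` defaults to `t_tot * sum(m (1 - phi)) / sum(m phi)` with `m` the
#' corrected MLE — the expected number of unconverted transcripts implied
#' by the observed library.
#'
#' @inheritParams run_dpb
#' @return A `posterior_draws` object; `$latent$r`, `$latent$m0` and
#'   `$latent$q` hold the unconverted-count chain, the augmented-category
#'   proportion and the raw augmented draws.
#' @export
run_md <- function(lib, prior = prior_spec(), config = chain_config()) {
  stopifnot(inherits(lib, "tag_library"), inherits(prior, "prior_spec"),
            inherits(config, "chain_config"))
  alpha <- resolve_alpha(prior, lib$l)
  mu <- prior$mu
  if (is.null(mu)) {
    if (lib$t_tot > 0) {
      mhat <- corrected_mle(lib)
      smphi <- sum(mhat * lib$phi)
      mu <- lib$t_tot * (1 - smphi) / smphi
    } else {
      mu <- 0
    }
  }
  res <- md_gibbs_cpp(lib$t, alpha, mu,
                      config$n_iterations, config$burn_in, config$thin,
                      config$seed, floor(mu))
  q <- res$q
  l <- lib$l
  corrected <- sweep(q[, seq_len(l), drop = FALSE], 2, lib$phi, "/")
  corrected <- corrected / rowSums(corrected)
  latent <- list(r = res$r, m0 = q[, l + 1],
                 q = q[, seq_len(l), drop = FALSE])
  colnames(latent$q) <- lib$gene_id
  draws <- new_posterior_draws(corrected, latent, "md", lib, prior, config,
                               res$clamps)
  draws$mu <- mu
  draws
}

#' Posterior summaries with equal-tail credible intervals
#'
#' @param draws A `posterior_draws` object (or a plain kept-by-genes
#'   matrix).
#' @param level Credible level in (0, 1); default 0.95.
#' @return Data frame with one row per gene: `gene_id`, `mean`, `median`,
#'   `lower`, `upper`.
#' @export
summarize_draws <- function(draws, level = 0.95) {
  if (length(level) != 1 || is.na(level) || level <= 0 || level >= 1) {
    stop("'level' must be in (0, 1)")
  }
  m <- if (inherits(draws, "posterior_draws")) draws$m else as.matrix(draws)
  if (nrow(m) < 2) stop("need at least 2 kept draws to summarise")
  probs <- c((1 - level) / 2, 0.5, (1 + level) / 2)
  qs <- apply(m, 2, quantile, probs = probs, names = FALSE, type = 7)
  data.frame(
    gene_id = colnames(m) %||% paste0("g", seq_len(ncol(m))),
    mean = colMeans(m),
    median = qs[2, ],
    lower = qs[1, ],
    upper = qs[3, ],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' @export
summary.posterior_draws <- function(object, level = 0.95, ...) {
  summarize_draws(object, level = level)
}

#' Sample autocorrelation of a scalar chain at chosen lags
#'
#' @param chain Numeric vector of draws (non-constant, longer than the
#'   largest lag + 1).
#' @param lags Nonnegative integer lags (lag 0 returns 1).
#' @return Named numeric vector of autocorrelations.
#' @examples
#' autocorrelation(rnorm(500), lags = c(0, 10))
#' @export
autocorrelation <- function(chain, lags = c(10, 20, 40, 80)) {
  if (any(lags < 0) || any(lags != floor(lags))) {
    stop("'lags' must be nonnegative integers")
  }
  if (length(chain) <= max(lags) + 1) {
    stop("chain is too short for the requested lags")
  }
  if (stats::sd(chain) == 0) {
    stop("autocorrelation is undefined for a constant chain")
  }
  a <- acf(chain, lag.max = max(lags), plot = FALSE, demean = TRUE)
  setNames(a$acf[lags + 1], lags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
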