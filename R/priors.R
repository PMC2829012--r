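# Prior and chain configuration containers shared by the three samplers.

#' Prior specification for the hierarchical samplers
#'
#' The Dirichlet parameter accepts the two named presets used throughout:
#' `"flat"` (`alpha_i = 1`, uniform over the simplex) and `"tub"`
#' (`alpha_i = 1/l`, mass concentrated at the simplex boundary), or an
#' explicit positive vector.  `gamma_shape` and `gamma_scale` parameterise
#' the Gamma prior on the DPB population size `N` (and the optional DMB
#' hyperprior on `lambda`); the defaults 100 and 200 give prior mean 20,000.
#' `lambda` is the DMB population-size mean (default `gamma_shape *
#' gamma_scale` when fixed); `mu` is the MD model's Poisson mean for the
#' unconverted count (default: plug the corrected MLE into
#' `t_tot * sum(m (1 - phi)) / sum(m phi)`, computed once before sampling).
#'
#' @param alpha `"flat"`, `"tub"`, or a positive numeric vector.
#' @param gamma_shape,gamma_scale Gamma prior shape/scale for the
#'   population size; both > 0.
#' @param lambda DMB population-size mean; `NULL` means
#'   `gamma_shape * gamma_scale`.
#' @param lambda_update If `TRUE`, DMB resamples lambda from its
#'   Gamma conditional each sweep instead of holding it fixed.
#' @param mu MD Poisson mean for the unconverted count; `NULL` means the
#'   corrected-MLE plug-in above.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(alpha = "flat", gamma_shape = 100, gamma_scale = 200,
                       lambda = NULL, lambda_update = FALSE, mu = NULL) {
  if (is.character(alpha)) {
    alpha <- match.arg(alpha, c("flat", "tub"))
  } else {
    if (anyNA(alpha) || any(alpha <= 0)) stop("all alpha_i must be > 0")
  }
  if (gamma_shape <= 0 || gamma_scale <= 0) stop("gamma parameters must be > 0")
  if (!is.null(lambda) && lambda <= 0) stop("'lambda' must be > 0")
  if (!is.null(mu) && mu < 0) stop("'mu' must be >= 0")
  structure(
    list(alpha = alpha, gamma_shape = gamma_shape, gamma_scale = gamma_scale,
         lambda = lambda, lambda_update = lambda_update, mu = mu),
    class = "prior_spec"
  )
}

resolve_alpha <- function(prior, l) {
  a <- prior$alpha
  if (is.character(a)) {
    a <- switch(a, flat = rep(1, l), tub = rep(1 / l, l))
  } else {
    a <- rep_len(a, l)
  }
  a
}

#' Gibbs chain configuration
#'
#' Defaults follow the simulation protocol: 20,500 sweeps, the first 500
#' discarded, every 20th kept thereafter (1,000 kept draws).
#'
#' @param n_iterations Total sweeps.
#' @param burn_in Discarded initial sweeps (< `n_iterations`).
#' @param thin Keep-every interval (>= 1).
#' @param seed Integer seed for the sampler's RNG stream.
#' @return A `chain_config` object.
#' @export
chain_config <- function(n_iterations = 20500, burn_in = 500, thin = 20,
                         seed = 1L) {
  if (burn_in >= n_iterations) stop("'burn_in' must be < 'n_iterations'")
  if (thin < 1) stop("'thin' must be >= 1")
  if ((n_iterations - burn_in) < thin) stop("no draws would be kept")
  structure(
    list(n_iterations = as.integer(n_iterations),
         burn_in = as.integer(burn_in),
         thin = as.integer(thin),
         seed = as.integer(seed)),
    class = "chain_config"
  )
}
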