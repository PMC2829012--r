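# Deterministic estimators and densities: observed proportions, the bias
# map between mRNA proportions m and tag-pool proportions theta, the
# bias-corrected MLE, the (unnormalised) log posterior, and the missing-data
# model's closed-form mode and Poisson-marginalised mean.

#' Observed tag proportions
#'
#' @param lib A [tag_library()].
#' @return Numeric vector `t_i / t_tot`.
#' @export
observed_proportions <- function(lib) {
  stopifnot(inherits(lib, "tag_library"))
  if (lib$t_tot <= 0) stop("library has no tags (all counts zero)")
  lib$t / lib$t_tot
}

#' Map true mRNA proportions to biased tag-pool proportions
#'
#' Tag counts sample the tag pool, not the mRNA pool: a gene's tag-pool
#' frequency is its mRNA proportion weighted by its tag formation
#' probability, `theta_i = m_i phi_i / sum_j m_j phi_j`.
#'
#' @param m Proportion vector (nonnegative, sums to 1).
#' @param phi Tag formation probabilities in (0, 1], same length.
#' @return The biased proportion vector theta (sums to 1).
#' @examples
#' biased_from_true(c(1 / 3, 2 / 3), c(1, 0.5))  # -> c(0.5, 0.5)
#' @export
biased_from_true <- function(m, phi) {
  check_proportions(m)
  if (length(phi) != length(m)) stop("m and phi must have equal length")
  w <- m * phi
  s <- sum(w)
  if (s <= 0) stop("sum(m * phi) is zero: no observable mass")
  w / s
}

#' Bias-corrected maximum likelihood estimate of mRNA proportions
#'
#' The corrected MLE is the proportion vector whose biased image equals the
#' observed tag proportions; in closed form `m_i` is proportional to
#' `t_i / phi_i`, normalised to sum to one.  Zero-count genes get exactly 0.
#'
#' @param lib A [tag_library()].
#' @return The corrected MLE proportion vector.
#' @examples
#' corrected_mle(tag_library(c("a", "b"), c(10, 10), c(1, 0.5)))  # (1/3, 2/3)
#' @export
corrected_mle <- function(lib) {
  stopifnot(inherits(lib, "tag_library"))
  if (lib$t_tot <= 0) stop("library has no tags (all counts zero)")
  w <- lib$t / lib$phi
  w / sum(w)
}

#' Unnormalised log posterior of the bias-corrected multinomial model
#'
#' Up to an additive constant:
#' `sum_i [t_i log(m_i phi_i) + (alpha_i - 1) log m_i]
#'  - t_tot log(sum_j m_j phi_j)`.
#' Boundary coordinates return `-Inf` (or `+Inf` where the Dirichlet
#' exponent is negative, as for the tub prior at a zero-count gene), never
#' an error.
#'
#' @param m Proportion vector.
#' @param lib A [tag_library()].
#' @param alpha Dirichlet prior parameters (scalar recycled, or vector).
#' @return Scalar log density (possibly infinite).
#' @export
log_posterior <- function(m, lib, alpha = 1) {
  stopifnot(inherits(lib, "tag_library"))
  check_proportions(m)
  if (length(m) != lib$l) stop("m must have one coordinate per gene")
  alpha <- rep_len(alpha, lib$l)
  # combined exponent on m_i is t_i + alpha_i - 1; phi enters through
  # t_i log(phi_i) and the normaliser
  e <- lib$t + alpha - 1
  lm <- ifelse(m > 0, log(m), 0)
  terms <- ifelse(
    m > 0,
    e * lm,
    ifelse(e > 0, -Inf, ifelse(e == 0, 0, Inf))
  )
  sum(terms) + sum(lib$t * log(lib$phi)) -
    lib$t_tot * log(sum(m * lib$phi))
}

#' Posterior mode of the missing-data model's augmented Dirichlet
#'
#' Given the unconverted count `r`, the augmented Dirichlet conditional has
#' mode `(t_i + alpha_i - 1) / (sum_j (alpha_j + t_j) + r - l)` in its first
#' `l` coordinates.  When some `alpha_i < 1` with `t_i = 0` the mode leaves
#' the parameter space and an error is raised.
#'
#' @param t Nonnegative integer counts.
#' @param alpha Dirichlet parameters (scalar recycled, or vector).
#' @param r Unconverted transcript count (>= 0).
#' @return The mode vector over the `l` gene coordinates.
#' @examples
#' md_posterior_mode(c(3, 1), c(1, 1), r = 4)  # (3/8, 1/8)
#' @export
md_posterior_mode <- function(t, alpha, r) {
  if (any(t < 0) || any(t != floor(t))) stop("counts must be nonnegative integers")
  if (r < 0) stop("'r' must be >= 0")
  l <- length(t)
  alpha <- rep_len(alpha, l)
  if (any(alpha + t < 1)) {
    stop("alpha_i + t_i < 1 for some gene: ",
         "the mode lies outside the parameter space ",
         "(sub-unit Dirichlet weight with a zero count)")
  }
  (t + alpha - 1) / (sum(alpha + t) + r - l)
}

#' Marginal posterior means of the missing-data model
#'
#' Marginalises the augmented-Dirichlet conditional mean
#' `E[m_i | r] = (t_i + alpha_i) / (sum_j (t_j + alpha_j) + r + 1)` over
#' `r ~ Poisson(mu)`, exhausting the Poisson mass numerically to within
#' `tol` of 1.  These are expectations of the augmented coordinates
#' (tag-pool scale); see the methods vignette for how they relate to the
#' Gibbs sampler's output.
#'
#' @param t Nonnegative integer counts.
#' @param alpha Dirichlet parameters (scalar recycled, or vector).
#' @param mu Poisson mean for the unconverted count (>= 0).
#' @param tol Unexhausted Poisson tail mass allowed (default 1e-12).
#' @return Vector of marginal expectations, one per gene.
#' @export
md_marginal_mean <- function(t, alpha, mu, tol = 1e-12) {
  if (mu < 0) stop("'mu' must be >= 0")
  l <- length(t)
  alpha <- rep_len(alpha, l)
  s <- sum(t + alpha)
  if (mu == 0) return((t + alpha) / (s + 1))
  # accumulate Poisson mass term by term (recursive weights, no dpois calls
  # in the loop); stop once the remaining tail is below tol
  w <- exp(-mu)
  acc_mass <- w
  acc <- w / (s + 1)
  r <- 0
  while (1 - acc_mass > tol) {
    r <- r + 1
    w <- w * mu / r
    acc_mass <- acc_mass + w
    acc <- acc + w / (s + r + 1)
    if (r > mu + 40 * sqrt(mu) + 1e4) break
  }
  (t + alpha) * acc
}

check_proportions <- function(m, tol = 1e-9) {
  if (anyNA(m) || any(m < 0)) stop("proportions must be nonnegative")
  if (abs(sum(m) - 1) > tol) {
    stop("proportions must sum to 1 (|sum - 1| <= ", tol, ")")
  }
  invisible(m)
}
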