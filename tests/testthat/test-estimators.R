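test_that("observed proportions are counts over the total", {
  lib <- tag_library(c("a", "b", "c"), c(1, 1, 2), c(1, 1, 1))
  expect_equal(observed_proportions(lib), c(0.25, 0.25, 0.5))
  expect_equal(sum(observed_proportions(toy_lib())), 1)
  zero <- tag_library(c("a", "b"), c(0, 0), c(0.5, 0.5))
  expect_error(observed_proportions(zero), "no tags")
})

test_that("the bias map reweights by phi and renormalises", {
  m <- c(1 / 3, 2 / 3)
  expect_equal(biased_from_true(m, c(1, 0.5)), c(0.5, 0.5))
  # uniform phi cancels
  m3 <- c(0.2, 0.3, 0.5)
  expect_equal(biased_from_true(m3, c(0.7, 0.7, 0.7)), m3)
  set.seed(4)
  for (i in 1:20) {
    mm <- runif(5)
    mm <- mm / sum(mm)
    phi <- runif(5, 0.1, 1)
    expect_equal(sum(biased_from_true(mm, phi)), 1, tolerance = 1e-12)
  }
  expect_error(biased_from_true(c(0.5, 0.6), c(1, 1)), "sum to 1")
})

test_that("corrected MLE inverts the bias map", {
  lib <- tag_library(c("a", "b"), c(10, 10), c(1, 0.5))
  expect_equal(corrected_mle(lib), c(1 / 3, 2 / 3))
  # constant phi recovers the unadjusted MLE
  lib2 <- tag_library(c("a", "b", "c"), c(6, 3, 1), c(0.8, 0.8, 0.8))
  expect_equal(corrected_mle(lib2), c(0.6, 0.3, 0.1))
  # round trip: the biased image of the corrected MLE is the observed
  # proportion vector, for arbitrary libraries
  set.seed(7)
  for (i in 1:25) {
    l <- sample(2:8, 1)
    lib3 <- tag_library(paste0("g", 1:l), rpois(l, 5), runif(l, 0.05, 1))
    if (lib3$t_tot == 0) next
    resid <- biased_from_true(corrected_mle(lib3), lib3$phi) -
      observed_proportions(lib3)
    expect_lt(max(abs(resid)), 1e-12)
  }
})

test_that("corrected MLE is invariant to rescaling phi by a constant", {
  lib <- toy_lib()
  scaled <- tag_library(lib$gene_id, lib$t, lib$phi * 0.31)
  expect_equal(corrected_mle(scaled), corrected_mle(lib), tolerance = 1e-14)
})

test_that("log posterior decomposes into corrected likelihood plus prior", {
  lib <- toy_lib()
  alpha <- c(2, 1, 0.5)
  set.seed(12)
  for (i in 1:10) {
    m <- runif(3, 0.05, 1)
    m <- m / sum(m)
    # independent brute-force product: multinomial-with-bias x Dirichlet
    theta <- (m * lib$phi) / sum(m * lib$phi)
    brute <- sum(lib$t * log(theta)) + sum((alpha - 1) * log(m))
    expect_equal(log_posterior(m, lib, alpha), brute, tolerance = 1e-10)
  }
})

test_that("flat-prior log posterior peaks at the corrected MLE", {
  lib <- tag_library(c("a", "b"), c(10, 10), c(1, 0.5))
  grid <- seq(0.001, 0.999, by = 0.001)
  lp <- vapply(grid, function(m1) log_posterior(c(m1, 1 - m1), lib, 1),
               numeric(1))
  expect_equal(grid[which.max(lp)], corrected_mle(lib)[1], tolerance = 2e-3)
  # with uniform phi and flat prior the peak is the plain MLE t/t_tot
  lib2 <- tag_library(c("a", "b"), c(30, 10), c(0.6, 0.6))
  lp2 <- vapply(grid, function(m1) log_posterior(c(m1, 1 - m1), lib2, 1),
                numeric(1))
  expect_equal(grid[which.max(lp2)], 0.75, tolerance = 2e-3)
})

test_that("log posterior handles simplex boundaries by sign of the exponent", {
  lib <- toy_lib()  # t = (5, 2, 0)
  # zero coordinate with positive exponent (t
  expect_identical(log_posterior(c(0, 0.6, 0.4), lib, 1), -Inf)
  # zero count, flat prior: exponent 0, finite value
  expect_true(is.finite(log_posterior(c(0.7, 0.3, 0), lib, 1)))
  # zero count, tub prior: negative exponent diverges to +Inf
  expect_identical(log_posterior(c(0.7, 0.3, 0), lib, 1 / 3), Inf)
})

test_that("MD augmented mode matches the closed form and guards the boundary", {
  expect_equal(md_posterior_mode(c(3, 1), c(1, 1), r = 4), c(3 / 8, 1 / 8))
  # flat prior reduction: t_i / (t_tot + r)
  t <- c(7, 2, 1)
  expect_equal(md_posterior_mode(t, 1, r = 5), t / (sum(t) + 5))
  expect_error(md_posterior_mode(c(3, 0), c(0.5, 0.5), r = 2),
               "outside the parameter space")
})

test_that("MD marginal mean matches an independent truncated Poisson sum", {
  t <- c(3, 1)
  alpha <- c(1, 1)
  expect_equal(md_marginal_mean(t, alpha, mu = 0),
               (t + alpha) / (sum(t + alpha) + 1))
  # independent oracle: direct dpois-weighted sum over an exhaustive range
  for (mu in c(0.5, 2, 17)) {
    r <- 0:300
    w <- dpois(r, mu)
    oracle <- vapply(seq_along(t), function(i) {
      sum(w * (t[i] + alpha[i]) / (sum(t + alpha) + r + 1))
    }, numeric(1))
    expect_equal(md_marginal_mean(t, alpha, mu), oracle, tolerance = 1e-10)
  }
})

test_that("MD marginal mean decreases as the unconverted mass grows", {
  t <- c(3, 1, 0)
  mus <- c(0, 0.5, 1, 2, 5, 20)
  vals <- sapply(mus, function(mu) md_marginal_mean(t, 1, mu))
  for (i in 1:3) expect_true(all(diff(vals[i, ]) < 0))
})
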