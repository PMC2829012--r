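test_that("every sampler keeps proportion draws on the simplex", {
  lib <- toy_lib()
  cc <- chain_config(2100, 100, 2, seed = 5)
  for (prior in list(prior_spec("flat"), prior_spec("tub"))) {
    for (fit in list(run_dpb(lib, prior, cc), run_dmb(lib, prior, cc),
                     run_md(lib, prior, cc))) {
      expect_lt(max(abs(rowSums(fit$m) - 1)), 1e-9)
      expect_true(all(fit$m >= 0))
      expect_equal(nrow(fit$m), 1000)
    }
  }
})

test_that("a single-gene library gives degenerate draws at 1", {
  lib <- tag_library("only", 7, 0.6)
  cc <- chain_config(600, 100, 1, seed = 2)
  expect_true(all(run_dpb(lib, prior_spec(), cc)$m == 1))
  expect_true(all(run_dmb(lib, prior_spec(), cc)$m == 1))
  expect_true(all(run_md(lib, prior_spec(), cc)$m == 1))
})

test_that("with phi = 1 and flat prior the samplers reduce to the conjugate", {
  t <- c(30, 10, 5)
  lib <- tag_library(c("a", "b", "c"), t, c(1, 1, 1))
  cc <- chain_config(8500, 500, 2, seed = 9)
  post_mean <- (t + 1) / (sum(t) + 3)
  fit_dpb <- run_dpb(lib, prior_spec("flat"), cc, keep_g = TRUE)
  fit_dmb <- run_dmb(lib, prior_spec("flat"), cc, keep_u = TRUE)
  expect_close(colMeans(fit_dpb$m), post_mean, tol = 0.012)
  expect_close(colMeans(fit_dmb$m), post_mean, tol = 0.012)
  # with perfect digestion nothing is latent: g = t, u = 0, every sweep
  expect_true(all(fit_dpb$latent$g == rep(t, each = nrow(fit_dpb$latent$g))))
  expect_true(all(fit_dmb$latent$u == 0))
})

test_that("DPB latent counts never fall below the observed counts", {
  lib <- toy_lib()
  fit <- run_dpb(lib, prior_spec("flat"), chain_config(1500, 100, 1, seed = 4),
                 keep_g = TRUE)
  expect_true(all(sweep(fit$latent$g, 2, lib$t, ">=")))
  expect_true(all(fit$latent$N >= 1))
})

test_that("sampler runs are reproducible from the seed", {
  lib <- toy_lib()
  cc <- chain_config(1100, 100, 2, seed = 42)
  expect_identical(run_dpb(lib, prior_spec(), cc)$m,
                   run_dpb(lib, prior_spec(), cc)$m)
  cc2 <- chain_config(1100, 100, 2, seed = 43)
  expect_false(identical(run_dpb(lib, prior_spec(), cc)$m,
                         run_dpb(lib, prior_spec(), cc2)$m))
})

test_that("MD reductions: mu = 0, raw augmented means, and prior recovery", {
  lib <- toy_lib()
  t <- lib$t
  cc <- chain_config(8500, 500, 2, seed = 31)
  fit <- run_md(lib, prior_spec("flat", mu = 0), cc)
  expect_true(all(fit$latent$r == 0))
  # raw renormalised augmented coordinates have mean (t + alpha) / S exactly
  q_renorm <- fit$latent$q / (1 - fit$latent$m0)
  expect_close(colMeans(q_renorm), (t + 1) / sum(t + 1), tol = 0.012)
  expect_true(all(fit$latent$m0 > 0 & fit$latent$m0 < 1))
  # no counts + mu -> 0: the augmented posterior is the prior Dir(alpha, 1)
  lib0 <- tag_library(c("a", "b"), c(0, 0), c(0.9, 0.4))
  fit0 <- run_md(lib0, prior_spec(alpha = c(2, 1), mu = 0), cc)
  expect_close(colMeans(fit0$latent$q), c(2, 1) / 4, tol = 0.015)
})

test_that("MD default mu follows the corrected-MLE plug-in", {
  lib <- toy_lib()
  fit <- run_md(lib, prior_spec(), chain_config(300, 100, 1, seed = 2))
  mhat <- corrected_mle(lib)
  s <- sum(mhat * lib$phi)
  expect_equal(fit$mu, lib$t_tot * (1 - s) / s, tolerance = 1e-12)
})

test_that("tub-prior chains survive zero counts without degenerate draws", {
  lib <- tag_library(paste0("g", 1:6), c(40, 5, 0, 0, 2, 0),
                     c(0.9, 0.55, 0.7, 0.99, 0.3, 0.85))
  cc <- chain_config(2100, 100, 2, seed = 8)
  fit <- run_dpb(lib, prior_spec("tub"), cc)
  expect_true(all(is.finite(fit$m)) && all(fit$m > 0))
  expect_lt(max(abs(rowSums(fit$m) - 1)), 1e-9)
  expect_gte(fit$clamps, 0)
})

test_that("posterior summaries give ordered equal-tail intervals", {
  cons <- matrix(0.25, nrow = 10, ncol = 4)
  s <- summarize_draws(cons, level = 0.9)
  expect_equal(s$lower, s$median)
  expect_equal(s$median, s$upper)
  lib <- tag_library(c("a", "b", "c"), c(30, 10, 5), c(1, 1, 1))
  fit <- run_dpb(lib, prior_spec("flat"), chain_config(16500, 500, 4, seed = 3))
  s2 <- summarize_draws(fit, level = 0.95)
  expect_true(all(s2$lower <= s2$median & s2$median <= s2$upper))
  # conjugate case: endpoints approach Beta(t_i + 1, t_tot + l - t_i - 1)
  # quantiles, evaluated independently through qbeta
  for (i in 1:3) {
    a <- lib$t[i] + 1
    b <- lib$t_tot + 3 - a
    expect_equal(s2$lower[i], stats::qbeta(0.025, a, b), tolerance = 0.02)
    expect_equal(s2$upper[i], stats::qbeta(0.975, a, b), tolerance = 0.02)
  }
  expect_error(summarize_draws(fit, level = 1.2), "level")
  expect_error(summarize_draws(cons[1, , drop = FALSE]), "at least 2")
})

test_that("autocorrelation matches closed forms for known processes", {
  set.seed(55)
  wn <- rnorm(10000)
  expect_lt(max(abs(autocorrelation(wn, c(10, 20, 40, 80)))), 0.03)
  ar <- as.numeric(stats::filter(rnorm(100000), 0.9, "recursive"))
  expect_equal(unname(autocorrelation(ar, 10)), 0.9^10, tolerance = 0.05)
  expect_equal(unname(autocorrelation(ar, 0)), 1.0)
  expect_error(autocorrelation(rep(1, 100), 10), "constant")
  expect_error(autocorrelation(rnorm(20), 50), "too short")
})
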