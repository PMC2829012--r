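test_that("odds-ratio bias factor reproduces the analytic cases", {
  # upstream tag (k = 1) with p 0.92 vs 0.96: phi ratio 0.0736 / 0.0384
  expect_equal(or_bias_factor(0.92, 0.96, k = 1), 0.0736 / 0.0384,
               tolerance = 1e-12)
  expect_equal(round(or_bias_factor(0.92, 0.96, k = 1), 1), 1.9)
  # equal cleavage probabilities: no bias at any position
  for (k in c(0, 1, 5)) expect_equal(or_bias_factor(0.8, 0.8, k), 1.0)
  # 3'-only analysis: phi = p cancels against the normaliser
  expect_equal(or_bias_factor(0.92, 0.96, k = 0), 1.0)
  # explicit normalisers sum(m phi) = p give the alternative (1-p_a)/(1-p_b)
  expect_equal(or_bias_factor(0.92, 0.96, 1, norm_a = 0.92, norm_b = 0.96),
               0.08 / 0.04)
  # swapping libraries inverts the factor
  expect_equal(or_bias_factor(0.92, 0.96, 3) * or_bias_factor(0.96, 0.92, 3),
               1.0, tolerance = 1e-12)
  expect_error(or_bias_factor(0.9, 0.9, -1), "k")
})

test_that("identical draw sets give null differences and unit odds ratios", {
  lib <- toy_lib()
  fit <- run_dpb(lib, prior_spec(), chain_config(1100, 100, 2, seed = 3))
  res <- diff_test(fit, fit)
  expect_equal(res$diff_mean, rep(0, 3))
  expect_equal(res$or_median, rep(1, 3))
  expect_false(any(res$flag))
  jt <- joint_test(fit, fit, c("a", "b"))
  expect_true(jt$degenerate)
  expect_true(is.na(jt$same_sign_fraction))
})

test_that("a twofold change with ample counts is detected", {
  dir <- withr::local_tempdir()
  make_fixture("twofold_pair", dir, seed = 5)
  lib_a <- read_tag_library(file.path(dir, "twofold_pair_library_a.tsv"))
  lib_b <- read_tag_library(file.path(dir, "twofold_pair_library_b.tsv"))
  cc_a <- chain_config(4500, 500, 4, seed = 11)
  cc_b <- chain_config(4500, 500, 4, seed = 12)
  fit_a <- run_dpb(lib_a, prior_spec(), cc_a)
  fit_b <- run_dpb(lib_b, prior_spec(), cc_b)
  res <- diff_test(fit_b, fit_a)
  marked <- res[res$gene_id == "mark", ]
  expect_gt(marked$diff_lower, 0)
  expect_true(marked$flag)
  expect_gt(marked$or_median, 1.4)
  # unchanged genes are mostly unflagged
  expect_lt(mean(res$flag[res$gene_id != "mark"]), 0.2)
  # gene order does not change per-gene results
  res_rev <- diff_test(fit_b, fit_a, genes = rev(res$gene_id))
  expect_equal(res_rev[match(res$gene_id, res_rev$gene_id), "diff_mean"],
               res$diff_mean)
  expect_error(diff_test(fit_a, fit_b, genes = "nope"), "absent.*nope")
})

test_that("joint test reduces to the marginal test for a singleton and
           detects a jointly shifted pair", {
  dir <- withr::local_tempdir()
  make_fixture("twofold_pair", dir, seed = 5)
  lib_a <- read_tag_library(file.path(dir, "twofold_pair_library_a.tsv"))
  lib_b <- read_tag_library(file.path(dir, "twofold_pair_library_b.tsv"))
  fit_a <- run_dpb(lib_a, prior_spec(), chain_config(4500, 500, 4, seed = 21))
  fit_b <- run_dpb(lib_b, prior_spec(), chain_config(4500, 500, 4, seed = 22))
  jt <- joint_test(fit_b, fit_a, "mark")
  res <- diff_test(fit_b, fit_a, genes = "mark")
  expect_equal(jt$max_tail_prob, res$p_tail)
  expect_equal(as.vector(jt$diff_draws),
               as.vector(fit_b$m[, "mark"] - fit_a$m[, "mark"]))
  expect_equal(mean(jt$diff_draws), res$diff_mean)
  expect_error(joint_test(fit_a, fit_b, character(0)), "empty")
})

test_that("two jointly doubled genes share a difference sign in most draws", {
  set.seed(91)
  l <- 30
  m_a <- rep(1 / l, l)
  m_b <- m_a
  m_b[1:2] <- 2 * m_b[1:2]
  m_b <- m_b / sum(m_b)
  st <- simulate_site_structures(l, 2, seed = 92)
  phi <- phi_from_structures(st, 0.55)
  lib_a <- simulate_library(m_a, phi, 30000, seed = 93)
  lib_b <- simulate_library(m_b, phi, 30000, seed = 94)
  fit_a <- run_dpb(lib_a, prior_spec(), chain_config(4500, 500, 4, seed = 95))
  fit_b <- run_dpb(lib_b, prior_spec(), chain_config(4500, 500, 4, seed = 96))
  jt <- joint_test(fit_b, fit_a, lib_a$gene_id[1:2])
  expect_gt(jt$same_sign_fraction, 0.9)
  expect_lt(jt$max_tail_prob, 0.05)
})
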