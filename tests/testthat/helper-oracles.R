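# Shared test utilities: a dense-grid integrator over the 2-simplex used as
# the independent route against the MCMC samplers, and small toy libraries.

toy_lib <- function() {
  tag_library(c("a", "b", "c"), c(5, 2, 0), c(0.9, 0.5, 0.7))
}

# Posterior mean over the 2-simplex (l = 3) by Riemann summation on an
# equally spaced (m1, m2) grid; log_density takes a 3-column matrix of
# proportion vectors and returns log densities up to a constant.
grid_simplex_mean <- function(log_density, h = 0.0025) {
  g <- seq(h / 2, 1 - h / 2, by = h)
  mm <- expand.grid(m1 = g, m2 = g)
  mm <- mm[mm$m1 + mm$m2 < 1, ]
  m <- cbind(mm$m1, mm$m2, 1 - mm$m1 - mm$m2)
  lw <- log_density(m)
  w <- exp(lw - max(lw))
  colSums(m * w) / sum(w)
}

expect_close <- function(x, y, tol) {
  expect_true(all(abs(x - y) <= tol),
              label = paste0("max|diff| = ", signif(max(abs(x - y)), 3),
                             " (tol ", tol, ")"))
}
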