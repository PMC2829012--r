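# Coverage simulation study: generate ground-truth proportion vectors with a
# prescribed per-bin composition, simulate biased multinomial libraries, run
# the samplers and tally credible-interval coverage and length per
# abundance bin.

#' Configuration of the coverage simulation protocol
#'
#' Defaults reproduce the l = 1000 study conditions: 15,000 tags per
#' library, cleavage probability 0.55, site counts `1 + Poisson(2)`, five
#' abundance bins holding 25/209/578/165/23 genes, and 20,500-sweep chains
#' (burn-in 500, thin 20).  `n_libraries` defaults to 1,000 replicate
#' libraries; reduce it for desk-scale runs.
#'
#' @param l Number of genes.
#' @param n_tags Tags per simulated library.
#' @param n_libraries Number of replicate libraries.
#' @param p Cleavage probability.
#' @param site_mean Poisson mean of the extra AE sites (`k = 1 + Pois`).
#' @param bin_edges Increasing abundance-bin boundaries (length bins + 1).
#' @param bin_gene_counts Genes drawn per bin; must sum to `l`.
#' @param samplers,priors Character vectors crossed to form the
#'   (sampler, prior) combinations evaluated; ignored when `combos` given.
#' @param combos Optional data frame with columns `sampler`, `prior` naming
#'   exactly the combinations to run.
#' @param chain A [chain_config()] (its seed is overridden per library).
#' @param seed Master seed; per-library seeds are `seed + library index`.
#' @param min_proportion Positive floor replacing a zero lower edge of the
#'   first bin for the log-uniform placement (default 1e-6: one part per
#'   million is effectively unobservable in a 15,000-tag library).
#' @param level Credible level for the intervals.
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(l = 1000, n_tags = 15000, n_libraries = 1000,
                            p = 0.55, site_mean = 2,
                            bin_edges = c(0, 1.67e-5, 1.23e-4, 9.12e-4,
                                          6.74e-3, 1.35e-1),
                            bin_gene_counts = c(25, 209, 578, 165, 23),
                            samplers = c("dpb", "dmb", "md"),
                            priors = c("flat", "tub"),
                            combos = NULL,
                            chain = chain_config(),
                            seed = 1L,
                            min_proportion = 1e-6,
                            level = 0.95) {
  if (sum(bin_gene_counts) != l) stop("bin_gene_counts must sum to l")
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (length(bin_gene_counts) != length(bin_edges) - 1) {
    stop("need one gene count per bin")
  }
  check_cleavage_prob(p)
  if (min_proportion <= 0 || min_proportion >= bin_edges[2]) {
    stop("'min_proportion' must lie in (0, first upper edge)")
  }
  samplers <- match.arg(samplers, c("dpb", "dmb", "md"), several.ok = TRUE)
  priors <- match.arg(priors, c("flat", "tub"), several.ok = TRUE)
  if (is.null(combos)) {
    combos <- expand.grid(sampler = samplers, prior = priors,
                          stringsAsFactors = FALSE)
  }
  structure(
    list(l = l, n_tags = n_tags, n_libraries = n_libraries, p = p,
         site_mean = site_mean, bin_edges = bin_edges,
         bin_gene_counts = bin_gene_counts, combos = combos,
         chain = chain, seed = as.integer(seed),
         min_proportion = min_proportion, level = level),
    class = "protocol_config"
  )
}

#' Build a ground-truth proportion vector with a prescribed bin profile
#'
#' Places the requested number of genes per abundance bin log-uniformly
#' within the bin's range (a zero lower edge is replaced by
#' `min_proportion`), renormalises the whole vector to the simplex, and
#' assigns each gene its bin AFTER renormalisation using half-open
#' intervals `[low, high)`.  Genes pushed outside the outermost edges get
#' bin `NA` and are excluded from per-bin tallies.
#'
#' @param config A [protocol_config()].
#' @param seed Optional seed override (default `config$seed`).
#' @return List with `m` (proportion vector), `bin` (post-renormalisation
#'   bin index per gene, `NA` if out of range), `drawn_bin` (bin each gene
#'   was drawn in), and `bin_edges`.
#' @export
build_synthetic_m <- function(config, seed = config$seed) {
  edges <- config$bin_edges
  counts <- config$bin_gene_counts
  lows <- pmax(edges[-length(edges)], config$min_proportion)
  highs <- edges[-1]
  if (any(lows >= highs)) stop("infeasible bin after applying the proportion floor")
  set.seed(seed)
  m <- unlist(lapply(seq_along(counts), function(b) {
    exp(runif(counts[b], log(lows[b]), log(highs[b])))
  }))
  drawn_bin <- rep(seq_along(counts), counts)
  m <- m / sum(m)
  bin <- findInterval(m, edges, left.open = FALSE)
  bin[bin < 1 | bin > length(counts)] <- NA_integer_
  list(m = m, bin = bin, drawn_bin = drawn_bin, bin_edges = edges)
}

#' Simulate one tag library from true proportions
#'
#' Draws `t ~ Multinomial(n_tags, theta)` with
#' `theta = biased_from_true(m, phi)`.
#'
#' @param m True mRNA proportion vector.
#' @param phi Tag formation probabilities.
#' @param n_tags Library size (total tags).
#' @param seed Optional integer seed (uses R's RNG).
#' @param gene_id Optional gene identifiers (default `g1..gl`).
#' @return A [tag_library()].
#' @export
simulate_library <- function(m, phi, n_tags, seed = NULL, gene_id = NULL) {
  if (n_tags < 1) stop("'n_tags' must be >= 1")
  theta <- biased_from_true(m, phi)
  if (!is.null(seed)) set.seed(seed)
  t <- as.integer(rmultinom(1, n_tags, theta)[, 1])
  if (is.null(gene_id)) {
    gene_id <- sprintf("g%0*d", nchar(length(m)), seq_along(m))
  }
  tag_library(gene_id, t, phi)
}

#' Run the interval-coverage simulation study
#'
#' For each replicate library and each (sampler, prior) combination, runs
#' the Gibbs sampler, computes equal-tail credible intervals, and tallies
#' per-bin empirical coverage of the true proportions and average interval
#' length, pooling genes within a bin across libraries.  Sampler failures
#' on individual libraries are caught, counted and excluded.
#'
#' @param config A [protocol_config()].
#' @param progress Print a progress line every 25 libraries.
#' @return A `coverage_report` data frame with one row per
#'   (bin x sampler x prior): bin bounds, gene count, library count,
#'   empirical `coverage` and `avg_length`.  Attributes carry the truth
#'   (`truth`), phi, failure count and the config.
#' @export
run_coverage_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "protocol_config"))
  structures <- simulate_site_structures(config$l, config$site_mean,
                                         seed = config$seed)
  phi <- phi_from_structures(structures, config$p)
  truth <- build_synthetic_m(config, seed = config$seed + 1L)
  m_true <- truth$m
  combos <- config$combos
  n_bins <- length(config$bin_gene_counts)
  n_combo <- nrow(combos)

  cover <- matrix(0, n_combo, n_bins)
  total <- matrix(0, n_combo, n_bins)
  len_sum <- matrix(0, n_combo, n_bins)
  lib_ok <- matrix(0L, n_combo, 1)
  failures <- 0L
  in_bin <- !is.na(truth$bin)
  bin_idx <- truth$bin[in_bin]
  bin_sizes <- tabulate(bin_idx, n_bins)

  for (i in seq_len(config$n_libraries)) {
    lib_seed <- config$seed + 1L + i
    lib <- simulate_library(m_true, phi, config$n_tags, seed = lib_seed,
                            gene_id = structures$gene_id)
    for (cb in seq_len(n_combo)) {
      cfg <- config$chain
      cfg$seed <- lib_seed
      prior <- prior_spec(alpha = combos$prior[cb])
      fit <- tryCatch(
        switch(combos$sampler[cb],
               dpb = run_dpb(lib, prior, cfg),
               dmb = run_dmb(lib, prior, cfg),
               md = run_md(lib, prior, cfg)),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        failures <- failures + 1L
        next
      }
      s <- summarize_draws(fit, level = config$level)
      covered <- (s$lower <= m_true & m_true <= s$upper)[in_bin]
      lens <- (s$upper - s$lower)[in_bin]
      cover[cb, ] <- cover[cb, ] + tabulate(bin_idx[covered], n_bins)
      total[cb, ] <- total[cb, ] + bin_sizes
      len_sum[cb, ] <- len_sum[cb, ] + vapply(
        seq_len(n_bins), function(b) sum(lens[bin_idx == b]), numeric(1))
      lib_ok[cb] <- lib_ok[cb] + 1L
    }
    if (progress && i %% 25 == 0) {
      message("coverage experiment: library ", i, "/", config$n_libraries)
    }
  }

  edges <- config$bin_edges
  report <- do.call(rbind, lapply(seq_len(n_combo), function(cb) {
    data.frame(
      bin = seq_len(n_bins),
      bin_low = edges[-length(edges)],
      bin_high = edges[-1],
      sampler = combos$sampler[cb],
      prior = combos$prior[cb],
      n_genes = bin_sizes,
      n_libraries = lib_ok[cb],
      coverage = ifelse(total[cb, ] > 0, cover[cb, ] / total[cb, ], NA_real_),
      avg_length = ifelse(total[cb, ] > 0, len_sum[cb, ] / total[cb, ],
                          NA_real_),
      stringsAsFactors = FALSE
    )
  }))
  structure(report,
            truth = truth, phi = phi, failures = failures, config = config,
            class = c("coverage_report", "data.frame"))
}

#' Write a coverage report as TSV
#'
#' @param report A `coverage_report`.
#' @param path Output file.
#' @export
write_coverage_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
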