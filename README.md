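# tagbayes

Bias-corrected Bayesian inference for SAGE / DGE tag-count libraries.

Tag-based transcriptome profiling counts short cDNA tags cut by a
restriction ("anchoring") enzyme. The enzyme cleaves each site only with
probability *p* < 1, and only the 3'-most cleaved site yields a tag, so a
gene with sites *j* = 1..*k* (from the 3' end) produces a tag at site *j*
with geometric probability (1−p)^(j−1) p, and forms *any* unambiguous tag
with probability

    phi_i = sum over unambiguous j of (1 - p)^(j-1) * p
          = 1 - (1 - p)^k   (all sites unambiguous).

Tag counts therefore sample a *biased* pool: the tag-pool proportion of
gene *i* is theta_i = m_i phi_i / sum_j m_j phi_j, not its true mRNA
proportion m_i. Aggregating a gene's tags increases power only if this
bias is corrected. `tagbayes` provides:

* the geometric tag-formation model (`site_tag_prob`,
  `tag_formation_prob`, `phi_from_structures`);
* the corrected maximum-likelihood estimator, in closed form
  `m_i ∝ t_i / phi_i` (`corrected_mle`), and the corrected log posterior
  under a Dirichlet prior (`log_posterior`);
* three Gibbs samplers for the full posterior of **m** — DPB
  (Dirichlet-Poisson-Binomial, also yields the population size *N*), DMB
  (Dirichlet-Multinomial-Binomial), and MD (missing-data augmentation,
  also yields the unconverted count *r*) — with the *flat* (alpha = 1)
  and *tub* (alpha = 1/l) prior presets, posterior summaries and
  autocorrelation diagnostics (`run_dpb`, `run_dmb`, `run_md`,
  `summarize_draws`, `autocorrelation`);
* a credible-interval coverage simulation study over abundance bins
  (`protocol_config`, `build_synthetic_m`, `simulate_library`,
  `run_coverage_experiment`);
* differential-expression machinery across libraries with different
  cleavage probabilities: the analytic odds-ratio bias factor
  (`or_bias_factor`), per-gene Monte-Carlo tests (`diff_test`) and joint
  gene-set tests (`joint_test`).

The Gibbs sweeps are conjugate throughout and run in compiled code on a
seeded internal generator stack, so a full coverage study (hundreds of
replicate libraries, 20,500-sweep chains, l = 1000 genes) completes in
minutes on one CPU.

## Worked example

```r
library(tagbayes)

lib <- tag_library(c("YAL003W", "YBR118W", "YCR012W", "YDL055C"),
                   count = c(320, 55, 12, 0),
                   phi   = c(0.91, 0.55, 0.75, 0.70))

observed_proportions(lib)   # 0.8269 0.1421 0.0310 0
corrected_mle(lib)          # 0.7520 0.2138 0.0342 0

fit <- run_dpb(lib, prior_spec("flat"),
               chain_config(20500, 500, 20, seed = 1))
summarize_draws(fit)
#>   gene_id    mean  median    lower  upper
#> 1 YAL003W 0.71978 0.71998 0.667612 0.7691
#> 2 YBR118W 0.24043 0.23966 0.193039 0.2912
#> 3 YCR012W 0.03664 0.03543 0.019718 0.0591
#> 4 YDL055C 0.00315 0.00208 0.000101 0.0108
```

The gene YAL003W holds 83% of the *tags* but only ~75% of the *mRNA*: its
high tag-formation probability (0.91 vs 0.55 for YBR118W) over-represents
it in the tag pool, and the correction moves mass to the poorly tagged
gene. The posterior mean sits below the corrected MLE (flat-prior
shrinkage toward uniformity — 1 pseudo-tag per gene), and the zero-count
gene receives a small positive estimate with an interval reaching ~0.011.

For differential expression across two libraries with cleavage
probabilities 0.92 and 0.96, a tag formed one position upstream of the 3'
end carries a multiplicative odds-ratio bias of

```r
or_bias_factor(0.92, 0.96, k = 1)   # 1.9167
```

— a spurious near-twofold "change" under equal expression, which the
samplers remove when each library is analysed with its own phi
(`diff_test(run_dpb(libA, ...), run_dpb(libB, ...))`).

A command-line interface wrapping these functions is installed at
`inst/cli/tagbayes` (subcommands `estimate`, `sample`, `coverage`,
`diffexp`, `fixture`).

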