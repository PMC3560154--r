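# seqpower

Simulation-based power analysis for RNA-Seq differential expression (DE)
experimental designs: how many biological replicates, and how much
sequencing depth per sample, does an experiment need — and what does
multiplexing n barcoded samples into a lane (replication bought at depth
1/n) do to error rates?

`seqpower` answers these questions for the negative-binomial (NB) model of
read counts,

    K_ij ~ NB(mu_i, var = mu_i (1 + phi_i mu_i)),

where `mu_i` is a transcript's expected count per lane and the dispersion
`phi_i` captures biological plus library-preparation overdispersion on top
of Poisson sequencing noise (`phi = 0` is the Poisson limit). The package
provides:

* a **synthetic transcriptome generator** — abundances spanning four
  decades, dispersions scattered around the empirical power-law trend
  `phi = c mu^(alpha-2)` (`c = 0.364`, `alpha = 1.700`), 15% induced DE via
  exponential regulating factors `theta = 1 + Exp(1)` (up) and
  `(1 + Exp(1))^-1` (down), with `theta <= 0.83` or `>= 1.20` defining the
  "effectively DE" ground truth — or parameter estimation from a real
  transcript-by-lane count matrix;
* **without-replacement depth subsampling** (multivariate hypergeometric
  per lane), the exact count-level analogue of sequencing less;
* an **exact conditional NB test** for two-group comparisons, conditioning
  on each transcript's total count, with four dispersion-estimation
  strategies: empirical-Bayes tagwise squeezing toward a common value
  (edgeR-like), the maximum of per-transcript and fitted-trend
  `phi = a + b/mu` estimates (DESeq-like), a global power-law fit
  (NBPSeq-like), and an oracle;
* **metrics**: false/true positive rates against the effectively-DE truth
  (Benjamini–Hochberg adjusted, quoted in percent), call rates, p-value
  histograms, high/low-count strata, fold-change criteria with pseudocount
  damping, cross-strategy call overlap;
* **experiment runners** for null calibration, replication-by-depth power
  grids, and multiplex scenarios (`n` vs depth `1/n`), with seeded child
  streams so every cell is individually reproducible.

## Worked example

Simulate a 4-vs-4 experiment over 5,000 transcripts at a quarter of the
full sequencing depth, test it with the conservative DESeq-like strategy,
and score the calls against the known ground truth:

```r
library(seqpower)

cfg <- generator_config(t = 5000)                       # 1e6 reads per lane
pop <- build_parameter_population(cfg, seed = 1)
pop <- label_effective_de(draw_regulating_factors(pop, seed = 2))
sum(pop$theta != 1)                                     # 750 induced
sum(pop$effective_label == "effectively-DE")            # 619 effectively DE

counts  <- simulate_counts(pop, n_reps = 4, seed = 3)
shallow <- subsample_depth(counts, depth_fraction = 0.25, seed = 4)
res     <- run_de_test(shallow, strategy = "max-parametric")
de_metrics(res, pop$effective_label, shallow)[, 1:4]
#>      stratum call_rate_percent fpr_percent tpr_percent
#> 1        all             1.200      0.0228        9.53
#> 2 high-count             3.940      0.0000       33.33
#> 3  low-count             0.873      0.0256        6.83
```

Of the 750 induced transcripts, 619 have a biologically meaningful fold
change; at 25% depth the pipeline recovers 9.5% of them overall (33% of
the high-count ones) while mislabelling only 0.02% of the true negatives —
the conservative profile this strategy is designed for. Scenario-level
sweeps use the runners:

```r
grid <- run_power_grid(n_values = c(2, 4, 8), depth_fractions = c(1, 0.5, 0.25),
                       repetitions = 5, config = cfg, seed = 1)
head(grid$summary)
write_report(grid, "power_grid_report")
```

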