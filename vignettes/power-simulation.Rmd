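---
title: "Simulating power and error for RNA-Seq differential expression designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating power and error for RNA-Seq differential expression designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqpower)
```

## The question

An RNA-Seq differential-expression (DE) experiment has two main budget
levers: the number of biological replicates per condition, $n$, and the
sequencing depth per sample. Multiplexing lets an experimenter barcode $n$
samples into one lane, buying replication at the price of an $n$-fold cut in
depth per sample. `seqpower` quantifies that trade-off by simulation: it
generates realistic count data with known differential expression, analyses
it with an exact negative-binomial (NB) test under several
dispersion-estimation strategies, and reports false and true positive rates
(FPR/TPR) across replication, depth, and multiplex designs.

## The count model

Reads mapped to transcript $i$ in lane $j$ are modelled as

$$K_{ij} \sim \mathrm{NB}\left(\mu_i,\ \mathrm{var} = \mu_i(1 + \phi_i\mu_i)\right),$$

the standard hierarchical account of RNA-Seq counts: Poisson sequencing
noise compounded by gamma-distributed variation in the transcript's
concentration across library preparations and biological replicates. The
dispersion $\phi_i$ is unitless; $\phi_i = 0$ recovers the Poisson limit,
and $\phi_i$ sets the squared coefficient of the extra-Poisson variation.
Internally the package converts to R's `(size, mu)` parameterisation via
$\mathrm{size} = 1/\phi$. A useful closure property drives the exact test:
a sum of $n$ iid $\mathrm{NB}(\mu, \phi)$ draws is
$\mathrm{NB}(n\mu, \phi/n)$ (`pooled_sum_params()`).

## The synthetic transcriptome

`build_parameter_population()` produces the per-transcript $(\mu_i, \phi_i)$
landscape either by maximum-likelihood estimation from a user-supplied
count matrix of single-condition biological replicates (lane totals
equalised by multivariate-hypergeometric subsampling, transcripts averaging
under one read per lane culled), or from a built-in generator with:

| parameter | default | meaning |
|---|---|---|
| `t` | 20000 | transcripts |
| `mu_log10_mean`, `mu_log10_sd` | 0.9, 0.8 | $\log_{10}\mu$ normal law |
| `mu_range` | $[1, 10^5]$ | truncation of the abundance draw |
| `library_size` | $10^6$ | expected reads per lane after rescaling |
| `dispersion_c`, `dispersion_alpha` | 0.364, 1.700 | trend $\phi = c\,\mu^{\alpha-2}$ |
| `sigma_phi` | 0.35 | $\log_{10}$ scatter around the trend |
| `phi_range` | $[10^{-4}, 10]$ | clamp on generated dispersions |
| `frac_up`, `frac_down` | 0.075, 0.075 | induced DE fractions |

The abundance law spans four decades, matching the dynamic range seen in
deeply sequenced human transcriptomes; the dispersion trend is the
empirical power law fitted to transcriptome-wide NB maximum-likelihood
estimates ($c = 0.364$, $\alpha = 1.700$), with log-normal scatter because
real per-transcript dispersions straddle any smooth trend by an order of
magnitude in both directions. The truncation bounds, the scatter scale
$\sigma_\phi = 0.35$, and the desk-scale lane total of $10^6$ are modelling
choices of this package, selected once to give a plausible landscape at
tractable size; `generator_config_full_scale()` switches to the
transcriptome-scale setting (46,446 transcripts, $1.3\times10^7$ reads per
lane, the midpoint of the 10–16 million range of the lanes the landscape
emulates).

Differential expression is induced by regulating factors
(`draw_regulating_factors()`): a random 7.5% of transcripts get
$\theta_i = 1 + X_i$ (up-regulated) and a disjoint 7.5% get
$\theta_i = (1 + X_i)^{-1}$ (down-regulated) with $X_i \sim
\mathrm{Exp}(1)$; subset sizes use floor rounding, so 46,446 transcripts
yield exactly $2\lfloor 0.075 \cdot 46446\rfloor = 6966$ regulated ones.
Treatment counts are drawn from $\mathrm{NB}(\theta_i\mu_i, \phi_i)$ with
the dispersion unchanged. Because many exponential draws produce fold
changes too small to matter biologically, transcripts only count as ground
truth positives when $\theta_i \le 0.83$ or $\theta_i \ge 1.20$
("effectively DE", `label_effective_de()`, boundaries inclusive); the rest
are effectively non-DE. Analytically, a fraction
$(e^{-0.2} + e^{-(1/0.83-1)})/2 \approx 0.817$ of induced transcripts is
effectively DE.

Sequencing depth is reduced by `subsample_depth()`: each lane is thinned to
`round(fraction * total)` reads (round-half-even) without replacement,
tracking the transcript of origin, i.e. one multivariate hypergeometric
draw per lane. This is exactly what resequencing the same library at lower
depth does to mapped counts, and it composes: two successive 50% thinnings
are distributed as one 25% thinning.

## The DE test and its dispersion strategies

All tested pipelines share the exact conditional NB test
(`exact_nb_test()`). For transcript $i$, the per-condition count sums
$S_A, S_B$ are modelled by the pooled laws
$\mathrm{NB}(n_A\mu, \phi/n_A)$ and $\mathrm{NB}(n_B\mu, \phi/n_B)$ with
the common null mean $\mu = (S_A+S_B)/(n_A+n_B)$ per lane; conditional on
$S = S_A + S_B$, the p-value sums the probabilities of all splits no more
probable than the observed one. In a balanced design, equal sums give
$p = 1$ exactly — the origin of the spike at 1 in p-value histograms for
low-count transcripts. Benjamini–Hochberg adjustment
(`adjust_pvalues_bh()`) is applied over all transcripts.

The strategies differ only in how $\phi_i$ is estimated
(`estimate_dispersions()`):

* **tagwise-squeeze** (edgeR-like): counts are quantile-adjusted (lanes
  scaled to the geometric-mean total and rounded — a simple stand-in for
  quantile-adjusted conditional likelihood), a common dispersion maximises
  the summed likelihood, and per-transcript estimates are shrunk linearly
  toward it with weight $\mathrm{prior\_df}/(\mathrm{prior\_df} +
  \mathrm{residual\_df})$, $\mathrm{residual\_df} = \mathrm{lanes} -
  \mathrm{conditions}$, so small experiments borrow more strength. The
  squeeze underestimates the most dispersed transcripts at small $n$,
  inflating the FPR — the behaviour documented for tagwise empirical-Bayes
  estimation.
* **max-parametric** (DESeq-like): per-transcript estimates are fitted to
  $\phi = a + b/\mu$ by a gamma-family GLM with identity link on $1/\mu$
  (OLS fallback), and each transcript receives the maximum of its own
  estimate and the trend — deliberately conservative.
* **powerlaw** (NBPSeq-like): per-transcript estimates are regressed in
  log–log space onto $\phi = c\,\mu^{\alpha-2}$ and every transcript
  receives its fitted value. The rigid functional form underestimates
  highly dispersed transcripts and inflates the FPR at every $n$. (The
  original estimator maximises a summed conditional likelihood; the
  log–log regression used here is a documented approximation.)
* **oracle**: the simulator's true $\phi_i$, for calibration studies.

Per-transcript and common estimates maximise a **Cox–Reid adjusted**
profile likelihood ($-\tfrac12\log\det X^\top W X$ with the two-group
design and NB working weights) on a 41-point log-spaced grid over
$[10^{-8}, 50]$ with parabolic refinement between neighbours. The
adjustment matters: plain profile likelihood ignores the degrees of freedom
spent on the two condition means and is biased low at small $n$, which
turns the deliberately conservative max-parametric strategy into an
anti-conservative one. A method-of-moments estimator was also considered
and rejected: at $n = 2$ its sampling noise (2 residual degrees of freedom)
inflates the maximum-of-estimate-and-trend so much that power collapses.
The adjusted profile likelihood is the closest unconditional analogue of
the conditional likelihood that all three emulated packages share.

## Metrics

With no DE simulated, `fpr_null()` is the fraction (in percent) of raw
p-values below $\alpha$; a calibrated test matches $\alpha$. With induced
DE, `fpr()` and `tpr()` use BH-adjusted p-values against the effectively-DE
ground truth (their complements are specificity and sensitivity), and
`call_rate()` is the overall percentage of DE calls. Results are reported
overall and split at 100 counts (control-condition replicate mean,
boundary low) into high-/low-count strata. `fold_change_detector()`
implements the pragmatic alternative criterion
$\max(\mathrm{fc}, 1/\mathrm{fc}) \ge 2$, with an optional pseudocount: at
low depth, Poisson shot noise makes low-count transcripts double or halve
spuriously, and adding one count to both means damps exactly those calls
while leaving the exact test's p-values essentially untouched.

## Experiment runners and reproducibility

`run_null_experiment()` (calibration), `run_power_grid()` (replication
$\times$ depth) and `run_multiplex_scenarios()` ($n$ vs depth $1/n$, for
$n \in \{2,3,4,6,8,12,32,96\}$ — depths kept as exact fractions rather than
the rounded percentages usually quoted) repeat each scenario over
independently generated datasets and summarise by the median and a 90%
interval, implemented as the 5th–95th percentile across repetitions.
Within a repetition, every reduced-depth dataset is a strict subsample of
the same full-depth dataset, so depth comparisons are paired. One root
seed drives everything through deterministic child streams
(`child_seed()`), keyed by repetition, stage, and scenario, so any cell is
individually reproducible and identical cells across experiment families
coincide. Null experiments default to 100 repetitions, power grids to 10;
the bundled acceptance checks use 2–3 repetitions at desk scale
($t = 20000$, $10^6$ reads per lane), sizes chosen so a complete run stays
in the minutes range on one core.

## Numerical choices and edge cases

* Dispersion search bounds $[10^{-8}, 50]$, grid tolerance set by the
  41-point log grid plus parabolic refinement; estimates at the lower bound
  mean "no overdispersion detected" and are excluded from trend fits,
  which would otherwise be dragged toward zero by the clamp.
* The exact test enumerates all $S + 1$ splits when $S \le 10^5$; above
  that it keeps the central region holding all but $\sim 10^{-12}$ of the
  conditional mass plus every split at least as extreme as the observed
  one (mirrored by symmetry in balanced designs; unbalanced large-$S$
  transcripts fall back to full enumeration). Probability ties with the
  observed split are included with relative tolerance $10^{-12}$.
* Transcripts with a zero total have $p = 1$ and stay in every
  denominator, so rates remain comparable across depths; all-zero
  count vectors yield a degenerate sentinel from `estimate_nb_mle()` and
  are dropped from estimated populations.
* Simulated lanes are depth-matched by construction, so size factors
  default to 1; median-of-ratios and a simplified (unweighted) TMM are
  available for real data.
* The fold-change pseudocount defaults to 0 in the testing pipeline
  (adding 1 does not materially affect the exact test's p-values) and is
  exposed where fold-change calling is the criterion.

## What the simulation does and does not show

The generator reproduces the features that drive DE testing behaviour — a
broad abundance distribution, a dispersion–mean trend with realistic
scatter, exponential-tailed fold changes, and exact without-replacement
depth loss. It deliberately omits lane and flow-cell batch effects,
barcode bias, GC/length bias, and technical-replicate variance components
(technical overdispersion is treated as nested within the biological
estimate). Passing tests therefore certify the statistical machinery and
the design trade-offs under the NB model, not robustness to those
systematic artefacts. Absolute TPR values depend strongly on the parameter
landscape (its abundance law in particular) and on total depth: depth
robustness is a statement about reads per transcript, so it weakens at
desk scale, where full depth already corresponds to ~50 reads per
transcript per lane, and calibration statements about the exact test hold
in the regime where the conditional support is rich (high counts); at very
low counts the test is conservative by discreteness, never
anti-conservative.
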