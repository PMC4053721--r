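---
title: "Precision weights for RNA-seq linear modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision weights for RNA-seq linear modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voomde)
```

# The model

RNA-seq experiments deliver a matrix of read counts $r_{gi}$ for genes
$g = 1,\dots,G$ and samples $i = 1,\dots,n$, with library sizes
$R_i = \sum_g r_{gi}$. All modelling in this package happens on the
log2 counts-per-million scale,

$$y_{gi} = \log_2\!\frac{r_{gi} + 0.5}{R_i + 1}\times 10^6 ,$$

where the 0.5 count offset keeps zero counts finite and damps the
variability of small counts, and the library-size offset of 1 guarantees
$(r+0.5)/(R+1)$ lies strictly inside $(0,1)$.

For a count with mean $\lambda$ and negative binomial variance
$\lambda + \phi\lambda^2$, first-order error propagation (the delta rule)
gives $\mathrm{var}(\log\text{-cpm}) \approx 1/\lambda + \phi$ on the
natural-log scale: a technical Poisson term that vanishes for large counts
plus the squared biological coefficient of variation $\phi$ that does not.
Two conventions circulate for the log2 scale — equating the sd of log-cpm
with the count CV directly, or dividing by $\ln 2$ as the chain rule
requires. `approx_sd_log_cpm()` exposes both via `log_base2`; the
empirical trend below is estimated from data and is unaffected by the
convention, but analytic comparisons on the log2 scale (and the tests of
this package) use the $\ln 2$-corrected form.

Expression is modelled gene-wise by a linear model
$E(y_g) = X\beta_g$ for an arbitrary full-rank design $X$ ($n \times p$),
with coefficients in log2-fold-change units. The variance structure, not
the mean structure, is what distinguishes the four engines exposed by
`voom_lm()`.

# The mean-variance trend and observation weights

`voom()` performs the four-step procedure:

1. **First pass.** Unweighted least squares per gene gives fitted values
   $\hat\mu_{gi}$, residual standard deviations $s_g$ on $n - p$ df, and
   average log-cpm $\bar y_g$.
2. **Trend.** $s_g^{1/2}$ (square-root sd, roughly symmetrically
   distributed) is smoothed against the average log2-count
   $\tilde r_g = \bar y_g + \log_2(\widetilde R) - \log_2 10^6$, where
   $\widetilde R$ is the *geometric* mean of $R_i + 1$ — the natural
   choice because the conversion is an additive shift of a log quantity.
   The smoother is Cleveland's LOWESS (base R `lowess()`), which is
   robust to the minority of genuinely variable genes.
3. **Evaluation per observation.** Each fitted log-cpm is converted to a
   fitted log2-count $\hat\lambda_{gi} = \hat\mu_{gi} + \log_2(R_i + 1) -
   \log_2 10^6$ using *its own* library size. With unequal depths,
   observations of one gene land on different parts of the trend — the
   entire point of observation-level weighting.
4. **Weights.** $w_{gi} = lo(\hat\lambda_{gi})^{-4}$, the inverse
   predicted variance ($lo$ predicts a square-root sd, hence the fourth
   power). The weighted fit plus empirical Bayes moderation then proceeds
   exactly as for microarray-style data.

## Numerical choices

* **Span and robustness.** LOWESS span 0.5 with 4 robustifying
  (bisquare) iterations. The smoother's published default span for this
  kind of scatter is used because only robustness, not a span, is
  intrinsic to the method; the tests check that one gross outlier among
  500 genes moves the trend by less than 1% anywhere.
* **Interpolation and extrapolation.** The smoothed values at the sorted
  $\tilde r$ define knots of a continuous piecewise-linear $lo(\cdot)$
  (`approxfun`). Beyond the observed range the function extrapolates as a
  constant — predicted standard deviations should neither explode nor go
  negative for extreme fitted counts.
* **Positivity floor.** Knot values are floored at 1% of the smallest
  positive knot so that weights stay finite even if the smoother touches
  zero on degenerate inputs.
* **Duplicate knots** (ties in $\tilde r$) are collapsed by averaging
  their smoothed values, because interpolation needs strictly increasing
  abscissae. Genes with zero residual df are excluded from trend
  *estimation* but still receive weights through $lo$.

# Empirical Bayes moderation

Gene variances are modelled as draws from a scaled inverse chi-square
prior with $d_0$ df and scale $s_0^2$. `estimate_prior()` recovers the
hyperparameters by moment matching on $z_g = \log s_g^2$: after
subtracting the known sampling mean $\psi(d_g/2) - \log(d_g/2)$
(digamma), the excess of the empirical variance of $z$ over the expected
sampling variance $\psi'(d_g/2)$ (trigamma) identifies $d_0$ through a
Newton inversion of the trigamma function; the mean equation then gives
$s_0^2$. When the excess is non-positive, $d_0 = \infty$ and the prior
collapses to the mean variance. The posterior (shrunken) variance is the
convex combination

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and moderated t statistics $\hat\beta_{gj}/(\tilde s_g u_{gj})$ are
referred to $t_{d_0 + d_g}$. Heterogeneous residual df are supported
throughout. Two engine variants re-use this machinery:

* **Trended prior** (`limma_trend`): the constant $\log s_0^2$ is
  replaced by a natural cubic regression spline (4 df) of $z$ on average
  log2-cpm, so variances are squeezed toward a gene-specific trend value.
  This is the right gene-level alternative when library sizes are similar.
* **No moderation** (`ordinary_t`): $d_0$ forced to 0 reproduces the
  classical gene-wise t-test exactly; it exists so the benchmark compares
  engines differing only in the ingredient under study.

The B statistic (log posterior odds of differential expression) uses an
assumed prior DE proportion of 0.01 and estimates the prior variance of
true coefficients from the upper tail of the moderated t statistics,
bounded between 0.1² and 4² on the squared log2-fold-change scale —
conventional values for this statistic, which is reported for ranking
rather than inference. `top_table()` reports the standard columns
(logFC, AveExpr, t, P value, FDR, B); FDR is Benjamini–Hochberg step-up
with ties sharing the maximal-rank value, and p-values of exactly zero
cannot occur because all reference distributions are continuous.

# Gene set tests

Both set tests consume the moderated statistics and the voom weights.

* `rotation_set_test()` (self-contained): per set gene, the data reduce —
  under the observation weights, via the QR of the weighted design with
  the contrast rotated into the last coefficient — to a contrast effect
  plus $n - p$ residual-space effects. This vector is spherically
  distributed under the null, so random rotations (the *same* random
  direction applied to every gene, preserving inter-gene correlation)
  generate the null distribution of the set statistic (mean of
  moderated-t z-scores by default; mean square for mixed alternatives).
  With $B$ rotations the p-value is $(b+1)/(B+1)$: exactly on a
  $1/(B+1)$ grid, never zero, smallest attainable value $10^{-4}$ at the
  default $B = 9999$. The reported p-value for the directional statistic
  is the one-sided p in the observed direction; both directions are
  returned.
* `competitive_set_test()`: moderated t statistics are converted to
  normal-equivalent z-scores and the set is compared against all other
  genes with a two-sample t-test whose set variance is inflated by
  $\mathrm{VIF} = 1 + (m-1)\bar\rho$, with $\bar\rho$ the mean pairwise
  correlation of the set genes' (weighted) residuals, floored at
  $-1/(m-1)$ so the VIF stays positive. With $\bar\rho = 0$ the test
  reduces to an ordinary two-sample comparison; singleton sets get
  VIF = 1.

# Normalization

Log-cpm is depth-normalized by construction. Two optional steps adjust
for composition and distributional differences: TMM scale factors
(`tmm_factors()`: 30% two-sided trim on M-values, 5% on A-values,
inverse-asymptotic-variance gene weights, reference column the one whose
75th cpm percentile is closest to the mean of those percentiles, factors
re-centred to geometric mean 1) multiply the library sizes into effective
sizes; quantile normalization forces all columns of the log-cpm matrix to
the mean of the column order statistics, with ties receiving the mean of
the values their positions span. TMM invariance to rescaling a column is
exact for the trimmed-mean core but only approximate once the
precision weights (which depend on depth) enter; the tests document this
with a 1% tolerance. In the case-study workflow genes are filtered
*before* TMM factors are computed (low-count genes carry the least
reliable M-values), and library sizes are frozen when the counts are
read: filtering does not change the sequencing depth of a library. cpm
values used for filtering are raw (`r/R × 10⁶`, no 0.5 offset) — the
offset belongs to the log transform only.

# The simulator

`simulate_nb_counts()` emulates a two-group count experiment:

* **Baseline proportions.** Each gene receives a relative expression
  proportion; defaults draw from a log-normal with log-scale sd 2.0 and
  normalize, giving a heavy-tailed distribution spanning roughly five
  orders of magnitude — a realistic dynamic range for bulk RNA-seq.
  An empirical cpm distribution from a reference dataset would be the
  ideal source; any user-supplied positive vector can be plugged in via
  `baseline_proportions(empirical = )`. The stand-in changes absolute
  power numbers modestly but not the qualitative contrasts between
  engines, which is what the benchmark asserts.
* **Study conditions.** 10,000 genes, two groups of three libraries;
  equal layout: all libraries at 11 million reads; unequal layout:
  odd-numbered libraries at 20 million and even-numbered at 2 million —
  the same 66 million total, distributed unevenly. The power scenario
  upregulates 100 randomly chosen genes twofold in each group (200 DE
  genes total); fold changes multiply expected counts without
  renormalizing the proportions.
* **Dispersions.** The trend is $\psi^{1/2} = 0.2 + \lambda^{-1/2}$,
  asymptoting to a 20% biological CV for large counts; gene-wise scatter
  $\delta_g$ has $40/\delta_g \sim \chi^2_{40}$, with a log-normal
  (sd 0.25) alternative matched in log-scale spread. The observation
  dispersion is $\phi_{gi} = \psi_{gi}\delta_g$, with the trend evaluated
  at the *realized* expected count (fold change included) — the trend is
  a property of the expected count of the observation, wherever that
  count comes from.
* **Sampling.** Counts are gamma-Poisson draws with shape $1/\phi$ and
  mean $\lambda$, which is the negative binomial for any positive
  (including non-integer-shape) $\phi$ and collapses to Poisson at
  $\phi = 0$. Everything is bit-reproducible from the configuration seed.

What the simulator does *not* emulate: empirical cpm distributions from
real tissue, isoform structure, GC or length biases, outlier samples, and
correlated genes. Passing benchmarks under these conditions shows the
engines behave correctly when their distributional assumptions hold (the
NB model is in fact the home ground of the count-based competitors, not
of the normal-theory engines tested here); it does not certify behaviour
under real-data pathologies.

# The evaluation harness

`run_benchmark()` repeats simulation plus analysis end-to-end: genes with
fewer than 10 total reads are filtered, each engine is fitted, and the
group-effect p-values are scored — the proportion below nominal cutoffs
(strict inequality) in the null scenario; true/false positives and the
empirical false discovery proportion $FP/\max(1, TP+FP)$ among BH calls
at $q < 0.1$; and the false discovery curve (non-DE genes among the top
$k$, ties broken stably by gene index) in the power scenario.
Per-simulation seeds derive deterministically from the master seed and
Monte-Carlo standard errors accompany every averaged quantity, so that
any tolerance applied to the averages can be stated in units of
simulation noise.

The default of 25 simulations keeps a full benchmark in the tens of
seconds on one CPU while leaving Monte-Carlo standard errors small
relative to the margins being tested (e.g. type I error means get a
standard error near 0.0002 at cutoff 0.01); `n_sims` scales it up when
tighter error bars are wanted.

# Known limitations

* Missing values in the expression matrix are not supported (the
  moderation machinery accepts heterogeneous residual df, so pre-filtered
  heterogeneous designs still work).
* The baseline-proportion stand-in is parametric; absolute power levels
  depend on it.
* Rotation p-values have granularity $1/(B+1)$; very small p-values need
  large $B$.
* No robust variant of the variance prior is provided: hypervariable
  genes influence $d_0$ through the moment equations (the LOWESS trend,
  by contrast, is robust).
* The spike-in benchmark constructor builds the truth table only; it does
  not simulate the spike-in count data themselves.

# Interfaces

All functionality is exposed as plain R functions returning classed S3
objects (`count_matrix`, `logcpm`, `genefit`, `ebfit`, `voom`,
`meanvar_trend`, `voom_lm`, `geneset_result`, `eval_result`) with
`print`/`summary`/`coef`/`fitted`/`residuals`/`plot` methods where they
make sense. File-based interfaces cover the tab-delimited count matrix
(and MatrixMarket with sidecar label files), tab-delimited design and
contrast matrices, GMT gene sets, and a two-column library-size/factor
table. `scripts/acceptance.R` is the scripted entry point that re-runs
the benchmark protocols and emits JSON.
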