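---
title: "Discovering network module biomarkers by discriminative activity area"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering network module biomarkers by discriminative activity area}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modisa)
```

## The model

`modisa` looks for *module biomarkers*: connected gene sets in a
protein–protein interaction (PPI) network whose joint expression separates
two phenotype groups. The working model has three parts.

**Activity.** The activity of a module $M$ with $k$ member genes in a
sample is $a(M) = \sum_{g \in M} a(g) / \sqrt{k}$, the member-gene sum
scaled by $\sqrt{k}$. For independent genes with unit variance this scaling
keeps the activity variance at 1 regardless of module size, so modules of
different sizes compete on a common scale, and the group-mean gap of a
module of $k$ genes each shifted by $e$ grows as $e\sqrt{k}$ — joint
activity amplifies per-gene signal.

**Normality.** Within each phenotype group the activity is modelled as
Gaussian. This is an assumption, not a theorem: it is exact when member
genes are jointly Gaussian (as in our generator) and approximately right
for sums of many weakly dependent genes, but heavy-tailed expression or
outlier samples can break it. All downstream separation statements inherit
this assumption.

**Discriminative area.** With $N(\mu_N, \sigma_N)$ fitted to control
activities and $N(\mu_C, \sigma_C)$ to case activities (sample moments,
denominator $n-1$), the module's discriminative area is the overlap of the
two densities,
$$\mathrm{disa}(M) = \int \min\!\big(\varphi(x;\mu_N,\sigma_N),\,
\varphi(x;\mu_C,\sigma_C)\big)\,dx \in [0,1].$$
It equals 1 when the groups are indistinguishable and tends to 0 as they
separate; unlike a t-statistic it reacts to variance differences as well as
mean differences, and it is invariant to shifting or rescaling both groups
together.

`gaussian_overlap()` evaluates the integral in closed form. Setting the two
log-densities equal gives a quadratic in $x$; with unequal SDs it has two
real roots, and the overlap is the sum of Gaussian CDF segments taking the
lower density on each interval. When $|\sigma_N - \sigma_C| < 10^{-12}$ the
computation routes to the single-crossing formula
$2\Phi(-|\mu_N-\mu_C|/2\sigma)$ (the quadratic is ill-conditioned there).
Which density is lower between the roots is decided on the *log* scale:
when both distributions are far from the crossing interval the raw
densities underflow to zero and the comparison would be arbitrary. If the
root arithmetic ever fails (non-finite discriminant), a piecewise adaptive
quadrature with breaks at both means is the fallback. The tests compare the
closed form against an independent quadrature oracle that locates crossings
by sign-scan plus `uniroot` on the log-density difference; agreement is at
the $10^{-12}$ level.

## The pipeline and its parameters

| stage | function | parameter (default) | role |
|---|---|---|---|
| z-score | `zscore_rows()` | `ddof = 1` | per-gene standardization across all samples |
| seeds | `gene_t_tests()`, `select_seeds()` | `alpha_seed = 0.01` | BH-adjusted Welch t-test threshold |
| growth | `grow_module()` | `delta = 0.001` | stop once disa < delta |
| growth | | `max_module_size = 50`, `require_improvement = TRUE` | termination guarantees (see below) |
| filter | `discover_modules()` | `disa_filter = 0.2` | discard weakly discriminative modules |
| selection | `score_modules()` | `alpha_enrich = 0.05` | BH-adjusted hypergeometric threshold defining MF |
| validation | `crossvalidate()` | `n_folds = 10`, `cost = 1` | linear-SVM CV |
| robustness | `noise_robustness()` | `n_reps = 100` | training-label noise repetitions |

Z-scoring is computed per gene across all samples pooled (both groups),
with the sample SD; the sign convention is the usual $(x-\bar x)/\sigma$.
Pooling is deliberate — standardizing within groups would erase the very
group difference the method hunts for. The t-test defaults to Welch's
unequal-variance form (identical to the pooled test when variances agree,
robust when they do not); `equal_var = TRUE` restores the pooled test.

**Greedy growth and termination.** The growth rule is pure forward
selection: evaluate disa$(M \cup \{g\})$ for every network neighbour $g$ of
the current members and accept the minimizer. A threshold stop alone
(disa < `delta`) does not guarantee termination — a seed in a noise region
may never reach it — so growth also stops when the neighbour set is
exhausted, when the best candidate no longer *strictly* lowers disa
(`require_improvement`), or at `max_module_size`. Setting
`require_improvement = FALSE` and a large cap recovers the bare
threshold rule. Members are never removed once added; candidate ties
within $10^{-12}$ break lexicographically by gene ID, making growth fully
deterministic. Candidates whose addition gives zero within-group activity
variance (a degenerate Gaussian fit) are skipped, not fatal.

The `disa_filter = 0.2` cut discards modules whose group distributions
still share a fifth of their area. Surviving modules are typically highly
redundant — their activities correlate strongly because they overlap or
share network neighbourhoods — so `activity_correlations()` is provided as
a *diagnostic*, not a filter: redundancy says the modules are
interchangeable, not that any is wrong.

**Functional selection.** Discriminative power alone overfits the
expression data at hand, so the winning module is chosen by annotation:
each module's enriched pathways (MF; hypergeometric upper tail with the
post-restriction network gene set as universe, BH across the catalogue,
adjusted p < `alpha_enrich`) are compared against the disease-background
set (DMF) with the bidirectional best-match average of Jaccard indices,
$$\mathrm{sim}(PS_1, PS_2) = \frac{\sum_i \max_j J(ps_{1i}, ps_{2j}) +
\sum_j \max_i J(ps_{2j}, ps_{1i})}{m + n}.$$
A module with an empty MF scores 0 and ranks last rather than erroring —
poor annotation should lose, not crash the run. DMF gene sets are
intersected with the analysis universe first (configurable), since genes
absent from the network cannot be evidence either way. The enrichment
threshold defining MF is a genuinely open choice; 0.05 on BH-adjusted
p-values matches the package's other multiplicity corrections and is
exposed as `alpha_enrich`.

**Validation.** The classifier contract is a maximum-margin linear
separator (`e1071::svm`, linear kernel) with fixed regularization
`cost = 1` on z-scored features; fold partitions are stratified so per-fold
class proportions stay within one sample of the global ones. AUC uses the
midrank (rank-sum) formulation, robust to tied scores. Label noise is
injected into *training* folds only — flipping test labels would corrupt
the measurement, not the learning problem. The 95% interval reported per
noise fraction is the normal approximation mean $\pm 1.96\,\mathrm{SD}/\sqrt{R}$
alongside empirical 2.5/97.5 percentiles, since "confidence interval" has
no canonical definition for repeated-CV accuracies.

## The synthetic generator

`generate_instance()` emulates the statistical structure the method
assumes, with known ground truth. The network is Erdős–Rényi
(`background_edge_prob = 0.02`, mean degree ≈ 6 at 300 genes — sparse, like
a filtered PPI network); the planted module is made connected by a random
spanning tree plus random internal edges (internal edge probability 0.3,
denser than background, as interacting disease genes tend to be).
Background genes are i.i.d. standard normal in both groups; planted genes
gain a mean shift of `effect` (in within-group SD units) in case samples.
The defaults — 300 genes, 60 samples per group, a 10-gene planted module,
`effect = 1.5` — put the planted module's theoretical disa at
$2\Phi(-1.5\sqrt{10}/2) \approx 0.018$: clearly below the 0.2 filter, while
individual planted genes are strong but not trivial seeds. The catalogue
holds 30 random gene sets of 8–15 genes; 10 form the disease background,
half of them forced to contain ≥ 50% planted genes (`dmf_overlap = 0.5`) so
functional selection has signal but also decoys.

What the generator does *not* emulate: heavy-tailed microarray noise,
probe-level artefacts, batch effects, correlated background genes,
scale-free degree distributions, or cross-dataset heterogeneity. Passing
tests on synthetic data therefore demonstrate the algorithmic contract —
recovery of a planted signal under the model's own assumptions — not
performance on real cohorts.

## Numerical and design notes

- Gene identifiers match by exact, case-sensitive string equality
  throughout; no symbol aliasing.
- Phenotype labels normalize through a configurable alias map
  (NGT/control/normal → NORMAL; DM/T2DM/case/disease → CASE,
  case-insensitively); anything unmapped is an error so intermediate
  phenotypes must be handled explicitly.
- Seed counts are data-dependent output; the seed threshold is a parameter,
  not a target.
- `run_pipeline()` skips the noise-robustness stage unless
  `noise_fractions` is set: it multiplies runtime by
  `length(fractions) × noise_reps` and validates the *selected* biomarker
  rather than informing selection. `noise_robustness()` is a first-class
  stage on its own.
- All stochastic stages (fold partitions, noise flips, the generator) are
  driven by explicit integer seeds; identical seeds give identical results,
  and noise repetitions share one fold partition so a zero-noise repetition
  reproduces the baseline exactly.
- Degenerate inputs fail loudly and early: constant expression rows at
  z-scoring, empty gene-universe intersections, non-binary labels, zero
  seeds and zero surviving modules raise typed conditions
  (`modisa_no_seeds`, `modisa_no_modules`) that the CLI maps to distinct
  exit codes.
- Problem sizes in the test suite follow the generator defaults (300 genes,
  60/group, 20 replicate instances for recovery and null studies, 100
  noise repetitions); these are the package's benchmark conditions.

## Known limitations

The greedy search is myopic: it cannot recover a module whose genes are
only jointly (not marginally) informative, and forward-only growth never
revisits an early mistake. The Gaussian activity model can be violated by
multimodal or heavy-tailed expression. The hypergeometric test treats
genes as exchangeable, ignoring network topology inside pathways. And with
many seeds the surviving modules are heavily redundant; interpretation
should lean on the top-scored module plus the correlation diagnostic, not
on the raw module count.
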