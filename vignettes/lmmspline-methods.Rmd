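---
title: "Modelling time-course omics data with penalized spline mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling time-course omics data with penalized spline mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A time-course omics experiment measures thousands of molecules
(transcripts, proteins) on several subjects at a handful of time points.
Three features make the analysis awkward: most profiles are noise with no
temporal signal; subjects differ systematically from one another; and the
number of time points (typically 4--6) is far too small to fit a flexible
curve per molecule without strong regularization. `lmmspline` addresses
these with a three-stage workflow: (1) noise-based filtering, (2)
per-molecule modelling with penalized spline mixed models selected
serially by likelihood-ratio tests, and (3) downstream analysis of the
modelled trajectories -- trajectory-level differential expression and
cluster analysis.

# Stage 1: filtering by variance ratios

For molecule values $y_i(t)$ (subject $i$, time $t$) define

* $s_T$: the mean over time points of the SD across subjects at that
  time,
* $s_I$: the mean over subjects of the SD across that subject's time
  points,
* $s_M$: the overall SD,

and the ratios $R_T = s_T / s_M$, $R_I = 1 - s_I / s_M$. A profile of
pure noise has each per-time SD close to the overall SD, so $R_T \approx
1$; genuine change over time inflates $s_M$ relative to $s_T$, so $R_T <
1$. $R_I$ is near 0 for both noisy and well-behaved profiles and mainly
flags profiles dominated by subject-level variance. Missing cells are
excluded from every sum with denominators reduced; groups (time points or
subjects) reduced below two present values are skipped from the
respective mean; a constant profile ($s_M = 0$) has undefined ratios and
is treated as non-informative.

Molecules with more than 50% missing values are removed outright.
The remaining $(R_T, R_I)$ points are classified by a two-component
Gaussian mixture (`mclust`, two clusters); the component with the larger
mean $R_T$ is the noise side. For multi-condition designs the
classification runs within each condition and a molecule is removed only
if non-informative in *every* condition, so profiles that are flat in one
arm but active in another survive.

This stage assumes subjects share sampled time points, with at least
three present values per time point for the per-time SDs to be stable.
Data from adaptive sampling designs should be binned to a common grid
before filtering; the package does not bin automatically.

# Stage 2: serial spline modelling

Each molecule is modelled on a truncated line basis with knots
$\kappa_1 < \dots < \kappa_K$:

$$f(t) = \beta_0 + \beta_1 t + \sum_{k=1}^K u_k (t - \kappa_k)_+ .$$

The knot count follows $K = \max(5, \min(\lfloor T/4 \rfloor, 40))$ with
$T$ the number of distinct time points, and knots sit at equally spaced
empirical quantiles (type-7, probabilities $k/(K+1)$) of the observed
time values including replicate multiplicity. With few distinct times
this rule produces duplicate knot values; duplicates are collapsed, so
the effective basis can be smaller than $K$. The penalty keeps the
remaining near-collinearity harmless.

The spline coefficients are *random effects*, $u_k \sim N(0,
\sigma^2_u)$: this is the standard mixed-model representation of a
penalized spline, with implied ridge penalty $\lambda =
\sigma^2_\varepsilon / \sigma^2_u$ chosen by the likelihood rather than
by a tuning constant. Four nested models are fitted in order of
complexity:

| class | name | structure |
|---|---|---|
| 0 | LIN  | straight line, ordinary least squares |
| 1 | SPL  | penalized spline |
| 2 | SSI  | SPL + subject random intercept $U_i$ |
| 3 | SSIS | SPL + subject random intercept and slope (independent) |

A more complex class is retained only when a likelihood-ratio test at
level $\alpha$ (default 0.05, exposed as an argument) rejects the simpler
one; selection stops at the first non-promotion. Each step adds one
parameter, so the reference is $\chi^2_1$. No 50:50 boundary mixture is
used for the variance-component steps; the resulting conservatism is
accepted deliberately -- it biases selection towards simpler models,
never towards spurious complexity.

Estimation details: variance ratios are profiled out of the likelihood
and optimised on the log scale (Nelder-Mead for two or more components,
golden-section for one), with log-ratios clamped to $[-30, 15]$, at most
200 outer iterations and relative tolerance $10^{-8}$; non-convergence is
a recorded flag, never a silent failure. Variance components are
*reported* under REML, but every likelihood-ratio comparison uses ML
log-likelihoods so that models differing in fixed effects remain
comparable. The population curve uses the REML coefficient estimates and
spline BLUPs.

The derivative of the fitted curve,
$f'(t) = \hat\beta_1 + \sum_k \hat u_k \,[t \ge \kappa_k]$, is piecewise
constant between knots and gives a rate-of-change profile; for a LIN fit
it is the constant slope. Clustering these derivative profiles groups
molecules by response *speed* rather than magnitude.

# Stage 3a: trajectory-level differential expression

With $R$ groups and indicators $h_{ir}$, the full group-aware mean curve
is

$$f_{h_i}(t) = \beta_0 + \beta_1 t + \sum_k u_k (t-\kappa_k)_+
 + \sum_{r \ge 2} h_{ir}\big(\alpha_{0r} + \alpha_{1r} t\big)
 + \sum_{r \ge 2} h_{ir} \sum_k v_{rk} (t-\kappa_k)_+ ,$$

with the group offset splines $v_{rk}$ penalized like $u_k$. Three
nested-model ML likelihood-ratio tests are provided:

* **time** -- full: common curve; null: intercept only. df = 2 by
  default: the slope plus one variance component for the spline block.
* **group** -- full: common spline plus group intercept offsets
  $\alpha_{0r}$; null drops the offsets; *neither* model carries the
  linear slope ($\beta_1 = 0$, $\alpha_{1r} = 0$). df = $R-1$. A
  `spline_df = "fixed"` mode and the slope-restoring variant exist for
  sensitivity analysis.
* **interaction** -- full: group-specific intercepts, slopes and offset
  splines; null: common shape plus group intercepts. df = $2(R-1)$.

Counting each penalized spline block as one degree of freedom (its
variance component) is a convention; since the convention is not uniquely
determined, the `spline_df = "fixed"` mode treats spline coefficients as
fixed effects and counts $K$ per block instead. Both models of a test
share the subject-level random structure; the default adds a subject
random intercept whenever a subject has repeated measures
(`random = "auto"`).

P-values are adjusted across molecules within each effect by
Benjamini-Hochberg; non-converged fits are reported untested and excluded
from the adjustment. Filtering before testing (the per-condition rule) is
optional and reduces the number of tests; it is appropriate here because
the tests are per-molecule likelihood ratios, not moderated statistics
with pooled posterior variances.

The full model is refitted from a boundary warm start (its extra blocks
switched off, shared blocks at the null's fitted ratios) whenever the
optimiser returns a full-model likelihood below the null's, which
enforces the nesting inequality numerically.

# Stage 3b: clustering

Modelled curves (or derivatives) are evaluated on the sorted distinct
observed times by default and clustered with five standard algorithms:
hierarchical (complete linkage), k-means, PAM, a one-dimensional
self-organizing map of length $k$ (100 epochs, nodes = clusters, best of
10 seeded restarts, written in-package since no SOM package is
available), and Gaussian-mixture model-based clustering. Euclidean
distance is the default for every input (a correlation distance is an
option); curves are not standardized by default, so clusters may separate
by magnitude as well as shape -- z-scaling is a flag. The single
selection criterion across algorithms and $k \in \{2,\dots,9\}$ is the
Dunn index (smallest inter-cluster distance over largest intra-cluster
distance); ties prefer smaller $k$, then the listed algorithm order, and
degenerate all-singleton solutions (infinite Dunn) are excluded unless
requested.

Cluster relevance is scored by hypergeometric over-representation of
user-supplied annotation sets (e.g. GO-style term $\to$ molecule lists),
with BH adjustment within cluster and terms overlapping a cluster in at
most one molecule dropped. The package performs no annotation retrieval
or identifier mapping.

# The simulation benchmark

The generator emulates a two-arm longitudinal study: 140 molecules, 30
subjects (10 + 20), times 0, 0.5, 1, 2, 3, 4 weeks, 50 molecules
differentially expressed. Effects are parameterised by a fold change
`fc` with magnitude $\Delta = \ln(\mathrm{fc})$ (natural-log scale by
default, base-2 selectable): a linear increase totalling $\Delta$ over
the time range (time effect), a constant between-group offset $\Delta$
(group), or opposite group slopes $\pm\Delta$ over the range
(interaction). Non-differential molecules are flat at zero. Noise is
i.i.d. Gaussian with SD `noise_level * sigma0`.

The absolute noise scale `sigma0` is the generator's single free
parameter. It is fixed once by bisection so that the mean sensitivity of
the anchor cell (time effect, noise 1, fc 1.5) matches 0.981, and then
frozen for every other cell, which makes all remaining cells out-of-sample
checks. The bisection reuses the same per-dataset seeds at every step
(common random numbers), making the measured sensitivity monotone in
`sigma0` up to Monte-Carlo noise. `scripts/acceptance.R` runs this
protocol at 20 datasets per cell (2,800 modelled profiles per cell), a
problem size chosen so the whole benchmark completes in minutes on one
core while keeping the Monte-Carlo SE of a cell mean below 0.01.

What the generator deliberately leaves out: per-molecule heterogeneity.
Every simulated molecule shares one residual SD and every differential
molecule one effect size, so the power of a test is essentially a single
number per cell and the sensitivity-versus-fold-change curve is steep --
small fold changes at high noise yield near-zero sensitivity, and cells
just above the detection boundary yield near-one. Real omics data have
molecule-specific noise and effect distributions, which *flatten* the
averaged power curve: mixtures of easy and hard molecules produce
intermediate sensitivities over a much wider range of conditions. Passing
benchmarks under this generator therefore demonstrates calibration and
ranking behaviour of the tests, not the exact sensitivity values to
expect on real data.

# Numerical and design choices

* **Missing values** are first-class (`NA`), excluded from sums with
  denominators reduced; fits drop missing observations row-wise.
* **Degenerate profiles** (constant; or all per-time groups below two
  present values) get undefined ratios and are treated as
  non-informative rather than erroring.
* **Mixture fallback**: if the two-component classification collapses
  (e.g. identical ratio points), all molecules are kept with a warning --
  filtering should fail open, not discard data.
* **Tie-breaks** are deterministic everywhere (documented above for
  clustering; component identification by mean $R_T$, then mean $R_I$).
* **Seeds**: every stochastic step takes an explicit seed; the composite
  pipeline fans one master seed out to stages, and rerunning a
  configuration reproduces output files byte for byte.
* **Serial selection with one subject** stops at class 1; class 3 needs
  two subjects with repeated measures.

# Known limitations

* Only the truncated *line* basis is implemented; cubic and penalized
  cubic bases are reserved in the interface but not available.
* The filter requires shared time points across subjects; no automatic
  binning.
* Subject-level clustering (grouping individuals rather than molecules)
  is out of scope.
* The $\chi^2$ reference without boundary correction makes
  variance-component tests conservative; promotion and detection rates
  at the nominal level are therefore slightly below it.
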