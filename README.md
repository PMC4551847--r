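# lmmspline

Linear mixed model splines for time-course omics data.

Time-course transcriptomics and proteomics experiments measure thousands
of molecules on a few subjects at a few time points. Most profiles are
noise; subjects differ systematically; and 4–6 time points cannot support
an unpenalized flexible curve per molecule. `lmmspline` implements a
three-stage framework for such data:

1. **Filtering.** Per-molecule variance ratios
   `R_T = s_T / s_M` and `R_I = 1 − s_I / s_M` (mean per-time SD and mean
   per-subject SD, each against the overall SD) separate noise-only
   profiles (`R_T ≈ 1`) from profiles with temporal signal (`R_T < 1`).
   Molecules over 50% missing are dropped; the rest are classified by a
   2-component Gaussian mixture on `(R_T, R_I)`, per condition, removing
   only molecules non-informative in *every* condition.
2. **Modelling.** Each molecule gets a penalized truncated-line-basis
   spline `f(t) = β0 + β1 t + Σ u_k (t − κ_k)_+` whose coefficients `u_k`
   are random effects (implied ridge penalty `σ²_ε/σ²_u`), optionally
   augmented with subject random intercepts/slopes. The four nested
   classes (line / spline / + subject intercept / + subject slope) are
   selected serially by ML likelihood-ratio tests. Derivative profiles
   `f′(t)` expose rates of change.
3. **Analysis.** Trajectory-level differential-expression tests for
   time, group and group×time effects (nested-model likelihood ratios,
   Benjamini–Hochberg FDR), and clustering of modelled trajectories with
   the Dunn index selecting both algorithm and cluster number, plus
   hypergeometric enrichment of user-supplied annotation sets.

A simulation module generates benchmark datasets (140 profiles, 50
differentially expressed, 10 + 20 subjects, 6 time points) and scores
calls by sensitivity/specificity.

## Worked example

```r
library(lmmspline)

sc <- sim_scenario("time", noise_level = 1, fc = 2, sigma0 = 0.4)
ds <- simulate_dataset(sc, seed = 7, index = 1)
ds$experiment
#> Time-course experiment: 140 molecules x 180 samples
#>   subjects: 30  distinct times: 6
#>   groups: g1=60, g2=120

fl <- filter_experiment(ds$experiment, per_group = TRUE, seed = 7)
n_molecules(fl$experiment)
#> [1] 65
```

Filtering keeps 65 of 140 molecules: all 50 with a real time trend plus
some noise profiles whose ratios happened to fall on the informative
side. Modelling then selects a class per molecule — here every trend is
linear by construction, so the class table concentrates on LIN:

```r
mod <- lmms_model_all(fl$experiment, derivative = TRUE)
mod$class_counts
#>  LIN  SPL  SSI SSIS
#>   65    0    0    0
```

Differential expression over time on the unfiltered data recovers the
planted truth exactly at this effect size (FC 2, low noise):

```r
de <- lmmsde(ds$experiment, effects = "time")
sum(de$significant)
#> [1] 50
evaluate_de(de, ds$truth)
#> sensitivity specificity
#>           1           1
```

Clustering the fitted curves separates the rising trend family from the
flat one:

```r
sel <- select_clustering(mod$curves,
                         algorithms = c("hierarchical", "kmeans", "pam"),
                         k_range = 2:5, seed = 7)
c(sel$best$algorithm, sel$best$k, round(sel$best$dunn, 3))
#> [1] "hierarchical" "2" "1.887"
```

A command-line front end over the same functions lives at
`inst/cli/lmmspline-cli.R` with subcommands `filter`, `model`, `de`,
`cluster`, `simulate`, `benchmark` and `run` (the composite pipeline;
fixed seeds give byte-identical outputs).

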