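# profclust

Time-course expression profile regression and clustering for
treatment-versus-control studies.

## The problem

A common design in nutrition, growth-promoter and pharmacology studies
profiles a tissue transcriptome in a treated arm and a control arm across a
handful of sampling days (here: days 1, 3, 7, 13 and 27, with about ten
animals per arm per day and more at the final day, animals cross-sectional —
each is sampled once).  The scientific questions are: which probes change
over time in response to treatment, and which groups of probes share a
temporal response shape?

`profclust` implements the two-stage regression strategy popularised by
maSigPro for exactly this situation, extended with a data-driven choice of
the number of k-means clusters, and pairs it with a planted-template
synthetic-data generator so the whole pipeline can be benchmarked without
any external data.  It is aimed at analysts who want a small, deterministic,
fully-testable reference implementation of this analysis.

## The model

Each probe's log-intensity is regressed on a polynomial in log-transformed
time `T = log(t)` with treatment-contrast terms (degree 2 by default):

```
y = b0 + b1 T + b2 T^2 + g (c0 + c1 T + c2 T^2) + e
```

where `g` is the treated-arm indicator, so `c0 + c1 T + c2 T^2` is the
treated-minus-control difference curve.  The log time scale stops days 13
and 27 from dominating the fit.  The pipeline is then:

1. **Stage-1 filter** — global F-test of the full model against
   intercept-only; keep probes with `p < 0.05` (raw by default,
   Benjamini-Hochberg optional).
2. **Stage-2 stringency** — backward stepwise term elimination at
   `alpha = 0.05` per term; keep probes whose reduced model reaches the
   R-squared stringency tier (0.5 stringent; 0.2 relaxed, for
   low-amplitude/high-variability responses).
3. **Clustering** — z-score each survivor's fitted treated-minus-control
   difference at the grid days and run seeded k-means over a range of k;
   the mean silhouette picks k, a gap-statistic comparison guards the
   single-cluster case, and fewer than 5 survivors yield the degenerate
   zero-cluster outcome.

Supporting statistics used around such studies are included: per-day Welch
differential expression with Venn overlap counts and top-n overlap
percentages, batch-blocked two-way ANOVA with SED
(`sqrt(MSE (1/n1 + 1/n2))`), one-way ANOVA, and Dunnett many-to-one
comparisons via seeded Monte-Carlo of the correlated max-|t| null.

## Worked example

Simulate the BA-mimic benchmark (nine planted temporal templates at
amplitude 5x the replicate sd, 50 probes each, seven extra probes of one
gene sharing the early-peak template, 1000 null probes), fit the contrast
and cluster the survivors:

```r
library(profclust)
sim <- simulate_study(preset_ba_mimic(seed = 1))
fit <- tc_fit(sim$expr, sim$design, contrast = "ba")
print(fit)
#> time-course fit: 1457 probes, contrast BA vs control, degree 2
#>   global p < 0.05: 501 probes; selected-model R2 >= 0.5: 457; >= 0.2: 457

cl <- tc_cluster(fit, r2_threshold = 0.5, k_max = 15, seed = 1)
print(cl)
#> profile clustering, BA vs control (alpha 0.05, R2 >= 0.50):
#>   457 surviving probes in 9 cluster(s); sizes: 50, 50, 57, 50, 50, 50, 50, 50, 50

recovery_score(cl, sim$truth)$ari
#> [1] 1
```

Reading the output: 501 of 1457 probes pass the stage-1 F-test (the 450
planted + 7 multi-probe-gene probes plus a ~5% false-positive share of the
nulls); the R-squared 0.5 tier then removes every null survivor, and the
457 survivors fall into 9 clusters matching the 9 planted templates
exactly (adjusted Rand index 1), with the 7-probe gene sitting inside its
57-probe cluster.  `plot(cl)` draws the per-cluster mean treated and
control curves; `run_pipeline()` executes the whole thing (both contrasts,
both stringency tiers, per-day DE, reports) into an output directory.

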