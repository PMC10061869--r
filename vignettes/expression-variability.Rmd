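---
title: "Measuring gene expression variability decorrelated from expression level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gene expression variability decorrelated from expression level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exvar)
```

## The problem

Differential expression analysis compares *means*. A complementary question
is whether a gene's expression *variability* across donors differs between
groups: genes under tight regulatory control should vary little from person
to person (hypo-variable), while genes whose regulation is degraded or
responsive to individual genetic and epigenetic background vary a lot
(hyper-variable). Naive variability statistics are confounded with the
expression level itself: for RNA-seq counts, the coefficient of variation
(CV = SD/mean) and the standardized MAD (d = MAD/median) both shrink
systematically as expression rises, so ranking genes by CV mostly ranks them
by how weakly they are expressed.

`exvar` implements an expression-variability (EV) statistic built to be
uncorrelated with expression magnitude, together with the filtering,
classification, confirmation and enrichment stages that turn it into a
donor-group comparison, and a negative-binomial simulator that generates
data with known hypo-/hyper-variable truth so every stage can be tested.

## The EV statistic

For each gene within one donor group x radiation dose stratum:

1. Counts are normalized with median-of-ratios size factors
   (`compute_size_factors()`): `s_j` is the median over reference genes
   (genes positive in every sample) of `count_gj / gm_g`, with geometric
   means computed in log space.
2. `MAD_obs` is the median over `B` bootstrap resamples of the sample MAD of
   the normalized counts (`bootstrap_mad()`; `B = 1000` by convention, the
   MAD scaled by the normal-consistency constant 1.4826).
3. `MAD_pred` is a loess prediction of `MAD_obs` from `log1p(median
   expression)`, fitted over all genes of the stratum (`fit_expected_mad()`;
   span 0.75, degree 2). It captures the mean-variability trend every count
   model imposes: for a negative binomial, `var = mu + phi * mu^2`, so the
   raw MAD necessarily grows with `mu`.
4. `EV = MAD_obs - MAD_pred`, in normalized-count units. A gene on the
   common trend has EV near 0 regardless of its expression level; the trend
   is absorbed by the loess rather than by dividing by the mean, which is
   what decorrelates EV where CV and d stay confounded.

The loess response/predictor pair is not dictated by convention elsewhere;
we regress the observed MAD on `log1p` of the median normalized count, per
stratum, because the log transform tames the leverage of highly expressed
genes and per-stratum fitting lets the trend differ between doses. A pooled
fit across strata is available (`per_stratum_loess = FALSE`).

## Excluding bimodally expressed genes

EV assumes one expression state whose width is being measured. Genes with
two expression states (on/off regulation, strong differential expression
between donor groups, sex-linked expression) would be flagged hyper-variable
for the wrong reason. Per dose, with all donor groups pooled,
`filter_bimodal()` fits each gene a two-component log-normal mixture by EM
and computes the bimodality index

  BI = sqrt(pi (1 - pi)) |mu1 - mu2| / sqrt(pi sigma1^2 + (1 - pi) sigma2^2),

the classical index generalized to unequal component SDs (it reduces to the
standard form when sigma1 = sigma2 and is invariant to label swapping).
Genes with BI >= 1.1 are excluded; sensitivity analyses on reduced sample
sizes use 1.3, because the index's sampling noise grows as n falls
(`apply_strata()` flags reduced data and the pipeline switches cutoffs
automatically).

Counts below `eps = 10` are treated as left-censored and dropped from the
fit; when more than `zero_percent_thr = 20%` of a gene's counts are censored
the gene is reported *ineligible* and retained, since bimodality cannot be
assessed from the remainder. This censoring convention is this package's
documented choice. EM details: natural-log values, best of 5 starts (a
2-means split plus 4 random perturbations), ties broken toward balanced
mixing proportions, convergence at relative log-likelihood change `1e-8` or
500 iterations, component SDs floored at `1e-3` of the sample SD to prevent
degenerate spikes. The observed-data log-likelihood is checked to be
non-decreasing on every fit and the flag is exported (`monotone`).
The mixture is fitted on pooled donor groups per dose; a per-group fit can
be emulated by calling `filter_bimodal()` on a group subset.

## Classification and split-half confirmation

Classification is anchored in the reference donor group (cancer-free
controls, N0): per dose, the interval is

  Median_EV(N0) +/- k * MAD_EV(N0),  k = 3,

with `MAD_EV` again a bootstrap-median MAD (`reference_interval()`). All
donor groups are classified against the *reference* interval, not their own,
so a group-specific widening of expression variability shows up as an excess
of hyper-variable calls in that group. EVs below the interval are
hypo-variable, above are hyper-variable; values exactly on a boundary count
as non-variable (closed interval — the conservative convention).

Because a 3-MAD interval on noisy EVs still mislabels tail genes,
classifications are confirmed by split-half cross-validation
(`crossvalidate()`): `R = 10` times, every donor group is split in half at
random (by matched triplet, so the three donors of a triplet stay together;
individual-level splitting is available), the complete EV and classification
pipeline is rerun on each half with the reference interval re-estimated from
that half, and a repeat counts as a success for a gene if both halves
reproduce the whole-data label. Success counts are tested against a fair
coin (one-sided binomial, alternative p > 1/2), BH-adjusted within each
donor group x dose, and unconfirmed hypo/hyper labels are reset to
non-variable. The bimodality filter is *not* re-run inside splits: the gene
universe per dose stays fixed. The whole-data concordance component of a
success uses the already-computed whole-data label rather than a re-run;
with a fixed gene universe the two are identical.

Two properties of this confirmation step matter for interpretation:

* It is deliberately conservative. Halving the sample size inflates both
  each gene's EV noise and the reference `MAD_EV` by about `sqrt(2)`, so
  only genes whose full-data EV clears the interval with a margin of roughly
  three sigma are reproduced in nearly every split. Confirmed hypo/hyper
  sets are therefore strict subsets of the whole-data sets — the test suite
  verifies this subset property on every synthetic run — and the *confirmed*
  sensitivity to a genuine dispersion change is substantially below the
  whole-data sensitivity (on the suite's 8-fold dispersion benchmark, about
  0.9 whole-data vs 0.6 confirmed for inflation; the suite reports both).
* The repeat count interacts with BH on discrete p-values. With R repeats
  the smallest attainable p is `2^-R`; at R = 5 that is 1/32, and a stratum
  then confirms either every perfectly concordant gene or none at all,
  depending on whether at least 62.5% of its genes are perfectly concordant.
  R = 10 avoids this cliff (10/10 and 9/10 successes both clear BH under
  mild conditions), which is why the default is 10 and why we do not scale R
  down in the acceptance runs even where the bootstrap is scaled down.

Detecting *deflated* dispersion (hypo-variability) is structurally harder
than inflation: an 8-fold dispersion increase raises the MAD by a factor
around 1.8, while an 8-fold decrease can lower it at most by a factor
`1/sqrt(8)` before hitting the Poisson floor `var = mu`, and EV itself is
bounded below by `-MAD_pred`. Confirmed hypo sensitivity is accordingly
lower than hyper sensitivity at the same effect size; the acceptance script
reports both rather than hiding the asymmetry.

## Competing metrics and set analysis

`variability_metrics()` computes CV and d per gene and stratum;
`metric_vs_expression()` reports Kendall's tau-b (tie-corrected, because
count-derived medians tie frequently) of each metric against median
expression, per group and pooled per dose. On trend-only synthetic data the
expected pattern is a strongly negative tau for CV and d and a tau near 0
for EV, with the raw observed MAD strongly positive — the signature that the
loess removed exactly the magnitude trend.

`exclusive_intersections()` decomposes the 9 confirmed gene sets (3 groups x
3 doses) per label into exclusive cells — each gene counted once, in the
cell matching its full membership pattern (what an UpSet plot draws); cell
counts sum to the union size by construction, and the suite asserts it.

`run_enrichment()` is a generic hypergeometric over-representation analysis
against GMT collections: upper-tail `P(X >= k)` per set, BH within each
query, and — following the background best practice — the background per
dose is the gene list retained after bimodality exclusion at that dose, not
the whole genome. Adjustment is per query (one family per tested gene
list); pooling across queries is not implemented.

## The synthetic-data generator

`simulate_counts()` emulates the study design the pipeline targets: three
donor groups (reference first) of 52 donors each, every donor measured at
three doses (0, 0.05, 2 Gy), matched triplets irradiated together, sex
matched within triplet, lifestyle covariates per donor. Counts are negative
binomial with mean `s_j * mu_g` (size factors uniform on [0.7, 1.4]) and
dispersion `phi(mu) = a/mu + b`, defaults `a = 3`, `b = 0.05` — a decreasing
mean-dispersion trend of the shape routinely estimated from bulk RNA-seq,
which makes the raw MAD rise with expression (the structure the loess must
remove). Baseline log-means are uniform on `log(50)`-`log(1500)`; this
range was calibrated once so that (i) CV shows the strong negative
association with expression and EV does not, and (ii) injected dispersion
classes are recoverable at n = 52 — within those constraints recovery proved
insensitive to the exact range. Truth injection:

* *hyper/hypo*: a fraction of genes (default 5% each) get their dispersion
  multiplied/divided by `effect` (> 1, default 8) in exactly one
  non-reference group, creating the group-exclusive sets the intersection
  stage looks for;
* *bimodal*: default 2% of genes draw each donor from one of two components
  whose log-means differ by 1.5 (a per-donor trait, consistent across
  doses and present in every group); the theoretical BI implied by the
  separation and the NB log-scale SD is stored in the truth table;
* *DE*: default 2% get a log-mean shift of 1 in one non-reference group.

What the generator does **not** emulate: batch and library-preparation
effects, gene-gene correlation, zero inflation beyond the NB, sex-linked
expression, and real biological dispersion heterogeneity beyond the single
trend — so green tests demonstrate that the machinery recovers the
structure it models, not that real fibroblast data satisfy that model.
One further honest caveat: with a wide expression range the EV noise is
heteroscedastic (high-expression genes have larger EV spread than the pooled
3-MAD interval anticipates), so even trend-only data yields a few percent of
tail misclassifications before confirmation; confirmation removes nearly
all of them.

## Numerical and reproducibility choices

* All randomness derives from one seed through `derive_seed(seed, tags...)`
  (a rolling string hash modulo 2^31 - 1): per-gene bootstrap streams are
  tagged by gene id, group and dose, so results do not depend on gene order;
  `bootstrap_mad()` sorts its input first, making it invariant to sample
  permutations.
* The bootstrap inner loop is compiled (Rcpp) but draws from R's RNG, so
  `set.seed()` fully determines it.
* Loess predictions outside the fitted predictor range are extended linearly
  from the boundary (relevant only when predicting for genes absent from the
  fit).
* Degenerate inputs: a zero-width reference interval classifies every
  unequal EV as hypo/hyper without error; all-tied vectors give `NA` Kendall
  tau; genes whose counts are all below `eps` raise an error, genes with too
  many censored counts are flagged ineligible and retained.

## Problem sizes in the shipped analyses

The `analysis/` scripts and the acceptance checks run at 1,000-5,000 genes
with the full 52-donor x 3-group x 3-dose design (or one dose where the
check is dose-independent) and `B = 200` bootstrap iterations; these sizes
were chosen so the whole workflow re-runs in minutes while keeping the
per-gene statistics at the study's sample size, which is what the power of
every stage depends on. `B` enters only through the Monte-Carlo noise of the
bootstrap median, which is already small at 200; `R` is kept at 10 for the
reason above.

## Limitations

* EV is a group-level statistic: it has no per-sample value, so it cannot
  feed per-sample classifiers directly.
* EV is not scale-free: unlike CV and d it changes under rescaling of the
  normalized counts (documented asymmetry; it is the price of
  decorrelation by subtraction).
* The confirmation step trades sensitivity for stability; studies needing
  higher recall should report whole-data labels alongside confirmed ones,
  as the classification table does.
* The mixture filter assesses bimodality on pooled groups per dose; a gene
  bimodal in only one group dilutes toward unimodality in the pool.
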