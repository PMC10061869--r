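# exvar — expression variability analysis for RNA-seq counts

Differential expression compares group *means*; `exvar` asks whether a
gene's expression *variability* across donors differs between groups. Naive
variability statistics — the coefficient of variation (CV = SD/mean) and the
standardized MAD (d = MAD/median) — are strongly confounded with expression
level, so they mostly rank genes by how weakly they are expressed. `exvar`
implements a decorrelated expression-variability statistic for raw RNA-seq
counts and the complete workflow around it, for transcriptomics analysts
comparing donor groups (here: cancer-free controls N0 vs childhood-cancer
survivors N1/N2+, fibroblasts irradiated at 0, 0.05 and 2 Gy):

1. **Normalization** — median-of-ratios size factors
   (`compute_size_factors()`).
2. **Bimodality filter** — per dose, a two-component log-normal mixture is
   fitted to each gene by EM and genes with bimodality index
   `BI = sqrt(pi(1-pi)) |mu1-mu2| / sigma_pooled >= 1.1` are excluded
   (`filter_bimodal()`; 1.3 for reduced, stratified samples).
3. **EV** — per gene and donor-group x dose stratum,
   `EV = MAD_observed − MAD_predicted`: the bootstrapped observed MAD
   (median of B = 1000 bootstrap MADs) minus a loess prediction of MAD from
   `log1p(median expression)` (`compute_ev()`). Subtracting the fitted
   mean–variability trend is what removes the expression-level confound.
4. **Classification** — genes are hypo-/non-/hyper-variable if their EV
   falls below/within/above the reference-group interval
   `Median_EV ± 3·MAD_EV` (`classify_whole()`), with the interval anchored
   in N0 for every group.
5. **Confirmation** — R = 10 random split-half repeats rerun the whole
   pipeline per half; per-gene concordance is tested against a fair coin
   (one-sided binomial), BH-adjusted, and unconfirmed labels are reset to
   non-variable (`crossvalidate()`).
6. **Comparison & downstream** — Kendall tau-b of EV/CV/d against median
   expression (`metric_vs_expression()`), exclusive set intersections of
   the 9 classifications (`exclusive_intersections()`), and hypergeometric
   over-representation analysis against GMT collections with per-dose
   retained-gene backgrounds (`run_enrichment()`).

Because the study's raw counts are not publicly deposited, the package
ships a negative-binomial simulator with known ground truth
(`simulate_counts()`): mean–dispersion trend `phi(mu) = 3/mu + 0.05`,
3 donor groups x 52 donors x 3 doses, matched triplets, and injected
hyper-/hypo-variable, bimodal and differentially expressed genes. Every
claim in the test suite is made against this known truth or against
closed-form oracles.

## Worked example

The `analysis/` directory is a numbered workflow over the package; running
it end to end (≈20 minutes on one CPU):

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

produces, among other output (abridged):

```
=== 02_normalize_filter ===
0 Gy: 110 of 2000 genes excluded as bimodal (12 ineligible)
=== 04_classify ===
confirmed    0 0.05    2
    hyper   82   78   83
    hypo   103   95   92
    non   5485 5509 5516
hyper: whole-data sensitivity 0.83, confirmed sensitivity 0.68 (n = 294)
hypo: whole-data sensitivity 0.63, confirmed sensitivity 0.49 (n = 298)
confirmed false-positive rate among true-non genes: 0.0113
=== 05_metrics_intersections ===
   dose     tau.cv      tau.d     tau.ev
      0 -0.6413539 -0.5407216 -0.0950072
   0.05 -0.6486124 -0.5503931 -0.1257674
      2 -0.6446206 -0.5483440 -0.1140529
=== 06_enrichment ===
     hyper|N1|0Gy planted_hyper_set 35 37 118 5.442102e-41
```

Reading these numbers: about 5% of genes are excluded as bimodal per dose;
after confirmation the hypo/hyper sets shrink to roughly a quarter of the
whole-data sets (the confirmation step is deliberately conservative — with
half-size samples both the per-gene EV noise and the reference interval
widen by √2, so only genes with large full-data margins reproduce);
CV and d correlate strongly and negatively with expression (tau ≈ −0.64 /
−0.55) while EV is close to uncorrelated (tau ≈ −0.1); and the gene set
seeded with the injected hyper-variable genes is recovered as massively
enriched exactly in the hyper-variable queries of the affected groups.
Detection of dispersion *deflation* (hypo) is weaker than inflation by
construction: an 8-fold dispersion drop can reduce the MAD at most by
1/√8 toward the Poisson floor, while an 8-fold rise nearly doubles it.

The same stages are available as one call:

```r
library(exvar)
sim <- simulate_counts(sim_config(n_genes = 500, samples_per_group = 16,
                                  doses = "0", seed = 1))
res <- run_ev_pipeline(sim$counts, sim$metadata,
                       pipeline_config(B = 200, R = 10, seed = 1))
table(res$classification$label_confirmed)
write_pipeline_result(res, "results/run1")   # TSVs + run manifest
```

Sensitivity re-runs (sex stratification, triplet-level exclusion of heavy
smokers/drinkers) go through `apply_strata()`, which also switches the
bimodality cutoff to 1.3 for the reduced sample sizes.

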