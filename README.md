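# dropcult

Analysis of massively parallel **droplet microfluidic culture**
experiments on complex microbial communities — the kind of assay in which
single cells from a gut microbiota sample are Poisson-encapsulated into
picoliter droplets, grown in isolation, and read out in bulk by 16S rRNA
amplicon sequencing plus total 16S qPCR. Because each loaded droplet is
(almost always) a clonal microcolony, the product of an SV's relative
abundance and the qPCR total tracks that taxon's absolute growth without
any droplet sorting.

The package is aimed at microbiologists running or analysing such
screens and covers the full chain:

* **Loading design** — Poisson occupancy mathematics. With mean
  occupancy n̄ = ρV, the empty / clonal / multi-cell droplet fractions
  are e⁻ⁿ̄, n̄e⁻ⁿ̄ and 1 − e⁻ⁿ̄ − n̄e⁻ⁿ̄; `loading_summary()`,
  `mean_for_single_fraction()` (smaller root of n̄e⁻ⁿ̄ = c, by
  bisection), `infer_mean_from_empty_fraction()`,
  `dilution_for_target()`.
* **Observation model** — strict >5,000-read sample filter, pseudocount
  of 1, relative abundances, qPCR scaling to absolute units, strict
  >5-sample detection filter (`filter_low_depth()`,
  `to_relative_with_pseudocount()`, `absolute_abundance()`,
  `detection_filter()`).
* **Growth kinetics** — the modified Gompertz law on the ln-abundance
  scale, y(t) = A·exp{−exp[(μe/A)(λ−t)+1]} + A₀, fitted by 100-restart
  bounded robust least squares (smooth-L1 loss, μ ≥ 2.5 fits discarded),
  with total growth Δ = y(127) − y(0), the Δ/ln 2 doubling conversion
  (1.48 ln-units ↔ 2.14 doublings), and closed-form times to capacity
  fractions (`fit_gompertz()`, `total_growth()`,
  `capacity_fraction_curve()`).
* **Threshold calibration** — endpoint preprocessing against no-carbon
  controls, reference well-plate calls at 20% of per-isolate maximum,
  ROC sweep and Youden's J = TPR − FPR (`preprocess_endpoint()`,
  `plate_growth_reference()`, `roc_youden()`, `classify_growth()`,
  `confusion_metrics()`).
* **Utilization ecology** — primary degraders, specialist/generalist
  lifestyles, glucose-consumer normalisation, phylum×lifestyle
  permutation tests, prebiotic-cocktail coverage and pattern
  enrichment, profile clustering, Mantel tests
  (`primary_degraders()`, `classify_lifestyle()`,
  `phylum_lifestyle_permutation()`, `combo_coverage()`,
  `combo_enrichment()`, `cluster_profiles()`, `mantel_test()`).
* **Synthetic experiments** — `community_spec()`,
  `simulate_timeseries()`, `simulate_prebiotic_experiment()` and
  `simulate_reference_plates()` generate droplet experiments with known
  ground truth, so the whole pipeline is testable end to end.

See the vignette (`vignettes/droplet-culture-analysis.Rmd`) for the
models, their assumptions, and every tunable parameter.

## Worked example

Design the loading, then run a synthetic utilization screen end to end:

```r
library(dropcult)

loading_summary(0.3)
#> Poisson droplet loading at mean occupancy 0.3
#>   empty                   74.08%
#>   loaded (>=1 cell)       25.92%
#>   single cell             22.22%
#>   multiple cells (>=2)     3.69%
#>   single | loaded         85.75%
```

At n̄ = 0.3, about 26% of droplets are loaded and ~86% of those are
clonal; ~4% of all droplets carry two or more cells (the main source of
false-positive utilization calls via cross-feeding).

```r
spec <- community_spec(40, seed = 101)           # known ground truth
sim  <- simulate_prebiotic_experiment(spec, n_replicates = 3,
                                      read_depth = 1e5, seed = 102)
processed <- preprocess_endpoint(sim$counts, sim$metadata, sim$qpcr)

polys <- spec$carbons
thr <- roc_youden(as.vector(processed[, polys]),
                  as.vector(spec$utilization_truth[, polys]))
thr
#> Calibrated growth threshold 82.32 (Youden's J = 0.9155; TPR 1, FPR 0.08451)

calls <- classify_growth(processed[, polys], thr$threshold)
confusion_metrics(calls, spec$utilization_truth[, polys])[1:4]
#> accuracy 0.93, sensitivity 1.00, specificity 0.92, FDR 0.40

table(classify_lifestyle(calls))
#> nondegrader  specialist  generalist
#>          21          14           5

head(combo_coverage(calls, k = 2), 3)
#>            combo  coverage
#> 2 inulin+dextrin 1.0000000
#> 3   inulin+xylan 0.8947368
#> 1     inulin+gos 0.8421053
```

The calibrated threshold (in the experiment's qPCR units) recovers the
simulated truth with 93% accuracy; 19 of 40 SVs are primary degraders,
mostly single-substrate specialists, and the best two-prebiotic cocktail
(inulin + dextrin) would stimulate all of them.

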