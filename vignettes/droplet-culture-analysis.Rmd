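---
title: "Analysing droplet microfluidic culture experiments with dropcult"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing droplet microfluidic culture experiments with dropcult}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropcult)
```

## The measurement problem

Droplet microfluidic culture encapsulates single bacterial cells from a
complex community (for example a human stool sample) into millions of
picoliter droplets, grows them in isolation, and reads growth out in bulk:
16S rRNA amplicon sequencing gives the *relative* abundance of each
sequence variant (SV) across all droplets, and total 16S qPCR gives the
*overall* amount of bacterial DNA. Because droplets are seeded with at
most a handful of cells, each droplet is (almost always) a clonal
microcolony, and the product of relative abundance and qPCR total tracks
each taxon's absolute growth without sorting droplets.

`dropcult` implements the complete analysis chain for such experiments:
loading design, the observation model, growth-curve fitting, growth
threshold calibration, and the ecology statistics used in carbohydrate
(prebiotic) utilization screens — together with a synthetic-data generator
that produces experiments with known ground truth, so every stage can be
validated end to end.

## Poisson loading design

Cells at density $\rho$ partitioned into droplets of volume $V$ land in a
droplet as a Poisson count with mean occupancy $\bar n = \rho V$. The
fraction of droplets that are empty, clonal, or multiply loaded follows
directly:

$$P(n) = \frac{\bar n^n e^{-\bar n}}{n!},\qquad
  P(\text{loaded}) = 1 - e^{-\bar n},\qquad
  P(\text{single}) = \bar n e^{-\bar n}.$$

```{r}
loading_summary(0.3)
loading_summary(0.1)
```

The working range $\bar n \in [0.1, 0.3]$ trades throughput (10–26% of
droplets loaded) against clonality (95–86% of loaded droplets contain a
single cell; 0.5–4% of all droplets carry two or more cells). Targeting a
clonal-droplet fraction directly means solving
$\bar n e^{-\bar n} = c$, which has two roots; `dropcult` returns the
smaller (dilution-regime) root by bisection, because protocols dilute
toward clonality:

```{r}
mean_for_single_fraction(0.2)
```

At 20% clonal loading the implied multi-cell fraction is just under 3%.
`infer_mean_from_empty_fraction()` inverts $P(0) = e^{-\bar n}$ so that
counting empty droplets under a microscope calibrates the realised
loading, and `dilution_for_target()` converts a target $\bar n$ into a
cell density through the plate-calibrated constant $K$ (CFU/ml per OD600
unit), which is supplied by the user — it is an empirical property of each
suspension, so the package ships no default.

Cell clumping, droplet polydispersity and cross-feeding between
co-encapsulated cells are outside the model; the multi-cell fraction
above is the honest summary of how often the clonality assumption fails.

## From counts to absolute abundances

The observation model is implemented exactly as stated, in a fixed order:

1. `filter_low_depth()` — drop samples with **strictly** ≤ 5,000 reads
   (a 5,001-read sample stays).
2. `to_relative_with_pseudocount()` — add a pseudocount of 1 to every
   cell (avoiding $\log 0$ downstream) and normalise rows to proportions.
3. `absolute_abundance()` — multiply each sample's proportions by its
   total 16S qPCR concentration. Row sums equal the qPCR totals by
   construction; negative qPCR readings (instrument artifacts) are
   clamped to zero with a warning.
4. `detection_filter()` — keep SVs detected (non-zero **raw** count, not
   pseudocounted) in strictly more than 5 samples; only these enter curve
   fitting.

Detection is deliberately defined on raw counts: with pseudocounts every
SV would be "present" everywhere. The pseudocount and the qPCR scaling
are both per-sample scalar operations, so their order does not matter —
the test suite asserts this metamorphic property.

## Growth kinetics: the modified Gompertz model

Per-SV ln-abundance trajectories are fitted with the Zwietering form of
the Gompertz law plus an inoculum offset:

$$y(t) = A\,\exp\!\left\{-\exp\!\left[\frac{\mu e}{A}(\lambda - t) + 1\right]\right\} + A_0$$

where $y$ is $\ln$(absolute SV abundance), $A$ the carrying-capacity
amplitude (ln-units), $\mu$ the maximum specific growth rate (h$^{-1}$,
the slope at the inflection), $\lambda$ the lag time (h) and $A_0$ the
inoculum level. `gompertz_ln()` treats $A = 0$ as the constant-$A_0$
limit so no-growth taxa are well defined.

Fitting (`fit_gompertz()`) is multi-start bounded robust least squares:

* **Bounds** (via `gompertz_bounds()`): $A \in [0, 15]$,
  $\mu \in [0, 2.6]$, $\lambda \in [-50, 12]$, $A_0 \in [0, 15]$. The
  $\mu$ ceiling corresponds to a doubling time on the order of 15 min,
  the fastest recorded for an anaerobe; the $A$/$A_0$ ceilings to the
  largest DNA amounts seen in replicate droplet samples; the negative
  lag floor stops fitted lags collapsing onto a boundary at 0.
* **Loss**: per-residual $2(\sqrt{1+r^2}-1)$ (smooth L1), which behaves
  quadratically for small residuals and linearly for outliers —
  replicate droplet samples occasionally produce wild qPCR readings.
* **Restarts**: 100 starting points drawn uniformly inside the bound box
  (the minimal reading of "randomly distributed between the bounds"),
  under a caller-supplied seed, optimised by `L-BFGS-B` with analytic
  gradients.
* **Retention**: restarts whose $\mu$ lands at or above 2.5 are
  discarded as ceiling collapses *first*; among the survivors the lowest
  loss wins, with ties broken toward smaller $\mu$ and then earlier
  restart so results are reproducible. If nothing survives, a
  failure-flagged fit is returned rather than an error.

Derived statistics:

* `total_growth()` — $\Delta = y(127) - y(0)$ by default, the rise of
  the fitted curve over a 127-hour sampling series.
* `doublings_from_delta_ln()` — $\Delta/\ln 2$; the growth limit of
  detection of 1.48 ln-units equals 2.14 doublings.
* `time_to_capacity_fraction()` — the closed form
  $t_q = \lambda + \frac{A}{\mu e}\left(1 - \ln(-\ln q)\right)$ for the
  time to reach a fraction $q$ of capacity. The fraction is measured
  against $A$ alone, excluding $A_0$: $A$ is the carrying capacity of
  the *growth*, and including the inoculum offset would make the
  statistic depend on how abundant a taxon happened to be at seeding.
* `capacity_fraction_curve()` — the empirical CDF of the $t_q$ values
  over a fit collection, i.e. the fraction of taxa at ≥ $q$ capacity
  through time.

```{r}
tt <- c(0:24, 48, 72, 96, 127)  # hourly day one, then daily
y <- gompertz_ln(tt, A = 5, mu = 1, lam = 3, A0 = 2)
fit <- fit_gompertz(tt, y + rnorm(length(tt), sd = 0.1),
                    n_restarts = 50, seed = 1)
fit
time_to_capacity_fraction(fit, 0.8)
```

A note on the $\mu$ bound: $\ln 2 / 2.6\,\mathrm{h}^{-1} \approx 16$ min
rather than exactly 15; the bound value 2.6 is adopted as configured and
the small rounding discrepancy left as is.

## Growth thresholds: reference plates, ROC, Youden's J

Endpoint utilization assays need a growth/no-growth cutoff. The package
calibrates one against conventional well-plate cultures:

* `plate_growth_reference()` normalises each isolate's OD endpoints to
  its own maximum and calls growth strictly above 20% of that maximum.
* `preprocess_endpoint()` prepares droplet endpoint data from one
  matched donor/session set: samples whose qPCR total falls below the
  mean of the no-carbon controls are zeroed (no overall growth),
  absolute abundances are computed, per-SV medians are taken across
  replicates within each condition, the matched no-carbon medians are
  subtracted, and negatives are floored at 0. Flooring is deliberate:
  every downstream quantity (growth level, degrader call) is
  non-negative, and a negative control-subtracted abundance carries no
  usable information about utilization. Multi-donor data are split by
  the caller, which keeps "matched control" explicit rather than hiding
  a grouping convention.
* `roc_youden()` sweeps every decision threshold — midpoints between
  consecutive sorted unique scores plus sentinels below and above all
  scores — classifying `score >= threshold` as growth, and returns the
  threshold maximising Youden's $J = \mathrm{TPR} - \mathrm{FPR}$. Ties
  are broken toward the smallest threshold, i.e. the most sensitive of
  the equally good cutoffs, deterministically.
* `classify_growth()` applies a threshold with a closed inequality
  (≥ — a total growth of exactly 1.48 ln-units counts as growth), and
  `confusion_metrics()` reports accuracy, sensitivity, specificity and
  FDR, with zero-denominator metrics returned as `NA`, never 0.

Kinetics mode and endpoint mode use separate thresholds: 1.48 ln-units
is the default for kinetics (`run_config()`), while endpoint thresholds
have no default and must be calibrated — their scale depends on the
qPCR units of the experiment at hand.

## Utilization ecology

All ecology statistics act on an SV × carbon growth matrix; glucose is a
viability control and the no-carbon condition a blank, so neither ever
counts as a utilization ("polysaccharide") column.

* `primary_degraders()` — SVs growing on ≥ 1 polysaccharide.
* `classify_lifestyle()` — exactly one polysaccharide → specialist,
  two or more → generalist, none → nondegrader. Specialists and
  generalists partition the primary degraders exactly.
* `normalize_by_glucose()` — divides per-donor degrader statistics
  (richness or summed abundance; both are meaningful, so the caller
  picks and labels) by glucose-consumer statistics, controlling for
  overall sample viability.
* `phylum_lifestyle_permutation()` — shuffles the SV-to-phylum
  assignment while keeping each SV's utilization profile intact, and
  compares each (phylum, lifestyle) membership count against its
  permuted distribution, one-sided with add-one correction:
  $p = (\#\{\text{perm} \ge \text{obs}\} + 1)/(B + 1)$. Shuffling
  *labels* rather than table entries tests the taxonomy–lifestyle
  association directly while preserving the lifestyle marginals and all
  within-SV correlation.
* `combo_coverage()` — for every size-$k$ prebiotic cocktail, the
  fraction of degraders stimulated (growing on ≥ 1 member).
* `combo_enrichment()` — whether exact utilization patterns occur more
  or less often than chance, against a null that shuffles each carbon
  column independently (preserving every carbon's prevalence); both
  tails are reported separately. Whether such a null should preserve
  rows, columns or entries is a genuine design choice; the
  column-marginal-preserving null is used because prevalence differences
  between carbons are a nuisance, not the signal.
* `cluster_profiles()` — average-linkage hierarchical clustering on
  Euclidean distances between continuous growth profiles, cut at
  $k = 2$ by default (the split that typically separates
  single-carbohydrate from multi-carbohydrate growers); the cut height
  is exposed because the two-group choice is ultimately a judgement
  call.
* `mantel_test()` — Pearson correlation of off-diagonal distances with
  significance from joint row/column permutation, one-sided (greater),
  add-one corrected. Taxonomic structure at a rank is encoded by the
  caller as a 0/1 same-taxon distance matrix.

The add-one correction means no permutation p-value can be 0; with a
discrete statistic it also makes the tests mildly conservative, which is
the usual price of validity for count-based permutation tests.

## The synthetic-data generator

`community_spec()` draws a community with known ground truth:
per-SV Gompertz parameters strictly inside the fitting bounds, a
growing/non-growing flag (defaults to 35% growing, roughly the fraction
of inoculating taxa that actively grow in a rich-medium droplet
culture), sparse Dirichlet(0.5) inoculum fractions so most taxa are
rare, gut-like phylum proportions, and an SV × carbon utilization truth
with specialists outnumbering generalists among degraders (60/40). The
inoculum offsets are derived from the fractions
($A_0 = \ln(f_i \cdot N_0)$, $N_0$ = 5 × 10⁴ qPCR units by default) so
the two views of the inoculum stay consistent.

`simulate_timeseries()` builds destructively sampled aliquots: the
latent abundance of each SV is the exponential of its Gompertz curve, so
the quantity the fitting stage estimates is *exactly* the simulated
curve; counts are multinomial at the stated read depth; the qPCR total
carries multiplicative lognormal noise with configurable CV (default
0.1, mean 1 — strictly positive and scale-free, as qPCR error is).
`simulate_prebiotic_experiment()` produces 48-h endpoints per carbon ×
replicate, where an SV grows on a polysaccharide only where the truth
says so, every viable SV grows on glucose, and nothing grows in the
mandatory no-carbon control. `simulate_reference_plates()` emulates the
well-plate validation arm at isolate scale.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: chimeras and taxonomy misassignment,
compositional artifacts of primer bias, droplet coalescence,
co-encapsulation cross-feeding (the main false-positive mechanism in
real utilization screens), and overdispersion of counts beyond
multinomial. Recovery results on synthetic data are therefore an upper
bound on real-data performance, not an estimate of it.

## Numerical choices and degenerate inputs

* Bisection for `mean_for_single_fraction()` runs to an interval of
  1e−12 on the monotone branch; no derivative needed.
* The optimizer floors $A$ at 1e−8 so the exponent $\mu e / A$ stays
  finite; curve and gradient evaluation use the underflow-safe form
  $\exp(u - e^u)$ so extreme parameter corners yield 0 rather than
  `NaN`.
* All-zero count rows become uniform proportions under the pseudocount;
  all-zero isolate rows in plate data yield all-`FALSE` calls with a
  warning; a qPCR total of 0 gives an all-zero abundance row.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; identical seeds give identical output.

Default problem sizes in the test suite are chosen at desk scale: 50-SV
parameter-recovery batches on the 29-point sampling design (hourly for
the first day, then daily to 127 h), 200-dataset null calibrations at
499 permutations, and exhaustive enumeration oracles at ≤ 6 SVs or 4
Mantel objects, which keeps the whole suite under a minute on one CPU.

## Known limitations

* `preprocess_endpoint()` handles one matched set per call; it does not
  model session effects or inoculum drift between sessions.
* The Gompertz model is the only growth law offered (no logistic or
  Baranyi alternatives, no model selection, no parameter confidence
  intervals).
* Endpoint thresholds calibrated on one experiment's qPCR scale do not
  transfer to another scale without recalibration.
* The specialist label is relative to the carbons tested: a taxon
  called a specialist may well grow on untested substrates.
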