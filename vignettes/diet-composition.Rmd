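---
title: "Quantitative diet composition from stomach-flushing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative diet composition from stomach-flushing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crocdiet)
```

## The problem

Stomach-flushing yields, for each captured animal, the identifiable prey items
in its stomach together with their counts and displaced volumes. For
size-structured predators — here hatchling Morelet's crocodiles during the
hatchling–juvenile transition — the questions are: which prey dominate the
diet, how does importance change across body-size classes, how diverse is the
diet per class, how strongly do classes overlap in resource use, and do
individual prey items become more or less likely with body length
(an ontogenetic diet shift)?

`crocdiet` implements that analysis end to end. The sampling unit is one
stomach (one individual); the covariate is total length (TL, mm); prey are
categories at the order level for invertebrates and the class level for
vertebrates.

## The indices

For a size class with $N$ stomachs, total prey count $N_t$ and total displaced
volume $vTd$ (mL), each category $i$ with count $N_i$, incidence $n$ (stomachs
containing it) and volume $vd_i$ gets

$$\%N_i = 100\,N_i/N_t, \qquad \%V_i = 100\,vd_i/vTd, \qquad \%FO_i = 100\,n/N,$$
$$RII_i = \%FO_i \times \%V_i / 100 \in [0, 100],$$

with importance classes low $[0,10)$, secondary $[10,40)$ and high
$[40,100]$. Boundaries belong to the upper class: this is forced by the
reference study's own table, which stars a cell with RII exactly 10 in the
secondary column. Incidence requires `count > 0`; a recorded but empty row
does not make a category "appear" in a stomach.

Two denominator subtleties:

* **`vTd` is configurable.** By default it is the per-class sum of
  identified-item volumes, so $\%V$ sums to 100. Field measurements of total
  displaced volume often exceed that sum (unidentifiable material); pass
  `vtd_total` to `diet_table()` to use the measured totals, in which case
  $\%V$ sums to less than 100. The reconstructed study dataset uses explicit
  totals of 10, 7 and 14 mL.
* **Pooled occurrence** (`pooled_occurrence()`) sums incidence over all
  stomachs and divides by the total — it is *not* the mean of per-class
  $\%FO$, which would weight classes equally regardless of size.

Size classes are equal-width bins of TL, $(\mathrm{upper}-\mathrm{lower})/k$,
half-open on the left with the last interval closed. Breaks are kept at full
precision (e.g. $300 + 209/3 = 369.6\overline{6}$); bounds like "369.6" in
printed tables are treated as display rounding, since the stated width formula
forces the exact thirds.

## Reconstructing integer counts from printed percentages

Published diet tables usually print rounded percentage columns without the
underlying counts. `infer_counts()` inverts this: it finds the smallest total
$T$ and non-negative integers $n_i$, $\sum n_i = T$, such that each
$100\,n_i/T$ rounded half-up to the printed precision reproduces the column.
The search is exhaustive over $T$ with a subset-sum dynamic program per
candidate total, and returns an explicit not-found result when no integer
composition exists (e.g. the inconsistent pair 33.3/50). Half-up rounding is
used throughout display-precision comparisons because it is what the printed
reference table uses (R's own `round()` rounds half to even).

## The packaged reconstruction

`table1_printed()` ships the published per-class metric table of the study the
package is built around (31 stomachs in classes of 10/7/14; 11 prey
categories). `table1_fixture()` rebuilds a stomach-level dataset consistent
with it:

* per class, incidence = printed $\%FO \times N/100$ — an integer in all 33
  cells;
* the count reconstruction of each $\%N$ column yields counts equal to those
  incidences in every class (totals $N_t$ = 34, 24, 54), i.e. one prey
  individual per incident stomach;
* each class's printed `vd` is split equally over its incident stomachs.

Two conventions are ours, because per-stomach rows are unpublished: TL values
are an even lattice within each class interval, and incidences are placed
round-robin across the class's stomachs with a running offset, which spreads
items so no stomach is empty. Any statistic that depends on within-stomach
co-occurrence (notably stomach-bootstrap variances) is therefore
convention-dependent; class-level indices are not.

Two printed cells are knowingly irreproducible and kept as published: the
initial-class Coleoptera $\%N$ of 26.6 (9/34 = 26.5, and no integer
composition matches the whole column exactly), and sub-0.1 disagreements in
$\%V$/RII caused by `vd` being printed at 0.1 mL resolution. Tests compare
fixture-derived metrics to the printed table at measured tolerances (%FO
exactly at print precision; $\%N$ within 0.15; RII within 0.5) and the RII
importance class agrees in all 33 cells. RII recomputed directly from the
printed $\%FO$ and $\%V$ columns matches every printed nonzero RII within
±0.1.

## Diversity and overlap

Simpson diversity is the plug-in complement form $D = 1 - \sum p_i^2$ on raw
count proportions — validated by exact agreement with the study's printed
medium-class value (0.8229 to 4 decimals) on reconstructed counts; the
unbiased finite-sample variant is deliberately not used for that reason. The
published initial and final $D$ values and all published Pianka overlaps
cannot be recovered from any published column (they evidently used
unpublished stomach-level structure), so the package makes no attempt to
force agreement there.

`simpson_test()` compares two classes by a stomach bootstrap: resample
stomachs with replacement within each class, recompute $D$ per replicate, and
refer $t = (D_a - D_b)/\sqrt{se_a^2 + se_b^2}$ to a t distribution with
Welch–Satterthwaite degrees of freedom. Under a shared generative null its
empirical size is close to nominal (checked at 0.05 ± 0.02 over 500 simulated
dataset pairs in the test suite). Groups of a single stomach are refused —
there is no resampling variance.

Pianka overlap $O_{jk} = \sum p_i q_i / \sqrt{\sum p_i^2 \sum q_i^2}$ defaults
to numeric (count-share) proportions, with volumetric and occurrence bases
selectable, since the reference analysis does not state which basis it used.
Verbal labels ("high" ≥ 0.6, "moderate" [0.4, 0.6)) are annotation only.

## Composition test and ontogenetic models

`bootstrap_gof()` tests pooled prey counts against uniform expected
frequencies $E_i = T/S$ over the $S$ supplied categories (overridable with
user-supplied expected proportions). The null distribution is built by
multinomial resampling of the $T$ prey individuals; the p value uses the
add-one convention $(1 + r)/(1 + B)$ and so is never exactly zero, and is
bit-reproducible given a seed. Per-category standardized residuals
$(O_i - E_i)/\sqrt{E_i}$ with the 1.96 cutoff localize which items are over-
or under-consumed. An option for the caller is the resampling unit: the
default resamples individual prey; resampling whole stomachs would answer a
slightly different question and can be composed from `stomach_matrix()`.
The empirical type-I error at $\alpha = 0.05$ is inside [0.03, 0.07] over 500
uniform-null simulations at $T = 100$, $S = 11$ (asserted in the tests).

`presence_logit()` fits $\operatorname{logit} P(\text{present}) = \beta_0 +
\beta_1 TL$ per prey item by IRLS, conventionally applied to items screened
at RII ≥ 1.0 in at least one class (`rii_filter()`, inclusive comparison).
Numerical choices: TL is centred at its sample mean for conditioning
(coefficients are reported on the raw scale); convergence is a relative
log-likelihood change below $10^{-8}$ with at most 100 iterations;
step-halving guarantees a non-increasing deviance trace (exposed as
`deviance_trace`). The item effect is a 1-d.f. likelihood-ratio chi-square
against the intercept-only fit; confidence bands are Wald intervals on the
linear predictor mapped through the inverse link. One-level outcomes and
complete separation have no finite MLE and are returned flagged
`estimable = FALSE` rather than forced. The fit is cross-checked in the test
suite against both `glm` and an independent brute-force likelihood grid
(agreement to 3 decimals on small instances); slope recovery at $n = 500$ is
within ±20% in the median across 100 simulation seeds.

## The synthetic generator

`sim_scenario()`/`simulate_stomachs()` emulate exactly the data structure the
analysis assumes: TL uniform on a range (the reference study reports only a
mean of 415 mm and the range 300–509 mm, so uniform is the least-committal
default); per category, Bernoulli presence with either constant prevalence or
a logistic TL link; given presence, a zero-truncated Poisson count (the
simplest model consistent with presence-plus-count data; negative binomial is
an extension point); per prey item, a log-normal displaced volume. Seeds make
datasets bit-reproducible. `scenario_from_data()` estimates a constant-
prevalence scenario from any dataset, enabling simulation "like the study" at
arbitrary sample size.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: seasonal/site structure, prey-community dynamics,
between-category dependence within a stomach (categories are independent
given TL), measurement error in volumes, and digestion-driven
detectability bias.

## Problem sizes and limitations

The test suite and acceptance checks run the resampling components at
moderated sizes chosen to make the statistical assertions sharp but cheap:
500 simulated datasets for the size checks, 1000 bootstrap iterations, 100
seeds for slope recovery at $n = 500$. The package assumes one stomach per
individual and a single categorical prey axis; it does not model prey size
or biomass, apply multiple-testing correction across items (the reference
analysis applies none), or provide rarefaction/Hill-number diversity
families.
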