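---
title: "Methodology: from ectopic activations to a validated survival classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methodology: from ectopic activations to a validated survival classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gecscreen)
```

## The problem

Genes with strictly tissue-restricted expression — testis, placenta,
embryonic stem cells (ESC) — are sometimes re-activated in tumours of
unrelated tissues. Such ectopic, out-of-context activations are attractive
biomarkers: in the tissue of interest (here, breast) the gene is normally
silent, so any robust signal is tumour-borne, and an ON/OFF reading is
clinically simpler than a continuous one. `gecscreen` implements the whole
chain from a normal-tissue panel to a validated gene-count classifier
(GEC), with a synthetic study generator in place of the controlled-access
cohorts such analyses are usually run on.

## Tissue predominance

Per-gene, per-tissue mean log2 expression is computed at two
granularities: the detailed tissue list, and coarse tissue groups (samples
pooled, so tissues weigh by sample count). For each gene the per-tissue
means `x` over the `N` *non-foetal* tissues are standardized:

$$Z = \frac{x - \mathrm{mean}}{\mathrm{std}},$$

and a tissue is called predominant when

$$Z > 0.6\,\frac{N-1}{\sqrt{N}},$$

i.e. 60% of the maximum attainable Z-score. Two conventions are worth
making explicit:

* **Population standard deviation** (divide by `N`). Under this convention
  a profile expressed in exactly one tissue attains `Z = (N-1)/\sqrt N`
  exactly, which is the quantity the threshold scales; with the sample-SD
  convention that identity breaks. Zero-variance genes are non-scorable and
  are dropped (with a count), never called.
* **Foetal tissues** enter neither the mean/std nor the calls; placenta and
  ESC are deliberately non-foetal here so they remain callable targets.

A gene is a *candidate* when it passes at **either** granularity with a
target predominant tissue (testis, placenta or ESC analogue), and its
breast expression is more than ten-fold below the predominant tissue on
the linear scale (`2^x - 1`; strict inequality at the boundary). The union
across granularities reflects that both lists are analysed and merged into
a single candidate set.

## Activation calling

For each candidate gene the activation threshold is the mean + 2 standard
deviations (sample SD, n−1: the usual estimator when a reference cohort
stands in for a population) of its log2 expression in non-tumour samples.
A tumour sample is ON when strictly above the threshold; ties and missing
values are OFF, and missing values are excluded from frequency
denominators so they can never inflate frequencies. Genes activated in
strictly more than 10% of tumour samples (pooled over subtypes) are
retained — infrequently activated genes cannot serve a broadly applicable
classifier.

A caveat inherited from bulk expression data: non-tumour breast tissue may
contain proportionally fewer epithelial cells than tumours, biasing the
reference threshold low for epithelial genes. No correction is applied;
the survival screen that follows is the safeguard, since it re-learns the
working threshold per gene.

## The threshold screen

The core of the package. For each frequent gene in the training cohort:

1. **Grid.** Candidate thresholds are the tumour-expression quantiles from
   the 15th to the 85th percentile in half-percentile steps — 141 points,
   linear-interpolation (type 7) quantiles. Duplicate values are collapsed
   to the lowest percentile; thresholds leaving either arm under 15% of
   samples are skipped (consistent with the grid's own bounds).
2. **Tests.** Each threshold's ON/OFF split is tested by the logrank
   statistic on the full cohort and on 15 cross-validation subsets — the
   held-in 2/3 portions of 3-fold partitions repeated 5 times. Held-in
   portions are the default because they preserve event counts (power) at
   the subset level; the held-out 1/3 folds are available as a switch. The
   *stability score* of a threshold is the fraction of subsets with
   p < 0.05; the criterion "a random selection of sample subsets keeps
   producing the same significant split" becomes a number in [0, 1].
3. **Gates and selection.** Full-cohort p-values of *all* genes and
   thresholds are BH-adjusted as one pooled family — the most conservative
   reading, and invariant to how many thresholds survive tie-collapsing
   per gene. A threshold is significant when p < 0.05, FDR < 0.2 and
   HR > 1; among significant thresholds the most stable wins, with ties
   broken by lower p, then lower percentile.
4. **Hazard ratios.** Per-threshold hazard ratios in the scan records are
   the Pike estimator `(O1/E1)/(O0/E0)` computed from the already-available
   logrank quantities; the scan evaluates up to 141 × 16 splits per gene
   and a partial-likelihood fit per split would dominate the run time of
   the simulation suites for no inferential gain — the HR > 1 gate only
   needs the direction of O−E, which the Pike estimator preserves exactly.
   Each selected candidate's reported hazard ratio is then re-estimated by
   a univariate Cox fit (Efron ties) at its reference threshold, and Cox
   models are used everywhere downstream.

The reference threshold is carried across cohorts as a **percentile
rank**: in a target cohort the working threshold is the tumour-expression
quantile at the reference percentile, with the same quantile convention as
the grid (so propagation into the defining cohort is the identity, and an
additive cross-cohort shift moves the threshold by exactly that shift).
This absorbs platform differences between, say, RNA-seq and microarray
cohorts without any joint normalization.

**Validation rule.** A candidate validates when significant (p < 0.05 and
HR > 1) in at least ⌈2m/3⌉ of the m validation cohorts, with p < 0.1 in
every remaining cohort (the 2-of-3-plus-lenient-third rule at m = 3). A
cohort that cannot produce a p-value blocks validation rather than being
silently skipped.

## The GEC classifier

Validated biomarkers form a panel of size K (default cap 5, ranked by
training p-value). Per patient the GEC is the count of ON panel genes at
the cohort-calibrated (percentile-propagated) thresholds. Counts 0–1
define the favourable group, ≥2 the unfavourable group; counts 0 and
≥K−1 define the GEC−/GEC+ extremes. Evaluation per cohort: low-vs-high
logrank, univariate Cox on the count, and a multivariate Cox with age,
molecular subtype and stage where annotated. Subtype enters as one ordered
numeric covariate by default (one HR per factor, as commonly tabulated;
ordering `luminal_A < luminal_B < HER2 < basal`), with dummy coding behind
a flag; entirely missing covariates are dropped per cohort. Subtype-wise
analyses pool cohorts only *after* per-cohort scoring, so counts stay
cohort-calibrated.

The extreme-group contrast (GEC+ vs GEC−, intermediate excluded) uses
two-sided Mann–Whitney tests, BH adjustment across genes, and a
linear-scale fold ratio of group means (`2^x − 1` back-transform; "ratio
above 1.5" reads most naturally as a linear fold change). Selection
requires both adjusted p < 0.05 and ratio > 1.5 or < 1/1.5.

## The synthetic study generator

`sim_config()` fixes the study conditions; the generators are
deterministic given the seed and always emit a planted-truth manifest
(gene classes, activation indicators) for recovery testing.

* **Expression**: Gaussian noise on the log2 scale (SD 0.5 around a
  baseline of 1), matching the `log2(1 + FPKM)`-style values the pipeline
  expects. This is a stand-in convenience, not a claim about real noise.
* **Panel**: 20 tissues × 5 samples, including breast, the three targets
  and two foetal tissues (18 non-foetal ⇒ detailed cutoff
  `0.6·17/√18 ≈ 2.40`); planted genes gain 6 log2 units in exactly one
  target tissue and stay at baseline in breast.
* **Cohorts**: by default 1 training (600 tumours + 100 non-tumour),
  3 validation (250 + 60) and 4 test cohorts (1500 + 60). 125 genes: 5
  prognostic (activation 25–35%, per-gene HR 2.5–3), 20 activated but
  non-prognostic (30%), 100 silent null genes. Activation adds 4 log2
  units; each cohort gets an additive offset (SD 0.5) emulating platform
  shifts. Training/validation sizes mirror a mid-size discovery design;
  the test cohorts are sized at the large end of public breast-cancer
  cohorts so that hazard-scale checks on a small per-gene effect (log-HR
  0.2, the magnitude typical of multivariate GEC estimates) have tight
  Monte-Carlo error.
* **Survival**: exponential event times with hazard
  `0.05 · exp(Σ log-HR · activation)` per year, independent exponential
  censoring at rate 0.03 capped at 15 years — roughly a 45% baseline event
  fraction, chosen to resemble long-follow-up disease-free survival in
  historical high-risk cohorts while giving closed-form oracles for every
  test.

What the generator does **not** emulate: correlated gene modules,
subtype-specific expression programs (subtype labels are independent
noise), non-proportional hazards, informative censoring, epithelial
content differences between tumour and non-tumour samples, and
missingness. Passing tests therefore demonstrate the statistical machinery
is correct and calibrated under a clean proportional-hazards world — not
that real cohorts would yield the same gene lists.

## Numerical choices and degenerate inputs

* Quantiles: type 7 (linear interpolation) everywhere, making the
  grid/propagation round trip exact.
* Logrank: O−E/V chi-square with 1 df and the hypergeometric variance,
  ties handled by distinct-event-time grouping; verified in the tests
  against `survival::survdiff` (to 1e-10) and against exhaustive
  permutation enumeration at n = 8.
* Cox: `survival::coxph` with Efron tie handling; non-convergent or
  separated fits are returned as flagged NA rows, never as exceptions
  inside the screen.
* Constant genes: empty grid (screen) or non-scorable (Z-profile), both
  skipped with counts; constant covariates are dropped with a warning.
* All randomness (generators, CV partitions) flows from explicit integer
  seeds; pipeline reruns are byte-identical, which the tests assert on the
  written files.

## Problem sizes used by the test suite

The statistical suites run at the configuration above: 50-seed
null-calibration and planted-recovery runs over 1 training + 3 validation
cohorts (the null suite at a 2.5-percentile grid step, the recovery suite
at the full 0.5 step), 200-seed Monte-Carlo checks for the Z-score and
activation-threshold oracles, and single large cohorts (n = 1000–1500) for
hazard-recovery checks. These sizes keep each suite's Monte-Carlo error
well inside the asserted margins.

## Known limitations

* The per-threshold Pike HR slightly underestimates large true hazard
  ratios; it gates direction only, and all reported effect sizes come from
  Cox fits.
* BH is applied to highly correlated tests (adjacent thresholds of one
  gene); this is conservative for FDR control but the nominal FDR level
  should not be read as an exact false-discovery fraction.
* With fewer than 3 validation cohorts the ⌈2m/3⌉ rule degenerates
  (m = 1 requires the single cohort to be significant); the generalization
  is provided but was designed around m = 3.
* The subtype covariate's ordinal coding imposes equal spacing between
  subtypes; use dummy coding when that assumption matters.
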