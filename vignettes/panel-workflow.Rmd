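---
title: "Panel selection and case subtyping for CMP proteomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panel selection and case subtyping for CMP proteomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cmpanel` implements a case–control biomarker discovery workflow for
circulating-microparticle (CMP) proteomic abundance data, together with a
synthetic-cohort generator that makes every stage falsifiable. This
vignette is the package's own account of the statistics it computes, the
defaults it ships, and the design decisions that were genuinely open.

## The data model

The unit of analysis is a samples × proteins matrix of positive abundances
(arbitrary units, `NA` for missing cells), a per-sample case/control label,
clinical variables for the cases, and an undirected protein interaction
graph given as an edge list. Nothing in the package assumes a particular
instrument; it assumes only that abundances are positive, roughly
lognormal, and that redundancy (correlated proteins) and annotation
sparsity (proteins without known interactions) are both present — the two
facts the preprocessing stage exploits.

## Preprocessing

Four filters, applied in a fixed order, each a pure function returning the
filtered matrix plus a report satisfying `in = out + removed`:

1. **TIC normalisation** — each sample divided by its total signal;
   idempotent.
2. **Reference-median normalisation** — each protein divided by its median
   over the control samples, so control medians are 1. Proteins with no
   usable reference values are removed, not imputed.
3. **CV filter** — a protein is kept only if its coefficient of variation
   (sd/mean, `n−1` denominator, missing values ignored) is at most
   `max_cv = 0.30` in the case group *and* in the control group. A CV that
   is undefined (zero mean, fewer than two observations) fails the filter:
   an unestimable protein should not reach the models.
4. **Correlation pruning** — Pearson correlations of log2 abundances on
   pairwise-complete observations; undefined correlations count as 0 and
   are logged. Among proteins linked by `|r| ≥ 0.7`, the one with the
   larger number of at-threshold partners displaces the others. Degrees
   are computed once on the input and held fixed, which makes the greedy
   result order-independent and the operation idempotent; degree ties
   break lexicographically for determinism. The absolute value is
   deliberate: anticorrelated redundancy is still redundancy. The
   threshold is compared on log2 abundance because the correlation of raw
   lognormal values is attenuated by skew.
5. **Network filter** — keep proteins with degree ≥ 4 in the interaction
   graph (proteins absent from the graph have degree 0). This is the
   "full" → "restricted" transition: the restricted set trades recall for
   annotation quality, suppressing fragments and unreviewed identifications.

The composition `cv → prune → network` is the pipeline order; each filter
remains individually callable and individually tested.

## The bivariate screen

For each protein, a one-predictor logistic regression of the label on the
*standardised log2* abundance; the Wald p-value of the slope is corrected
by an **uncapped** Bonferroni product `m × p` (m = number of proteins
tested). Uncapped products above 1 carry no inferential content beyond
"not significant", but reporting them preserves the ranking and matches
the convention of the differential tables this workflow produces.
Standardising the predictor stabilises the fit; the Wald p is invariant to
that affine choice.

## Logistic core

All model fitting goes through one iteratively-reweighted-least-squares
core (implemented in C++ for the panel search's ~2×10⁵ fits per run). With
tens of samples and up to four predictors, quasi-separation is routine, so
the core is guarded: if IRLS fails to converge, the standardised slopes
diverge (>12), or fitted probabilities saturate, the model is refitted
with a ridge penalty of 10⁻⁴ on the standardised slopes and flagged. The
AIC is always `2k − 2ℓ` with ℓ the *unpenalised* log-likelihood at the
returned coefficients — the penalty is a numerical guard, not a model
change. The ridge strength is the smallest value that gave stable
coefficients on toy separated data; results are insensitive to an order of
magnitude either way because separated models win or lose on their AUC,
not their AIC.

## Panel selection

Each of `n_iter = 100` iterations:

1. **Outer split** — stratified by class, training fraction 0.8 with
   banker's rounding per class (for 23/50 that is 18 + 40 training, 5 + 10
   validation). Stratification is not optional at this imbalance:
   unstratified 5-fold folds of a 58-sample training set are frequently
   single-class, which makes the described procedure inexecutable.
2. **Ensemble ranking** — three bivariate scores per protein on the
   training portion (one-predictor logistic AIC; rank-sum p; absolute
   standardised mean difference), combined as the ascending mean of the
   three ranks. Constant proteins rank last; ties break lexicographically.
   Inside the ranking the rank-sum p is computed by a vectorised
   tie-corrected normal approximation — ordering-equivalent to the exact p
   and two orders of magnitude faster; the exported `wilcoxon_rank_sum()`
   keeps the exact small-sample path.
3. **Shortlist and search** — top 10 proteins; all 385 panels of size ≤ 4;
   each panel evaluated on one shared stratified 5-fold assignment per
   iteration (same folds for every panel, so panels are compared on the
   same resampling noise).
4. **Selection** — lexicographic: max mean AUC, min SD of the AUC, min
   full-training AIC, smallest panel, lexicographic member order. The AUC
   leads and the AIC only breaks ties, which is what the selection
   sentence this design follows prescribes.
5. **Outer validation** — the winning panel refitted on the full training
   portion; validation samples are projected using *training* means and
   SDs and scored once. Nothing downstream of the split ever reads a
   validation row (a leakage test perturbs them and asserts identical
   selections).

Shortlisted proteins are z-scored once on the outer-training statistics.
Because the logistic MLE is equivariant under affine predictor transforms,
fold-level refits on this shared scale give predictions identical to
per-fold standardisation; only the ridge fallback "sees" the scale, and
only in degenerate fits.

Aggregation counts how often each panel and each protein is selected;
proteins in ≥ 5 selected panels are flagged "recurrent". The whole
procedure is a deterministic function of `(data, seed)`: a root seed
spawns three per-iteration seeds (permutation, split, folds), so any
iteration can be reproduced in isolation.

## The permuted-label null

`compare_permuted()` reruns the identical engine with the labels freshly
and uniformly permuted at the start of every iteration (rather than one
permutation reused for all 100 — the per-iteration draw is a better
approximation of the null and avoids conditioning the whole null run on a
single unlucky shuffle). It reports both the per-iteration outer AUCs and
per-protein summaries (mean and SD of the outer AUC over iterations whose
panel contains the protein), because the scatter/density diagnostics can
be read at either unit; a two-sided rank-sum p compares the two AUC
samples as a descriptive summary, not a calibrated finite-sample test.

## Case subtyping

Restricted to candidate proteins (those occurring in at least one selected
panel), cases only:

* K-means in Euclidean space on **standardised log2 abundance** (K-means
  is scale-sensitive; without standardisation the highest-variance protein
  owns the partition). Lloyd's algorithm with k-means++ seeding, best of
  25 restarts by within-cluster sum of squares, empty-cluster outcomes
  reseeded. Cluster labels are renumbered so cluster 1 is the smallest.
* k chosen by the average-silhouette method over k = 2..6 (ties to the
  smaller k). The scan stops at 6 because with ~23 cases, finer grading is
  not estimable.
* Differential expression: two-sided rank-sum per candidate protein, the
  higher-expression cluster defined by the larger median, uncapped
  Bonferroni with m = number of candidates.
* Clinical association: continuous variables by rank-sum with per-cluster
  medians; binary indicators as 2×2 tables on evaluable subjects with
  Pearson chi-square (no continuity correction) *and* Fisher exact —
  which test "is appropriate" per cell is a judgement the package does not
  make, so both are reported, with the Bonferroni family correction
  applied within each table family. The no-correction chi-square default
  is deliberate: it is the convention this workflow's tables follow.
* **Extreme-indicator permutation test**: T = the maximum over clusters of
  the number of indicators whose prevalence among evaluable subjects is
  strictly greatest in that cluster; the null permutes subject cluster
  assignments (sizes preserved; each subject's missingness pattern
  travels with the subject), and `p = (1 + #{T* ≥ T}) / (1 + n_perm)`.
  Two properties of this statistic are worth knowing. First, its null
  floor is high: indicator prevalences essentially never tie, so every
  permutation awards each indicator to *some* cluster and T* concentrates
  on 4–5 of 7. Second, when indicators are strongly correlated across
  subjects the permutation preserves that correlation, so a perfectly
  concordant observed pattern can be reproduced by every permutation —
  the test is powered against *independent* scattering of indicators, not
  against any concentration whatsoever. It is a diagnostic, and reported
  as such.

## The synthetic generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not the instrument. On the log2 scale each protein is
`μⱼ + effects + (σ/ln 2)·zᵢⱼ` with `z` standard normal, equicorrelated at
`block_rho = 0.7` within ten 6-protein blocks (a Gaussian copula on the
log scale — the natural way to make Pearson-on-log pruning meaningful for
positive MS-style data), and independent elsewhere. Defaults: 23 cases, 50
controls, 226 proteins, 4 signal proteins shifted by 1.5 log2 units in
cases, 8 subtype-marker proteins, missing cells MCAR at rate 0 (the
paper-gap: no missingness mechanism is documented anywhere, so the default
exercises none and `missing_rate` exposes it).

Two defaults deserve their rationale:

* **`cv_noise = 0.8`** (between-subject lognormal σ). This makes a planted
  1.5-log2 signal protein a *realistic* marker — single-protein AUC ≈ 0.8,
  the scale of reported panel performance — rather than a perfect
  separator, so the all-subsets search faces a genuine
  bias/variance trade-off and multi-protein panels genuinely beat
  singletons. The price is a within-group CV (~90 %) far above the 30 %
  filter, i.e. the generator emulates the classifier-stage structure, not
  post-filter variance levels; tests that exercise the CV filter build
  their own low-noise inputs.
* **Centred subtype contrast.** Subtype markers are shifted
  `+e·(1−f)` in subtype 2 and `−e·f` in subtype 1 (f = subtype-2
  fraction), separating the subtypes by `e` log2 units while leaving the
  overall case mean unchanged. An uncentred shift leaks into the
  case-vs-control comparison and the markers masquerade as signal
  proteins; centring keeps the panel-selection and clustering tests
  independently falsifiable.

Clinical variables for cases: four continuous severity measures (delivery
week, maximal systolic and diastolic pressure, 24-h urinary protein),
normal around subtype-specific centres with subtype 2 shifted by
`severity_shift` SD units in the severe direction; seven binary
derangement indicators drawn per subtype with prevalences that are
strictly higher in subtype 2 (severe ~0.5–0.75 for the renal/hepatic/
coagulation flags, mild ~0–0.15). The interaction graph is Erdős–Rényi
with expected background degree 4 (so roughly half the proteome survives
the degree-4 filter), plus forced edges so planted signal proteins always
reach degree 4 — the signal is never silently discarded by annotation.

What the generator does **not** emulate: peptide/spectrum-level noise,
batch effects, informative missingness, heavy-tailed abundance
distributions, and any real protein identity. Passing tests therefore
demonstrate that the *procedures* behave as specified under the assumed
statistical structure — not that any particular real dataset will yield a
particular panel.

## Problem sizes and numerical choices

The test suite runs the full engine at study dimensions (23/50 × 226, 100
iterations) for the permutation-null and recovery checks — one run takes
roughly 15 s on one CPU thanks to the compiled IRLS core — and smaller
40-protein cohorts everywhere else. Monte-Carlo checks use 20–200 seeds
depending on the granularity of the property. Other numerical choices:
IRLS tolerance 10⁻⁸ with a 30-iteration cap; AUC ties counted ½; exact
rank-sum p for untied samples of combined size ≤ 25, tie-corrected normal
approximation otherwise; silhouette ties to the smaller k; fold assignment
by per-class round-robin over a random permutation.

## Known limitations

* The engine's frequency tables quantify *stability under resampling of
  this cohort*, not replication: a lucky protein in one cohort can recur
  across many of its iterations. Only across independent cohorts does the
  planted signal dominate uniformly — which is how the recovery tests are
  aggregated.
* With ~23 cases, silhouette-based k selection is reliable only when the
  clustered analytes genuinely carry the subtype contrast; on
  marker-poor candidate sets it drifts to spurious small clusters.
* The extreme-indicator test's subject-level permutation is conservative
  against correlated indicators (see above).
* Uncapped Bonferroni values are reporting conventions; they are not
  p-values above 1.
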