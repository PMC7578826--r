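# cmpanel

Biomarker panel selection and case subtyping for circulating-microparticle
(CMP) proteomics.

## The problem

Early-onset preeclampsia announces itself clinically in the third
trimester, but its physiology is latent much earlier. Proteins carried by
circulating microparticles — plasma extracellular vesicles sampled at the
end of the first trimester — can be profiled by mass spectrometry in a
nested case–control design (tens of cases, tens of controls, a few hundred
quantified proteins). Two questions follow:

1. **Risk stratification.** Which small panel (≤ 4 proteins) best separates
   future cases from controls, and how much of its apparent performance is
   an artefact of selection on a small sample?
2. **Subtyping.** Among the cases only, do the same proteins reveal
   subgroups with different clinical severity?

`cmpanel` implements the full workflow for both questions, plus a seeded
synthetic-cohort generator so that every stage is testable without access
to any study data.

## The method

**Preprocessing.** Total-ion-current normalisation, scaling of each protein
to the control-group median, a within-group coefficient-of-variation filter
(CV ≤ 30 % in cases and in controls), correlation pruning (among proteins
with pairwise |r| ≥ 0.7 on log abundance, the protein with more correlated
partners is retained), and an interaction-network filter that keeps
proteins with ≥ 4 documented interaction edges (the "restricted" dataset).

**Panel selection.** Over 100 iterations: a stratified 80/20
training/validation split; proteins ranked on the training portion by an
ensemble of bivariate scores (one-predictor logistic AIC, rank-sum p,
absolute standardised mean difference); the top 10 shortlisted; all
C(10,1)+…+C(10,4) = 385 panels evaluated by stratified 5-fold
cross-validation; the panel with the greatest mean AUC (ties: lowest SD of
the AUC, then lowest AIC) refitted on the training portion and scored on
the held-out validation samples. AUC is the Mann–Whitney statistic
U/(n₁n₀). Panel and protein occurrences are aggregated over iterations.

**Permutation null.** The identical engine re-run with case/control labels
freshly permuted at every iteration; observed vs permuted outer-AUC
distributions (and per-protein AUC/SD summaries) quantify how much of the
observed performance survives label destruction.

**Subtyping.** Cases only, restricted to the analytes that occurred in
selected panels: K-means (Lloyd's algorithm, k-means++ seeding, best of 25
restarts) in Euclidean space on standardised log2 abundance, with k chosen
by the average-silhouette method; per-protein rank-sum differential
expression with *uncapped* Bonferroni correction (m × p, reported even when
above 1); clinical association tables (rank-sum for continuous variables,
chi-square without continuity correction plus Fisher exact for binary
ones); and a permutation test for whether extreme laboratory values
concentrate in one cluster.

## Worked example

```r
library(cmpanel)

cohort <- generate_cohort(synth_config(seed = 42))
cohort
#> <synthetic_cohort> 23 cases / 50 controls x 226 proteins
#>   planted signal: P001, P002, P003, P004
#>   subtype markers: P005, P006, P007, P008, P009, P010, P011, P012
#>   graph: 226 nodes, 475 edges

labels <- setNames(cohort$metadata$label, cohort$metadata$sample_id)
run <- select_panels(cohort$abundance, labels, n_iter = 100, seed = 42)
summary(run, n = 5)
#> Iterated panel selection (100 iterations)
#> Outer validation AUC: median 0.840, IQR [0.740, 0.900]
#>
#> Top panels:
#>                panel count frequency
#>  P001+P002+P003+P004     8      0.08
#>  P002+P003+P004+P081     7      0.07
#>  P002+P003+P004+P130     5      0.05
#>  P002+P003+P004+P198     5      0.05
#>  P002+P003+P004+P218     3      0.03
#>
#> Top proteins (recurrent = in >= 5 selected panels):
#>  protein count frequency recurrent
#>     P002    78      0.78      TRUE
#>     P004    78      0.78      TRUE
#>     P003    70      0.70      TRUE
#>     P001    29      0.29      TRUE
#>     P130    28      0.28      TRUE
```

The modal panel is exactly the four planted signal proteins, and all four
head the membership frequencies — the behaviour the engine is designed to
produce when a real signal exists. Against the permuted-label null the
picture collapses to chance:

```r
perm <- select_panels(cohort$abundance, labels, n_iter = 100,
                      seed = 43, permute = TRUE)
median(perm$iterations$outer_auc)
#> [1] 0.5
```

Case-only subtyping on a marker-carrying candidate set recovers the
planted severe subtype and its clinical correlates:

```r
cohort2 <- generate_cohort(synth_config(n_subtype_markers = 16,
                                        subtype_effect = 3, seed = 42))
cases <- cohort2$abundance[cohort2$metadata$label == "case", ]
sel <- c(cohort2$truth$subtype_markers,
         setdiff(colnames(cases), c(cohort2$truth$signal_proteins,
                                    cohort2$truth$subtype_markers))[1:8])
fit <- cluster_subtypes(cases, candidates = sel, seed = 42)
fit
#> <subtype_fit> 2 clusters (sizes 7/16) over 24 candidate proteins
#>   mean silhouette by k:  k=2 0.356, k=3 0.233, k=4 0.175, k=5 0.151, k=6 0.173
#>   14 protein(s) differential after Bonferroni correction

md <- cohort2$metadata[cohort2$metadata$label == "case", ]
clinical_association(md, fit$assignments,
                     continuous = c("delivery_week", "max_systolic",
                                    "max_diastolic", "protein_24h"))$continuous
#>        variable median_cluster1 median_cluster2  raw_p bonferroni_p
#> 1 delivery_week            35.3            33.7 0.1353       0.5411
#> 2  max_systolic           168.6           167.1 0.6244       2.4974
#> 3 max_diastolic            86.1            93.0 0.1353       0.5411
#> 4   protein_24h           211.2           536.1 0.0111       0.0444
```

The 7/16 split matches the planted subtype assignment exactly, and the
24-hour urinary protein difference survives the (uncapped) Bonferroni
correction over the four-variable family.

`run_workflow(workflow_config(...), out_dir)` chains all stages
(simulate/read → preprocess → screen → select-panel → permute → cluster)
and writes CSV artifacts plus a JSON run manifest; with the same
configuration and seed the CSV artifacts are byte-identical.

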