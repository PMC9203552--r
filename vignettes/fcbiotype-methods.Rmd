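---
title: "Biotyping alcohol misuse from functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biotyping alcohol misuse from functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcbiotype)
```

## The problem

Alcohol misuse (AM) — meeting at least one DSM-IV criterion for alcohol use
disorder — is behaviorally heterogeneous, and case–control analyses that
pool all AM subjects tend to wash out subgroup-specific neural signatures.
`fcbiotype` implements a complete, tested pipeline for a subtyping-first
analysis of resting-state functional connectivity (FC):

1. **Motion QC**: framewise displacement (FD) and DVARS scrubbing, band-pass
   filtering, and Pearson FC computed over uncensored frames only.
2. **Covariate residualization**: age, sex, and head motion (the count of
   censored frames) regressed out of each FC feature, with coefficients
   fitted on the training split and frozen.
3. **Feature screening**: Spearman correlation of each FC feature with ten
   alcohol-use metrics and eight ASR psychiatric scores, union a Wilcoxon
   AM-vs-control rank-sum screen, at thresholds 0.05 / 0.005 / 0.0005.
4. **Biotype discovery**: dimension reduction of the screened AM features to
   2–4 dimensions; K-means and Ward clustering; the number of clusters
   chosen by the Variance Ratio Criterion; undersized clusters omitted.
5. **Classification**: a baseline AM-vs-control network and a biotype-aware
   network with a joint objective, compared on a held-out replication split
   by AUC and G-score, with permutation inference.
6. **Genetics**: classifier scores (or any quantitative trait) tested for
   SNP association under a linear mixed model with a genetic relationship
   matrix (GRM) random effect, with LD-adjusted Bonferroni correction.

A synthetic-cohort generator with planted ground truth makes every stage
testable end to end; it is first-class, exported code, not a test fixture.

## Motion QC

FD is the sum of the six absolute realignment-parameter differentials. The
printed formula sums raw angular differences with translations; the package
converts rotations to arc length on a 50 mm sphere by default so the
conventional 0.2 mm threshold applies to all six terms
(`rotation_arc = FALSE` gives the literal sum). DVARS is the root
across-unit mean square of the frame-to-frame % BOLD change; the threshold
75 is taken as-is on the simulated intensity scale and is configurable,
since the scaling convention of the original threshold is not recoverable
from the published description. The first frame has no differential;
`FD(1) = DVARS(1) = 0` and the first frame is never censored by definition.

Censoring marks frames above either threshold plus one frame before and two
after, then removes surviving runs shorter than five frames. The rules are
idempotent and local: padding a trace with clean frames does not change the
interior of the mask.

The band-pass (0.009–0.08 Hz) is realized as a cascade of zero-phase
order-2 Butterworth high- and low-pass filters (`signal::filtfilt`, which
squares each magnitude response). A single order-4 band-pass transfer
function at a normalized lower edge of 0.013 (TR = 0.72 s) is numerically
fragile; the cascade is stable and meets the contract the tests enforce:
at least 90% amplitude at 0.04 Hz, at most 20% at 0.2 Hz, DC removed.
Filtering precedes censoring by default; the original ordering is not
documented, and the mask is computed from the unfiltered series either way.

Residualization fits ordinary least squares per FC feature on the training
split only (`adjusted = raw − X·beta + training mean`); validation and
replication panels reuse the frozen coefficients. Scan-2 panels are
residualized with a scan-2 model fitted on the same training subjects.

## Feature screening

"Correlated with one or more of the 18 metrics" is implemented as the
minimum two-sided Spearman p across metrics with no multiplicity correction
— union semantics; under independence a null feature is selected at rate
`1 − 0.95^18 ≈ 0.60` at alpha 0.05, and the tests verify this. P-values use
the t approximation on average-rank correlations, vectorized across the
panel; the Wilcoxon screen uses exact p-values when both groups have at
most 20 subjects and the tie-corrected continuity-corrected normal
approximation otherwise. Whether the original Spearman screen included
controls is ambiguous; `screen_features(population = "all")` is the default
(controls carry metric values too) and `"am"` is available. Masks at the
three thresholds are nested by construction.

## Biotype discovery

The reducer is a pluggable contract: any deterministic-under-seed function
`f(x, d, seed)` that preserves between-subject proximity conforms, and a
nonlinear reducer such as UMAP can be supplied through the `reducer`
argument. The built-in default is principal component analysis with a fixed
sign convention: it is exactly reproducible, dependency-free, and recovers
the planted biotype geometry of the synthetic cohorts, where the
between-biotype structure is linear by construction. Real FC manifolds are
more nonlinear than the generator's, which is the main caveat when
transferring conclusions from synthetic tests to real data.

Each (alpha, dimension) grid cell is clustered with K-means (10 restarts,
best inertia) and Ward (`ward.D2`) linkage at k in 2–4; the cell's solution
is the method/k pair with the best Variance Ratio Criterion
(Calinski–Harabasz), ties to the smaller k. Cells whose mask selects fewer
features than dimensions are skipped with a warning. Clusters below
`min_cluster_size` (default 20, chosen to separate the published omitted
n = 18 cluster from the smallest retained n = 46 cluster) are flagged
omitted: excluded from biotype-level analyses, retained as AM for the
overall classification. The grid cell itself is selected downstream by
validation AUC, never by the VRC.

## The classifiers

Both classifiers consume the full residualized FC vector (all
`R(R−1)/2` features), not the screened subset. Each biotype head is its own
subnetwork: a grouped linear stage maps each ROI's pairwise features to a
small per-ROI code (`code_dim`, default 2), the concatenated codes pass
through one `tanh` hidden layer (default width 16; 8 in the scaled-down
study conditions), and a logistic unit scores biotype-vs-control
membership. Parameters grow as `p × code_dim` per head rather than
`p × hidden`, the stated motivation for feature grouping. The baseline
model is the same architecture with a single head trained directly on
AM-vs-control.

The joint objective is

```
L = sum_b CE(s_b; biotype-b vs {controls + other retained biotypes})
    + lambda * CE(combined; AM vs control),
```

with `combined = sigmoid(v0 + sum_b softplus(v_b) * s_b)`. Three design
points deserve explanation:

* **Head negatives include the other retained biotypes.** With
  controls-only negatives, the overall AM term pushes every head high for
  every AM subject and the per-biotype scores lose all one-vs-rest
  specificity; the second-scan consistency analysis (weighted one-vs-rest
  AUC) then degenerates to chance. Adding the other biotypes as negatives
  supervises exactly the contrast that analysis measures.
* **The combination is a logistic link on the nonnegative weighted sum,**
  not a convex combination. A convex combination caps the combined score of
  a subject whose evidence lives in one head, forcing heads to de-specialize
  during training; the logistic link with a trained bias behaves like a
  soft OR over biotype evidence while staying in [0, 1] and monotone
  nondecreasing in every head score.
* **`lambda` (default 1) ramps in linearly over the first third of
  training** so heads first fit their own contrasts; early-stopping
  snapshots (by validation AUC of the combined score, every 5 epochs) are
  restricted to the post-ramp phase.

Training is full-batch Adam with decoupled weight decay (default 0.1) —
with tens to hundreds of times more features than subjects both models
otherwise memorize the training split. All seeds are explicit and the
fitted object serializes and reloads to identical scores. Omitted-cluster
AM subjects appear only in the overall AM term; biotypes with fewer than 5
training subjects are merged into that term with a warning.

The decision threshold is the midpoint between adjacent sorted unique
validation scores minimizing |specificity − sensitivity|, ties resolved
toward higher specificity and then the lower threshold.

## Permutation inference and scan-2 consistency

Permutation tests use the add-one estimator
`p = (1 + #{null ≥ observed}) / (n_perm + 1)` — never zero, minimum
`1/(n_perm+1)` (1/201 at the conventional 200 permutations). Labels permute
independently within the discovery and replication strata, preserving each
stratum's AM fraction. The pipeline-level test
(`replication_significance()`) retrains the classifier per permutation with
the clustering solution held fixed: subjects that remain AM keep their
cluster labels, permuted-in AM subjects enter only the overall AM term.
Recomputing the feature masks and clustering per permutation is the
stricter reading of the original procedure, but the published description
("on the basis of the selected AM biotyping assignment solution") indicates
the clustering was fixed, and that reading is followed; the retraining
budget is recorded in the result.

Scan-2 consistency scores the scan-1-trained model on the residualized
second-scan panel of the clustered subjects and reports per-biotype
one-vs-rest AUCs among retained AM subjects, combined as a
subject-count-weighted mean.

## Genetics

SNP QC retains a SNP when call rate ≥ 95%, the exact Hardy–Weinberg p-value
(Levene–Haldane enumeration, computed in the pooled tested sample) is
≥ 1e−7, and the folded minor allele frequency is ≥ 5% in every population;
the three rules commute and each failure is flagged. The exact HWE p-value
is conservative, as for any discrete test; a mid-p variant is provided and
used where calibration (uniformity under the null) matters, while QC
thresholding keeps the plain exact p.

The GRM is `Z Zᵀ / m` over standardized dosages (missing imputed to the SNP
mean, centered at `2p`, scaled by `sqrt(2p(1−p))`; monomorphic SNPs
skipped). The association model is
`y = W a + x b + u + e`, `u ~ N(0, σg² K)`, `e ~ N(0, σe² I)`: the variance
ratio `λ = σg²/σe²` is profiled by REML in the eigenbasis of K (one
decomposition shared across all SNPs), searched on a log grid then refined,
with the `λ → 0` boundary always compared; the Wald statistic `(b/se)²` is
referred to chi-square with 1 df. At `K = I` the fit reduces exactly to
OLS, which the tests assert at relative 1e−6. Race enters as
reference-coded indicators.

LD blocks use a deterministic greedy rule — a SNP joins the current block
while its squared dosage correlation with the block's seed is ≥ 0.5 within
a 50-SNP window, within chromosome. The original confidence-interval-based
blocking differs in boundary placement, but only the independent-test count
`m` (blocks plus singletons) feeds the corrected threshold `alpha / m`,
which is far less conservative than correcting for every correlated SNP.
Four traits are tested (three biotype scores and the overall AM score) with
no cross-trait correction, matching the original analysis.

## The synthetic cohort generator

`generate_cohort()` draws, under one seed, a subject table (age uniform
22–35; sex ~ 45% male; race mix EA/AA/other = 0.744/0.139/0.117, the
composition of the motivating cohort; AM prevalence 0.33 per split),
two FC panels, genotypes with twin structure, and ground truth. All
randomness flows through the configuration seed; identical configurations
are bit-identical.

The generative chain is latent-severity based: every subject carries one
latent score per biotype; AM subjects of biotype *b* sit 1.5 SD high on
their own score; signal FC features and clinical metrics are noisy monotone
functions of it, producing the rank-correlation structure the Spearman
screen targets. FC noise is Gaussian on the Fisher-z scale and
back-transformed, so correlations stay in (−1, 1). Scan 2 adds independent
z-scale noise (SD 0.15) to scan 1.

Two planted FC effect classes emulate the heterogeneity that motivates
subtyping:

* **Signal features** (default 20 per biotype, disjoint across biotypes):
  shifted by `effect_size` noise-SD units with a random fixed sign per
  feature — connectivity effects are a mix of increases and decreases.
* **Contrast features** (default 60, shared): on each, one biotype connects
  *more* and another *less* than controls. Pooled over AM subjects these
  effects cancel, so they are nearly invisible to a case–control contrast,
  while they strongly separate biotypes. This mirrors the reported edge
  effects in which one biotype shows higher and another lower connectivity
  on the same circuit, and it is what makes biotype knowledge genuinely
  useful: without such features the pooled and per-biotype problems are
  equally easy and subtyping cannot help.

The default `effect_size = 0.8` places the baseline classifier near
replication AUC 0.68 and the biotype-aware classifier near 0.83 — the
operating regime of the motivating study. Clustering-recovery conditions
use `effect_size = 1.5`, where the planted partition is recovered with
adjusted Rand index ≥ 0.8 and k = 3 selected essentially always.

Drinking-frequency metrics are ordered biotype 3 > biotype 1 > biotype 2
and the antisocial ASR score is elevated in biotype 2, matching the
reported phenotype profile (moderate AM drinks most, comorbid least but
with antisocial elevation). Alcohol metrics are clipped to the normalized
0–5 severity scale.

Genotypes: founders drawn allele-wise at per-SNP MAFs uniform on
[0.05, 0.5]; MZ twins copy genotypes; DZ twins are gene-dropped from shared
simulated parents (expected GRM entries ≈ 1 and ≈ 0.5). The causal SNP
(MAF `causal_maf`) adds `causal_beta` per minor allele to the causal
biotype's latent score for **all** subjects — that latent is the
quantitative trait an association scan should recover, mirroring the use of
continuous classifier scores as traits.

`generate_motion_and_bold()` plants motion outliers as persistent level
shifts on a smooth sub-threshold baseline, so FD exceeds 0.2 mm exactly at
the requested frames, with matching DVARS steps in the BOLD panel.

What the generator does **not** emulate: hemodynamics, spatial structure of
the 268-ROI atlas, nonlinear FC manifolds, non-Gaussian FC marginals,
population stratification of allele frequencies, and LD beyond what the
finite founder pool induces. Passing tests therefore demonstrate the
pipeline's statistical machinery and its leakage hygiene, not performance
on real rsFMRI.

## Simulation scale

The packaged study conditions are scaled down for routine re-running on one
CPU: 40-ROI panels (780 FC features) for clustering/classification
conditions, 300 training / 80 validation / 120 replication subjects
(matching the published training-set order of magnitude), 500-SNP panels
with a replication split of 200 for the genetic-recovery conditions, and
reduced training budgets (150–200 epochs, hidden width 8). The full-scale
geometry (268 ROIs, 35,778 features) runs through the identical code path
and is exercised by the panel-width tests; seed counts of the recovery
studies (50 seeds for clustering, 20 for classification and genetics, 200
and 50 permutations) follow the stated protocols.

## Known limitations

* The default reducer is linear; on real data a nonlinear reducer should be
  plugged in, and the published analysis suggests a linear reduction may
  fail to reveal clustering structure at all.
* The exact architecture and combination rule of the original networks are
  not public; the implementation honors the stated constraints (grouped
  feature extraction, parameter budget, weighted-sum combination, joint
  objective) but is not a replication of the original weights.
* The LMM profiles a single variance ratio by REML; multi-component or
  sparse-kinship models are out of scope.
* The permutation test's strict reading (re-screening and re-clustering per
  permutation) is not the default; the recorded choice follows the
  published description.
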