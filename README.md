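# fcbiotype

Data-driven biotyping of alcohol misuse (AM) from resting-state
functional-connectivity (FC) features, with biotype-aware classification and
quantitative-trait genetic association.

Pooling all problem drinkers into one case group blurs subgroup-specific
neural signatures: connectivity edges on which one subgroup connects *more*
and another *less* than controls cancel in a case–control contrast.
`fcbiotype` implements the subtyping-first alternative as a reusable,
tested pipeline for researchers working with ROI-level rsFMRI time series,
clinical alcohol-use/psychiatric metrics, and SNP genotypes:

* **Motion QC & FC construction** — framewise displacement
  `FD(t) = |Δdx| + |Δdy| + |Δdz| + r·(|Δα| + |Δβ| + |Δγ|)` (rotations on a
  50 mm sphere) and `DVARS(t) = √⟨(I(t) − I(t−1))²⟩`; frames with
  FD > 0.2 mm or DVARS > 75 censored together with 1 frame before and 2
  after, kept runs < 5 frames dropped; 0.009–0.08 Hz zero-phase band-pass;
  Pearson FC over uncensored frames (35,778 unique edges for 268 ROIs);
  age/sex/head-motion residualization frozen on the training split.
* **Feature screening** — per-edge Spearman tests against 10 alcohol-use +
  8 ASR metrics ("significant for one or more" union semantics) plus
  Wilcoxon AM-vs-control rank-sum tests, united at α ∈ {0.05, 0.005, 0.0005}.
* **Biotype discovery** — pluggable proximity-preserving reducer (PCA
  default, UMAP-compatible contract) into 2–4 dimensions; K-means and Ward
  clustering with k ∈ {2,3,4} chosen by the Variance Ratio Criterion
  `[tr(B)/(k−1)]/[tr(W)/(n−k)]`; undersized clusters omitted.
* **Classification** — per-biotype subnetworks (grouped per-ROI feature
  extraction, parameter count ∝ p·code_dim) trained with the joint loss
  `Σ_b CE(s_b) + λ·CE(combined)` where
  `combined = σ(v₀ + Σ_b softplus(v_b)·s_b)`; baseline single-head model for
  comparison; AUC, G-score `√(sens·spec)`, |spec − sens|-balancing
  threshold; add-one permutation tests; scan-2 weighted one-vs-rest AUC.
* **Genetics** — SNP QC (call rate ≥ 0.95, exact HWE p ≥ 1e−7, per-population
  MAF ≥ 0.05), GRM `ZZᵀ/m`, REML linear mixed model
  `y = Wa + xb + u + e`, `u ~ N(0, σ_g²K)` with Wald tests, and LD-adjusted
  Bonferroni (α / number of independent blocks).
* **Synthetic cohorts** — `generate_cohort()` plants biotype structure
  (including the opposite-signed "contrast" edges that defeat pooled
  contrasts), rank-correlated clinical metrics, MZ/DZ twin kinship, and one
  causal SNP, so every stage has recoverable ground truth.

## Worked example

Simulate a cohort at the packaged study conditions, run discovery
(screens → 9-cell grid → clustering → classifiers → selection on the
validation split), then score the untouched replication split:

```r
library(fcbiotype)

cohort <- generate_cohort(cohort_config(n_roi = 40, n_snps = 200, seed = 42))
cohort
#> <fcb_cohort> 500 subjects (165 AM), 780 FC features, 200 SNPs
#> replication       train  validation
#>         120         300          80

run <- run_discovery(cohort, min_cluster_size = 10,
                     classifier = list(hidden = 8), seed = 42)
run
#> <fcb_run> selected cell alpha0.05_d2 (alpha = 0.05, d = 2, k = 3, kmeans)
#>   validation AUC: biotype-aware 0.873, baseline 0.682

run_replication(run, cohort)
#> # A tibble: 2 x 5
#>   model           auc sensitivity specificity gscore
#> 1 biotype_aware 0.841       0.675       0.862  0.763
#> 2 baseline      0.725       0.475       0.85   0.635
```

The grid selected a 3-cluster K-means solution (the planted number), and
the biotype-aware classifier generalizes better than the pooled baseline
(replication AUC 0.841 vs 0.725) because a third of the planted edges carry
opposite-signed effects across biotypes that cancel in the pooled contrast.
`tidy(run)` lists all grid cells; `glance(run)` is a one-row summary;
`autoplot(run$grid[[run$selected_cell]])` draws the clustered embedding.

Association of a quantitative trait with the genotype panel, GRM-corrected:

```r
subj <- cohort$subjects
disc <- subj$split != "replication"
dos  <- cohort$genotypes$dosage
keep <- which(snp_qc(dos[disc, ], subj$race[disc])$retained)

scan <- assoc_scan(cohort$truth$trait[subj$subject_id[disc]],
                   dos[disc, keep], subj[disc, c("age", "sex", "race")],
                   compute_grm(dos[disc, keep]),
                   snp_info = cohort$genotypes$snp_info[keep, ])
blocks <- ld_blocks(dos[disc, keep], cohort$genotypes$snp_info$chrom[keep])
head(dplyr::arrange(scan, p), 3)
#>   snp     chrom    pos   maf  beta     se            p
#> 1 snp0100     2 250000 0.304 0.490 0.0882 0.0000000281
#> 2 snp0139     3 195000 0.307 0.270 0.0974 0.00546
#> 3 snp0038     1 190000 0.403 0.247 0.0926 0.00765
sum(ld_adjusted_bonferroni(scan$p, blocks))
#> [1] 1
```

The planted causal SNP (`snp0100`, true effect 0.5 per minor allele) ranks
first with an estimated effect of 0.49 and is the only SNP surviving the
LD-adjusted Bonferroni threshold (0.05 / 196 independent blocks);
`autoplot(scan, blockset = blocks)` draws the Manhattan plot.

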