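# hdscore

Transcriptome-derived **HDAC scoring** of the gastric-cancer tumor
microenvironment.

Histone deacetylases (HDAC1–11) and sirtuins (SIRT1–7) — an 18-gene
regulator panel — shape chromatin state and, through it, the immune
composition of tumors. No single family member tracks the tumor
microenvironment (TME) reliably; the panel's joint expression pattern does.
`hdscore` builds a per-sample **HDAC score (HDS)** from bulk expression data
and evaluates it against survival, immune-signature enrichment, and
immunotherapy response. It is aimed at computational oncologists who want a
tested, reproducible implementation of this class of signature-score
pipeline, with a synthetic-cohort generator providing ground truth for every
stage.

## The method

Starting from a gene × sample expression matrix (TPM or FPKM,
log2(x+1)-transformed) and a survival table:

1. **Subtype discovery.** Consensus non-negative matrix factorization on the
   18-gene panel: for each rank *k* ∈ {2,…,5}, many restarts of
   multiplicative-update NMF (Frobenius loss ‖X − WH‖²_F); the consensus
   matrix C(i,j) = fraction of runs assigning samples *i, j* to the same
   argmax cluster; *k* chosen by cophenetic correlation. Three subtypes with
   good / intermediate / poor prognosis emerge.
2. **Differential expression.** Per-gene moderated one-way F tests across
   the subtypes (empirical-Bayes variance shrinkage), Benjamini–Hochberg
   adjusted p < 0.01.
3. **Prognostic screen.** Univariate Cox proportional-hazards regression per
   gene (Newton–Raphson on the Breslow partial likelihood, per-SD hazard
   ratios), Wald p < 0.05. Genes with HR < 1 are *protective* (set A
   candidates), HR > 1 *risk* (set B).
4. **Boruta reduction.** All-relevant feature selection against the subtype
   labels: permuted shadow features, random-forest importance, binomial hit
   tests.
5. **Scoring.** One PCA per gene set on the z-scaled training data;
   per-sample score = oriented PC1 projection on A minus oriented PC1
   projection on B:

   HDS_i = PC1_i(A) − PC1_i(B)

   Samples above the training median are the high-HDS ("hot", better
   prognosis) group.
6. **Evaluation.** Kaplan–Meier / log-rank contrast of the HDS groups,
   Spearman correlation of HDS with ssGSEA immune-signature enrichment, and
   — given a pembrolizumab-style cohort — ROC/AUC of the HDS alone and fused
   with the PD-L1 combined positive score (CPS) and MSI-H status by
   logistic regression, with a nomogram point scale.

## Worked example

```r
library(hdscore)

coh <- generate_cohort(cohort_config(seed = 1))   # 300 samples, 3 subtypes
cfg <- pipeline_config(
  expression      = coh$expression,
  clinical        = coh$survival,
  regulator_genes = coh$truth$regulator_genes,
  seed = 1, outdir = "hds_run")
report <- run_pipeline(cfg)
report
#> <pipeline_report> seed 1 | DEG 110 -> prognostic 110 -> selected 110 (A 60 / B 50)
#>   log-rank high vs low HDS: chisq 121.148, p 3.55e-28

mean(report$setA %in% coh$truth$protective_genes)  # precision vs planted truth
#> [1] 1
```

The report says: 110 of the 510 non-panel genes were subtype-associated and
prognostic, all 110 survived Boruta, and they split into 60 protective (A)
and 50 risk (B) genes — exactly the planted programs. The high-HDS group's
survival advantage is overwhelming (log-rank p ≈ 3.6 × 10⁻²⁸), as designed
into the simulated hazards. Run outputs (`subtypes.tsv`, `deg.tsv`,
`cox_screen.tsv`, `boruta.tsv`, `hds_model.json`, `hds_scores.tsv`,
`km_curves.tsv`, `logrank.tsv`, `run.log`) land in `outdir`; re-running the
same configuration reproduces them byte for byte.

A thin CLI wrapper for shell use lives at `inst/cli/hds.R`
(`simulate` / `fit` / `apply` verbs).

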