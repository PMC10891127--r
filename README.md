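# clonalsig

Clonal gene signature discovery and validation from multi-region tumor
expression data.

## The problem

Prognostic expression signatures are usually built from one biopsy per
tumor. In cancers with high transcriptomic intratumor heterogeneity (the
motivating cases are malignant pleural mesothelioma and non-small-cell
lung cancer), a single biopsy is a noisy draw from a spatially variable
tumor, and signatures built on such measurements reproduce poorly. Genes
whose expression is *clonally fixed* — consistent across regions of one
tumor, variable between tumors — dodge the sampling problem: any biopsy
measures them about equally well.

`clonalsig` is aimed at translational researchers with (a) a small
multi-region RNA-seq cohort (several samples per tumor) and (b) one or
more single-region cohorts with survival follow-up. It identifies clonal
genes from (a), selects a prognostic subset on (b), and evaluates the
resulting risk score.

## Method at a glance

Per gene, on log2 expression:

* **intratumor heterogeneity score** = median over patients of the sample
  SD across that patient's regions;
* **intertumor heterogeneity score** = mean over B = 100 resampling
  iterations of the cross-patient SD of one randomly drawn region per
  patient;
* **Q4 (clonal) genes**: intertumor score above the cohort median,
  intratumor score at or below it;
* **concordance coefficient**: mean over k = 2…min(26, P) of the fraction
  of patients whose regions co-cluster under one-dimensional k-means on
  that gene; clonal genes score near 1.

Signature discovery chains five filters: drop the 50% lowest-median genes
→ univariable Cox screen (p < 0.01) → Q4 intersection → concordance
> 0.2 → lasso-Cox selection at fixed λ = 0.06 followed by an unpenalized
Cox refit giving the weights `c_i`. A sample's risk score is
`S = Σ c_i x_i`; cohorts are split at score tertiles and evaluated by
Kaplan–Meier / log-rank and uni-/multivariable Cox proportional hazards.
Gene-set overlaps are tested with the upper-tail hypergeometric
distribution in log space; copy-number call matrices reduce to per-gene
(or per-band) amplification/deletion frequencies compared across cohorts
by Spearman correlation.

A seeded synthetic-data generator (`sim_config()`,
`simulate_multiregion()`, `simulate_survival_cohort()`, `simulate_cnv()`)
plants clonal/subclonal/null genes and a Cox-model survival signal with
known ground truth, so the entire pipeline is testable without any data
download.

## Worked example

```r
library(clonalsig)

cfg <- sim_config(n_genes = 1000)                       # 26 patients x 3 regions
mr  <- simulate_multiregion(cfg, seed = 1)              # multi-region cohort + truth
sv  <- simulate_survival_cohort(cfg, mr$truth, n = 300, seed = 2)

sig <- run_discovery(mr$cohort, sv$cohort, seed = 3)
#> filter chain: input 1000 -> expression_filter 500 -> prognostic 15 -> q4 10 -> concordance 10 -> lasso 10

planted <- names(mr$truth$beta)[mr$truth$beta != 0]
sum(sig$genes %in% planted)                             # 10 of 10 signature genes planted

ev <- evaluate_signature(sig, sv$cohort,
                         covariates = c("age", "sex", "stage", "histology"))
ev
#> RiskStratification: 300 samples (low 100, intermediate 100, high 100)
#> log-rank across tertiles: p = 7.31e-25
#> univariable Cox on score: HR = 2.718 [2.244, 3.293], p = 1.69e-24
```

The provenance line is the filter chain: 1,000 simulated genes, 500 after
the median-expression filter, 15 passing the Cox screen, 10 surviving the
Q4 and concordance clonality filters, 10 selected by the lasso. All ten
are planted prognostic-clonal genes, the tertiles split 100/100/100, and
the high-score tertile has markedly worse survival (log-rank p ≈ 7e-25);
the univariable hazard ratio of 2.7 per score unit recovers the planted
effect (the generator's true score coefficient is 1, e¹ ≈ 2.72).

Gene-set overlap, with the worked numbers from the motivating study (7,064
shared genes, Q4 sets of 948 and 472 with 208 genes in common):

```r
hypergeometric_overlap(N = 7064, K = 948, n = 472, k = 208, tail = "gt")
#> Overlap: 208 of sets 948 and 472 in universe 7064
#> enrichment = 3.28, P(X > 208) = 2.262e-66
```

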