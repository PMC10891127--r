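---
title: "Clonal gene signature discovery from multi-region tumor expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal gene signature discovery from multi-region tumor expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalsig)
```

## The problem

Bulk expression biomarkers are usually derived from a single biopsy per
tumor. In cancers with substantial transcriptomic intratumor heterogeneity —
malignant pleural mesothelioma and non-small-cell lung cancer are the
motivating examples — a single biopsy is a noisy draw from a spatially
variable mixture, and prognostic signatures built on such measurements
travel poorly between cohorts. Genes whose expression is *clonally fixed* —
consistent across regions of one tumor yet variable between tumors, often
because they sit on clonal copy-number events — escape this sampling
problem: any biopsy measures them about equally well. `clonalsig`
implements a pipeline that uses a small multi-region RNA-seq cohort to
identify such genes and a larger single-region survival cohort to select a
prognostic subset of them.

## Heterogeneity scores and the Q4 quadrant

All scores operate on log2-scale expression. For gene $g$ with patients
$p = 1 \dots P$, each with $R_p \ge 2$ regional samples:

* **intratumor score**: the sample SD ($n-1$ denominator) of $g$'s
  expression across patient $p$'s regions, median over patients. Units:
  log2 expression.
* **intertumor score**: one region is drawn uniformly at random per patient
  and the cross-patient sample SD of the resulting single-region cohort is
  computed; the score is the mean over $B$ such draws (default
  $B = 100$). The region draw is shared by all genes within an iteration,
  preserving cross-gene correlation and making the whole matrix computable
  in one pass. A small test cohort admits exhaustive enumeration of all
  $\prod_p R_p$ region combinations, which the test suite uses as the
  oracle for the resampling estimator.

A gene is a **Q4 (clonal) gene** when its intertumor score strictly exceeds
the median intertumor score while its intratumor score is at or below the
median intratumor score, both medians taken over the gene set being
classified. The median quadrant split is the only parameter-free cut; the
strict/non-strict pairing guarantees that a completely degenerate score
distribution (all genes tied) yields zero Q4 genes rather than half the
genome.

## Clustering concordance

The concordance coefficient asks a complementary question: if all
region-samples are clustered on one gene's expression alone, do each
patient's regions stay together? For each $k$ in `k_range` (default
$2 \dots \min(26, P)$) the gene's values are clustered by one-dimensional
k-means; the per-$k$ concordance is the fraction of patients whose regions
share a cluster, and the coefficient is the mean over $k$. Genes with a
coefficient strictly above 0.2 are retained.

Numerical choice: plain random-restart Lloyd iterations proved unreliable
on these one-dimensional, strongly multimodal profiles — at 10 restarts
they frequently return local optima whose concordance differs from the
exact optimum (the suite contains an exact dynamic-programming 1-D k-means
oracle exploiting the contiguity of optimal clusters in sorted order).
Each restart therefore seeds centers kmeans++-style (distance-proportional
sampling of data points) and refines with Hartigan–Wong; the test bench
requires agreement with the exact oracle on at least 95% of (gene, k)
pairs at the default 10 restarts. When a gene has at most $k$ distinct
values, each distinct value becomes its own cluster, which sidesteps
empty-cluster failures.

A caveat worth recording: the coefficient is *not* invariant under
arbitrary strictly monotone transforms of the data, even at $k = 2$ —
optimal variance-based splits depend on spacings, not only ranks. Only
contiguity of clusters in sorted order is rank-determined. The suite
asserts invariance for affine and for convex monotone transforms on
well-separated data, where the optimal split genuinely cannot move.

## The five-step discovery chain

`run_discovery()` executes, in order, on a discovery survival cohort (step
1, 2, 5) and a multi-region cohort (steps 3, 4):

1. **expression filter** — remove the $\lfloor G/2 \rfloor$ genes with the
   lowest median expression ("filter out 50%" is read as *removing* half;
   with an odd gene count the kept set is the larger half);
2. **prognostic screen** — univariable Cox proportional hazards per gene,
   keep Wald $p < 0.01$ (Efron tie handling; Wald is the conventional
   default of `survival::coxph`);
3. **Q4 intersection** — heterogeneity scores are computed over *all*
   genes of the multi-region cohort (the parameter-free universe; the
   alternative, scoring only screen survivors, shifts the medians and
   makes the quadrant depend on the discovery cohort);
4. **concordance filter** — coefficient strictly greater than 0.2;
5. **lasso-Cox selection** — L1-penalized Cox partial likelihood via
   `glmnet` at fixed $\lambda$ (default 0.06, on glmnet's standardized
   scale — the scale on which such tuning values are conventionally
   reported), followed by an **unpenalized multivariable Cox refit** on
   the selected genes. The refit coefficients are the signature weights
   $c_i$; the penalized coefficients are kept alongside for comparison.

Each step logs its surviving gene count (`provenance`), which is monotone
non-increasing by construction, and any step that empties the candidate
set aborts with an error naming the step.

The per-sample prognostic score is the dot product
$S = \sum_i c_i x_i$ with $x_i$ the log2 expression of signature gene
$i$. Cohorts are stratified at the 1/3 and 2/3 rank quantiles of their own
score distribution (no frozen cutpoints; validation cohorts differ in
platform and scale). Ties are broken by stable sample order; when $n$ is
not divisible by 3 the remainder goes to the higher group(s), e.g. 10
samples split 3/3/4. Evaluation couples Kaplan–Meier curves and the
k-group log-rank test across tertiles with univariable Cox on the
continuous score and multivariable Cox adding clinical covariates
(requested covariates that are absent or constant are dropped with a
warning rather than failing a whole validation run).

## Normalization and input handling

Expression tables are normalized by scaling every sample to the cohort
*median* total signal and then $\log_2(x + 1)$; the pseudocount of 1 maps
zero counts to 0 and is configurable. For inputs already normalized
upstream (FPKM/RSEM) the library rescaling can be switched off
(`library_normalize = FALSE`), since whether such data should be
re-normalized is a judgment call left to the analyst. Duplicate gene ids
collapse to the row with the highest median expression. An optional
short-survivor exclusion (e.g. overall survival below 30 days, typical for
peri-operative mortality) is off by default and enabled per cohort.

## Overlap and copy-number statistics

Gene-set overlap significance uses the upper tail of the hypergeometric
distribution, computed in log space so p-values down to the ~1e-300 range
remain representable. Two tail conventions are exposed: the inclusive
$P(X \ge k)$ (default, the standard enrichment definition) and the strict
$P(X > k)$, which is what a direct `phyper(k, K, N-K, n, lower.tail =
FALSE)` call returns and therefore what many published overlap p-values
actually are; reproducing such a published value requires `tail = "gt"`.

Copy-number profiles reduce a genes × samples call matrix (discrete
−1/0/+1 or real-valued segment means thresholded at ±0.3 by default) to
per-gene amplification and deletion frequencies; band-level profiles are
unweighted means over member genes; cross-cohort comparison uses Spearman
rank correlation with the asymptotic p-value (ties make the exact
permutation p unavailable).

## The synthetic test bench

`sim_config()` defines the generative model the whole test suite runs on.
Its defaults emulate the motivating study design: 26 patients × 3 regions
for the multi-region cohort, 2,000 genes. Gene classes on the log2 scale:

| class | between-patient SD | within-patient SD | fraction |
|---|---|---|---|
| clonal | 2.0 | 0.2 | 0.15 |
| subclonal | 0.2 | 2.0 | 0.15 |
| null | 0.6 | 0.6 | 0.70 |

The clonal fraction mirrors the ~15% Q4 fraction reported in multi-region
tumor studies. Null genes carry intermediate noise on *both* axes:
regional sampling and measurement noise affect every gene, while clonal
genes are distinctly tight within a tumor. (A degenerate alternative —
null genes exactly as tight as clonal ones — would make the Q4 median
split a coin flip for true clonal genes and tests meaningless.) Per-gene
baseline means are drawn from $N(6, 2^2)$ so the median-expression filter
has signal to act on.

Survival follows an exponential-baseline Cox model: 40 of the clonal genes
get a log-hazard effect of $\beta = 0.2$ per unit log2 expression (HR
≈ 1.5 per expression SD per gene — typical for individually detectable
prognostic genes; jointly, a linear-predictor SD of ~2.5), plus modest
clinical effects (age 0.02/yr, male 0.1, stage II/III 0.3/0.6, biphasic
histology 0.4). Censoring is an independent exponential time whose rate is
calibrated to the target censoring fraction (default 0.3) at the average
hazard. Times are continuous days, so tie handling never matters in the
bench itself.

What the generator does **not** emulate: negative-binomial count
dispersion, gene–gene co-expression beyond the shared patient effect,
batch effects, platform differences, or non-proportional hazards. Passing
tests therefore demonstrate correctness of the estimators and selection
machinery under the stated model, not robustness to real RNA-seq
artifacts.

Problem sizes used by the bench (chosen to exercise each claim at the
smallest informative scale): heterogeneity recovery at 26 × 3 × 2,000
genes over 20 seeds; end-to-end discovery at n = 300 with 10 seeds;
Cox type-I error at n = 200 over 2,000 replicates; oracle enumeration
on 5-patient cohorts (3⁵ combinations) and 200 genes for the clustering
oracle.

## Known limitations

* The concordance coefficient's k-means is a heuristic; the ≥95%
  oracle-agreement requirement is an empirical property of the default
  restart count, not a guarantee.
* The univariable screen at $p < 0.01$ admits, by construction, about 1%
  of the non-prognostic clonal genes; on synthetic cohorts these survive
  the later clonality filters (they *are* clonal) so the final signature
  retains a corresponding share of false positives. The lasso step at a
  fixed penalty does not remove them preferentially; it prunes weak true
  effects at a similar or higher rate.
* $\lambda$ is a fixed input (matching how such signatures are reported);
  no cross-validation is provided.
* Mean imputation of signature genes missing from a validation matrix
  shifts scores by a per-sample constant; it preserves ranking only
  approximately and is off by default.
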