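#' Per-gene intratumor heterogeneity scores
#'
#' For every gene, the sample standard deviation (n - 1 denominator) of its
#' log2 expression across each patient's regions is computed, and the score
#' is the median of those per-patient SDs across patients. A low score means
#' the gene is expressed consistently within tumors.
#'
#' @param cohort A `MultiRegionCohort` (log2 expression expected).
#' @return Named numeric vector, one score per gene.
#' @examples
#' sim <- simulate_multiregion(sim_config(n_genes = 50), seed = 1)
#' head(intratumor_scores(sim$cohort))
#' @export
intratumor_scores <- function(cohort) {
  cols <- patient_columns(cohort)
  bad <- names(cols)[lengths(cols) < 2]
  if (length(bad))
    stop("patient(s) with fewer than 2 regions: ", paste(bad, collapse = ", "))
  expr <- unclass(cohort$expr)
  sds <- vapply(cols, function(idx) row_sds(expr[, idx, drop = FALSE]),
                numeric(nrow(expr)))
  if (is.null(dim(sds))) sds <- matrix(sds, nrow = 1)  # single-gene cohort
  stats::setNames(apply(sds, 1L, stats::median), rownames(expr))
}

# sample SD of each row (n-1 denominator), vectorized
row_sds <- function(m) {
  k <- ncol(m)
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (k - 1))
}

#' Per-gene intertumor heterogeneity scores by region resampling
#'
#' In each of `B` iterations one region is drawn at random per patient (the
#' same draw for all genes, preserving cross-gene correlation) and the
#' cross-patient sample SD of the resulting single-region cohort is taken
#' per gene; the score is the mean over iterations. A high score means the
#' gene varies strongly between tumors.
#'
#' @param cohort A `MultiRegionCohort`.
#' @param B Number of resampling iterations (default 100).
#' @param seed Optional integer seed for the region draws.
#' @return Named numeric vector, one score per gene.
#' @export
intertumor_scores <- function(cohort, B = 100, seed = NULL) {
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cols <- patient_columns(cohort)
  bad <- names(cols)[lengths(cols) < 2]
  if (length(bad))
    stop("patient(s) with fewer than 2 regions: ", paste(bad, collapse = ", "))
  expr <- unclass(cohort$expr)
  acc <- numeric(nrow(expr))
  for (b in seq_len(B)) {
    pick <- vapply(cols, function(idx) idx[sample.int(length(idx), 1L)], 1L)
    acc <- acc + row_sds(expr[, pick, drop = FALSE])
  }
  stats::setNames(acc / B, rownames(expr))
}

#' Classify Q4 (clonal) genes by median quadrant split
#'
#' A gene is flagged Q4 when its intertumor score strictly exceeds the
#' cohort median of intertumor scores while its intratumor score is at or
#' below the median of intratumor scores — high variability between tumors
#' with consistent expression within tumors, the expression pattern expected
#' of clonally fixed alterations. Medians are computed over the gene set
#' passed in.
#'
#' @param intra,inter Aligned per-gene score vectors.
#' @return Named logical vector.
#' @export
classify_q4 <- function(intra, inter) {
  if (length(intra) != length(inter))
    stop("intra and inter score vectors differ in length")
  if (!is.null(names(intra)) && !is.null(names(inter)) &&
      !identical(names(intra), names(inter)))
    stop("intra and inter score vectors are not aligned to the same genes")
  flag <- inter > stats::median(inter) & intra <= stats::median(intra)
  names(flag) <- names(intra)
  flag
}

#' Full per-gene heterogeneity profile
#'
#' Convenience wrapper computing intratumor and intertumor scores and the Q4
#' flag in one pass.
#'
#' @inheritParams intertumor_scores
#' @return A data.frame with columns `gene`, `intra`, `inter`, `q4`, and
#'   attributes `B` and `seed`.
#' @export
heterogeneity_profile <- function(cohort, B = 100, seed = NULL) {
  intra <- intratumor_scores(cohort)
  inter <- intertumor_scores(cohort, B = B, seed = seed)
  out <- data.frame(gene = names(intra), intra = unname(intra),
                    inter = unname(inter),
                    q4 = unname(classify_q4(intra, inter)),
                    stringsAsFactors = FALSE)
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  out
}
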