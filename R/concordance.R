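#' Clustering concordance coefficient for clonal expression
#'
#' For a single gene, all region-samples are clustered on that gene's
#' one-dimensional expression with k-means for each k in `k_range`
#' (best of `n_restarts` random starts by within-cluster sum of squares).
#' The per-k concordance is the fraction of patients whose regions all land
#' in one cluster, and the coefficient is the mean over k. Genes expressed
#' clonally (tight within a tumor, separated between tumors) co-cluster at
#' every k and score near 1.
#'
#' `k_range` defaults to `2:min(26, n_patients)` so the upper end never
#' exceeds the number of tumors.
#'
#' @param cohort A `MultiRegionCohort`.
#' @param genes Genes to score (default: all genes in the cohort).
#' @param k_range Integer vector of cluster counts.
#' @param n_restarts Random restarts per (gene, k).
#' @param seed Optional integer seed.
#' @return A data.frame with columns `gene` and `coefficient`, with the
#'   per-k concordance matrix (genes x k) as attribute `per_k`.
#' @examples
#' sim <- simulate_multiregion(sim_config(n_genes = 20), seed = 1)
#' head(concordance_coefficients(sim$cohort, k_range = 2:5, seed = 1))
#' @export
concordance_coefficients <- function(cohort, genes = rownames(cohort$expr),
                                     k_range = NULL, n_restarts = 10,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  patients <- cohort$map$patient_id
  n_pat <- length(unique(patients))
  if (is.null(k_range)) k_range <- 2:min(26L, n_pat)
  k_range <- as.integer(k_range)
  if (any(k_range < 2)) stop("k_range must be >= 2")
  if (max(k_range) > ncol(cohort$expr))
    stop("k_range exceeds the number of samples")
  cols <- patient_columns(cohort)
  if (any(lengths(cols) < 2))
    stop("each patient needs >= 2 regions for concordance scoring")
  expr <- unclass(cohort$expr)
  per_k <- matrix(NA_real_, length(genes), length(k_range),
                  dimnames = list(genes, paste0("k", k_range)))
  for (gi in seq_along(genes)) {
    x <- expr[genes[gi], ]
    for (ki in seq_along(k_range)) {
      labels <- kmeans_1d(x, k_range[ki], n_restarts)
      per_k[gi, ki] <- mean(vapply(
        cols, function(idx) length(unique(labels[idx])) == 1L, logical(1)))
    }
  }
  out <- data.frame(gene = genes, coefficient = rowMeans(per_k),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "per_k") <- per_k
  attr(out, "k_range") <- k_range
  attr(out, "n_restarts") <- n_restarts
  out
}

# 1-D k-means, best of n_restarts runs (within-cluster sum of squares).
# Each restart seeds centers kmeans++-style (distance-proportional sampling
# of data points) and refines with Hartigan-Wong; plain random restarts get
# stuck in local optima far too often on multimodal 1-D data. When there are
# at most k distinct values every distinct value becomes its own cluster
# (the degenerate-k handling: empty clusters are impossible).
kmeans_1d <- function(x, k, n_restarts = 10) {
  ux <- unique(x)
  if (length(ux) <= k) return(match(x, ux))
  best <- NULL
  best_ss <- Inf
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers_1d(x, k)
    dup <- duplicated(centers)
    if (any(dup))
      centers[dup] <- sample(setdiff(ux, centers), sum(dup))
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = matrix(centers, ncol = 1),
                                     iter.max = 100L)),
      error = function(e) NULL)
    if (!is.null(km) && km$tot.withinss < best_ss) {
      best_ss <- km$tot.withinss
      best <- km$cluster
    }
  }
  if (is.null(best)) {  # every restart failed; deterministic fallback
    km <- stats::kmeans(x, centers = matrix(stats::quantile(
      ux, probs = seq(0, 1, length.out = k)), ncol = 1), iter.max = 100L)
    best <- km$cluster
  }
  best
}

kmeanspp_centers_1d <- function(x, k) {
  centers <- x[sample.int(length(x), 1L)]
  while (length(centers) < k) {
    d2 <- vapply(x, function(v) min((v - centers)^2), numeric(1))
    centers <- c(centers,
                 if (sum(d2) == 0) sample(x, 1L)
                 else x[sample.int(length(x), 1L, prob = d2)])
  }
  centers
}

#' Filter genes by concordance coefficient
#'
#' Retains genes whose coefficient strictly exceeds the cutoff (default
#' 0.2).
#'
#' @param results Output of [concordance_coefficients()].
#' @param cutoff Retention threshold; strict inequality.
#' @return Character vector of retained gene ids.
#' @export
concordance_filter <- function(results, cutoff = 0.2) {
  keep <- results$gene[results$coefficient > cutoff]
  message(sprintf("concordance filter (> %s): kept %d of %d genes",
                  format(cutoff), length(keep), nrow(results)))
  keep
}
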