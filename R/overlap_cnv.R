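#' Hypergeometric gene-set overlap test
#'
#' Enrichment test for the intersection of two gene sets of sizes `K` and
#' `n` within a universe of `N` genes, observing `k` shared genes. The
#' p-value is the upper tail of the hypergeometric distribution, computed in
#' log space (no underflow down to p near 1e-300). Two tail conventions are
#' offered: `"geq"` (default) is the inclusive tail P(X >= k); `"gt"` is the
#' strict tail P(X > k), i.e. what `phyper(k, K, N - K, n, lower.tail =
#' FALSE)` returns and the convention in wide use for published phyper-based
#' overlap p-values.
#'
#' @param N Universe size.
#' @param K,n Sizes of the two sets.
#' @param k Observed overlap.
#' @param tail `"geq"` or `"gt"`.
#' @return An `OverlapTest` list: `N`, `K`, `n`, `k`, `p`, `log10_p`,
#'   `enrichment` (`k / (K n / N)`), `tail`.
#' @examples
#' hypergeometric_overlap(N = 7064, K = 948, n = 472, k = 208)
#' @export
hypergeometric_overlap <- function(N, K, n, k, tail = c("geq", "gt")) {
  tail <- match.arg(tail)
  for (v in list(N = N, K = K, n = n, k = k))
    if (length(v) != 1 || v != round(v) || v < 0)
      stop("N, K, n, k must be single non-negative integers")
  if (K > N || n > N) stop("set sizes cannot exceed the universe size")
  if (k > min(K, n)) stop("overlap k cannot exceed min(K, n)")
  if (k < max(0, K + n - N))
    stop("overlap k below the minimum possible overlap max(0, K + n - N)")
  q <- if (tail == "geq") k - 1 else k
  logp <- stats::phyper(q, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  structure(list(N = N, K = K, n = n, k = k,
                 p = exp(logp), log10_p = logp / log(10),
                 enrichment = if (K == 0 || n == 0) NaN else k / (K * n / N),
                 tail = tail),
            class = "OverlapTest")
}

#' @export
print.OverlapTest <- function(x, ...) {
  cat(sprintf(
    "Overlap: %d of sets %d and %d in universe %d\nenrichment = %.2f, P(X %s %d) = %.4g\n",
    x$k, x$K, x$n, x$N, x$enrichment, if (x$tail == "geq") ">=" else ">",
    x$k, x$p))
  invisible(x)
}

#' Per-gene amplification and deletion frequencies
#'
#' From a genes-by-samples copy-number matrix (discrete -1/0/+1 calls or
#' real-valued segment means), computes the fraction of samples amplified
#' (value >= `amp_threshold`) and deleted (value <= `del_threshold`) per
#' gene. The default thresholds of +/- 0.3 reproduce the discrete-call path
#' on pre-thresholded data.
#'
#' @param cnv Numeric matrix, genes in rows.
#' @param amp_threshold Amplification call threshold (> 0).
#' @param del_threshold Deletion call threshold (< 0).
#' @return A `CnvFrequencyProfile` data.frame: `gene`, `amp_freq`,
#'   `del_freq`, with attribute `n_samples`.
#' @export
cnv_frequencies <- function(cnv, amp_threshold = 0.3, del_threshold = -0.3) {
  if (!(del_threshold < 0 && 0 < amp_threshold))
    stop("thresholds must satisfy del_threshold < 0 < amp_threshold")
  if (any(!is.finite(cnv))) stop("copy-number matrix contains non-finite entries")
  out <- data.frame(gene = rownames(cnv),
                    amp_freq = rowMeans(cnv >= amp_threshold),
                    del_freq = rowMeans(cnv <= del_threshold),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_samples") <- ncol(cnv)
  class(out) <- c("CnvFrequencyProfile", "data.frame")
  out
}

#' Aggregate gene-level CNV frequencies to chromosome bands
#'
#' Band frequency is the unweighted mean of the member genes' frequencies.
#' Genes absent from the map are excluded (count logged); bands with no
#' profiled genes are dropped with a warning.
#'
#' @param profile A `CnvFrequencyProfile`.
#' @param band_map Named character vector: gene id -> band.
#' @return A `CnvFrequencyProfile` keyed by band (column `gene` holds the
#'   band id).
#' @export
band_aggregate <- function(profile, band_map) {
  mapped <- profile$gene %in% names(band_map)
  if (any(!mapped))
    message(sprintf("band aggregation: %d unmapped gene(s) excluded", sum(!mapped)))
  pf <- profile[mapped, , drop = FALSE]
  if (!nrow(pf)) stop("no profiled genes map to any band")
  bands <- band_map[pf$gene]
  empty <- setdiff(unique(band_map), bands)
  if (length(empty))
    warning("band(s) with no profiled genes dropped: ",
            paste(empty, collapse = ", "))
  out <- data.frame(
    gene = sort(unique(bands)),
    amp_freq = tapply(pf$amp_freq, bands, mean)[sort(unique(bands))],
    del_freq = tapply(pf$del_freq, bands, mean)[sort(unique(bands))],
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_samples") <- attr(profile, "n_samples")
  class(out) <- c("CnvFrequencyProfile", "data.frame")
  out
}

#' Rank correlation of CNV frequency profiles between cohorts
#'
#' Spearman correlation (asymptotic p) of the amplification or deletion
#' frequencies over the genes/bands shared by two profiles.
#'
#' @param a,b `CnvFrequencyProfile` objects (gene- or band-level).
#' @param what `"amp"` or `"del"`.
#' @param method Correlation method (default `"spearman"`).
#' @return List with `estimate`, `p`, `n_shared`, `what`, `method`.
#' @export
correlate_profiles <- function(a, b, what = c("amp", "del"),
                               method = "spearman") {
  what <- match.arg(what)
  shared <- intersect(a$gene, b$gene)
  if (length(shared) < 3) stop("fewer than 3 shared genes/bands")
  col <- paste0(what, "_freq")
  va <- a[[col]][match(shared, a$gene)]
  vb <- b[[col]][match(shared, b$gene)]
  ct <- suppressWarnings(stats::cor.test(va, vb, method = method,
                                         exact = FALSE))
  list(estimate = unname(ct$estimate), p = ct$p.value,
       n_shared = length(shared), what = what, method = method)
}
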