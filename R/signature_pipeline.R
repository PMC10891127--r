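#' Discover a clonal prognostic gene signature
#'
#' Runs the five-step filter chain on a discovery survival cohort plus a
#' multi-region cohort:
#'
#' 1. **expression filter** — drop the `floor(G/2)` genes with lowest median
#'    expression across the discovery cohort;
#' 2. **prognostic screen** — keep genes with univariable Cox p below
#'    `p_cutoff` (default 0.01);
#' 3. **Q4 intersection** — keep genes classified Q4 (high intertumor, low
#'    intratumor heterogeneity) in the multi-region cohort;
#' 4. **concordance filter** — keep genes whose clustering concordance
#'    coefficient exceeds `concordance_cutoff` (default 0.2);
#' 5. **lasso-Cox selection** — L1-penalized Cox at `lambda` (default 0.06)
#'    on the survivors, followed by an unpenalized multivariable Cox refit
#'    on the selected genes to obtain the final coefficients.
#'
#' Any step that leaves zero genes aborts with an error naming the step.
#'
#' @param multiregion A `MultiRegionCohort` (log2 scale).
#' @param discovery A `SurvivalCohort` (log2 scale).
#' @param p_cutoff Univariable Cox p-value threshold.
#' @param concordance_cutoff Concordance coefficient threshold (strict).
#' @param lambda Lasso penalty.
#' @param B Intertumor resampling iterations.
#' @param k_range Cluster counts for the concordance score (default
#'   `2:min(26, n_patients)`).
#' @param n_restarts k-means restarts per (gene, k).
#' @param seed Integer seed for the resampling and clustering steps.
#' @return A `Signature`: list with `genes`, `coef` (unpenalized refit),
#'   `coef_penalized`, `lambda`, and `provenance` (gene counts after each
#'   step).
#' @export
run_discovery <- function(multiregion, discovery,
                          p_cutoff = 0.01, concordance_cutoff = 0.2,
                          lambda = 0.06, B = 100, k_range = NULL,
                          n_restarts = 10, seed = 1) {
  stopifnot(inherits(multiregion, "MultiRegionCohort"),
            inherits(discovery, "SurvivalCohort"))
  if (scale_tag(discovery$expr) != "log2")
    stop("discovery expression must be log2-scaled")
  expr <- unclass(discovery$expr)
  time <- discovery$clinical$time
  event <- discovery$clinical$event
  genes0 <- rownames(expr)
  prov <- c(input = length(genes0))

  # 1. median-expression filter: remove the floor(G/2) lowest-median genes
  med <- apply(expr, 1L, stats::median)
  n_drop <- floor(length(genes0) / 2)
  genes1 <- names(sort(med, decreasing = TRUE))[seq_len(length(genes0) - n_drop)]
  prov["expression_filter"] <- length(genes1)
  if (!length(genes1)) stop("no genes left after step 1 (expression filter)")

  # 2. univariable Cox screen
  pvals <- vapply(genes1, function(g) {
    fit <- tryCatch(cox_univariable(expr[g, ], time, event, name = g),
                    error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$p
  }, numeric(1))
  genes2 <- genes1[!is.na(pvals) & pvals < p_cutoff]
  prov["prognostic"] <- length(genes2)
  if (!length(genes2)) stop("no genes left after step 2 (prognostic screen)")

  # 3. Q4 intersection (heterogeneity scored over the full multi-region set)
  het <- heterogeneity_profile(multiregion, B = B, seed = seed)
  q4_genes <- het$gene[het$q4]
  genes3 <- intersect(genes2, q4_genes)
  prov["q4"] <- length(genes3)
  if (!length(genes3)) stop("no genes left after step 3 (Q4 intersection)")

  # 4. concordance filter
  conc <- concordance_coefficients(multiregion, genes = genes3,
                                   k_range = k_range,
                                   n_restarts = n_restarts, seed = seed)
  genes4 <- concordance_filter(conc, cutoff = concordance_cutoff)
  prov["concordance"] <- length(genes4)
  if (!length(genes4)) stop("no genes left after step 4 (concordance filter)")

  # 5. lasso-Cox selection + unpenalized refit
  path <- lasso_cox(t(expr[genes4, , drop = FALSE]), time, event, lambda)
  genes5 <- path$selected
  prov["lasso"] <- length(genes5)
  if (!length(genes5)) stop("no genes left after step 5 (lasso selection)")
  refit <- cox_multivariable(as.data.frame(t(expr[genes5, , drop = FALSE])),
                             time, event)
  coef_refit <- stats::setNames(refit$coef, refit$term)[genes5]

  message(sprintf("filter chain: %s",
                  paste(sprintf("%s %d", names(prov), prov), collapse = " -> ")))
  structure(list(genes = genes5, coef = coef_refit,
                 coef_penalized = path$coef[genes5],
                 lambda = lambda, provenance = prov),
            class = "Signature")
}

#' @export
print.Signature <- function(x, ...) {
  cat(sprintf("Signature: %d genes (lambda = %g)\n", length(x$genes), x$lambda))
  cat("filter chain: ",
      paste(sprintf("%s %d", names(x$provenance), x$provenance),
            collapse = " -> "), "\n")
  invisible(x)
}

#' Write / read a signature as a two-column table
#'
#' Serialized as tab-separated `gene`, `coefficient` (the unpenalized refit
#' values).
#'
#' @param sig A `Signature` (or any list with `genes` and `coef`).
#' @param path Output file.
#' @export
write_signature <- function(sig, path) {
  utils::write.table(
    data.frame(gene = sig$genes, coefficient = unname(sig$coef[sig$genes])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(list(genes = df$gene,
                 coef = stats::setNames(df$coefficient, df$gene),
                 lambda = NA_real_,
                 provenance = c(input = NA_integer_)),
            class = "Signature")
}

#' Linear per-sample risk score
#'
#' The prognostic score of a sample is the dot product of the signature
#' coefficients with the sample's log2 expression of the signature genes:
#' `S = sum_i c_i * x_i`.
#'
#' @param sig A `Signature`.
#' @param m Log2-scaled `ExpressionMatrix`.
#' @param impute_missing `"none"` (default): missing signature genes are an
#'   error; `"mean"`: a missing gene's expression is imputed with each
#'   sample's mean log2 expression over all measured genes (for
#'   cross-platform validation matrices that lack some genes).
#' @return Named numeric score vector, one per sample.
#' @export
score_samples <- function(sig, m, impute_missing = c("none", "mean")) {
  impute_missing <- match.arg(impute_missing)
  if (scale_tag(m) != "log2")
    stop("expression matrix must be log2-scaled (scale_tag 'log2')")
  missing <- setdiff(sig$genes, rownames(m))
  expr <- unclass(m)
  if (length(missing)) {
    if (impute_missing == "none")
      stop("signature gene(s) absent from matrix: ",
           paste(missing, collapse = ", "))
    warning(sprintf("mean-imputing %d missing signature gene(s)", length(missing)))
    imp <- matrix(rep(colMeans(expr), each = length(missing)),
                  length(missing), ncol(expr),
                  dimnames = list(missing, colnames(expr)))
    expr <- rbind(expr, imp)
  }
  drop(crossprod(expr[sig$genes, , drop = FALSE], unname(sig$coef[sig$genes])))
}

#' Tertile risk stratification
#'
#' Splits samples into low / intermediate / high score groups at the 1/3
#' and 2/3 rank quantiles. Ties are broken by stable sample order (first
#' occurrence ranks lower); with `n` not divisible by 3, the larger
#' remainder goes to the higher groups (e.g. 10 samples split 3/3/4). If
#' all scores are equal the split is meaningless: a warning is raised and
#' every sample is labelled `low`.
#'
#' @param scores Numeric score vector (>= 3 samples).
#' @return Ordered factor with levels `low < intermediate < high`.
#' @export
tertile_stratify <- function(scores) {
  n <- length(scores)
  if (n < 3) stop("need at least 3 samples for tertile stratification")
  lv <- c("low", "intermediate", "high")
  if (length(unique(scores)) == 1) {
    warning("all scores identical; assigning every sample to one group")
    return(factor(rep("low", n), levels = lv, ordered = TRUE))
  }
  r <- rank(scores, ties.method = "first")
  g <- lv[ceiling(3 * r / n)]
  stats::setNames(factor(g, levels = lv, ordered = TRUE), names(scores))
}

#' Evaluate a signature on a survival cohort
#'
#' Scores the cohort, stratifies it into tertiles, and runs the evaluation
#' battery: Kaplan-Meier curves with the log-rank test across tertiles, a
#' univariable Cox fit on the continuous score, and a multivariable Cox fit
#' adding the requested clinical covariates. Requested covariates that are
#' absent, constant, or all-missing are dropped with a warning.
#'
#' @param sig A `Signature`.
#' @param cohort A `SurvivalCohort`.
#' @param covariates Character vector of clinical column names to adjust
#'   for (e.g. `c("age", "sex", "stage", "histology")`).
#' @param impute_missing Passed to [score_samples()].
#' @return A `RiskStratification` list: `scores`, `groups`, `km`
#'   (`KMLogrank`), `logrank_p`, `cox_univariable`, `cox_multivariable`
#'   (`NULL` when no usable covariates were supplied).
#' @export
evaluate_signature <- function(sig, cohort, covariates = character(),
                               impute_missing = "none") {
  stopifnot(inherits(cohort, "SurvivalCohort"))
  scores <- score_samples(sig, cohort$expr, impute_missing = impute_missing)
  groups <- tertile_stratify(scores)
  time <- cohort$clinical$time
  event <- cohort$clinical$event
  km <- km_logrank(groups, time, event)
  uni <- cox_univariable(scores, time, event, name = "score")

  multi <- NULL
  use <- character()
  for (cv in covariates) {
    if (!cv %in% names(cohort$clinical)) {
      warning("covariate '", cv, "' not in clinical table; skipped")
    } else if (length(unique(stats::na.omit(cohort$clinical[[cv]]))) < 2) {
      warning("covariate '", cv, "' is constant; dropped")
    } else use <- c(use, cv)
  }
  if (length(use)) {
    X <- cbind(data.frame(score = unname(scores)),
               cohort$clinical[use])
    multi <- cox_multivariable(X, time, event)
  }
  structure(list(scores = scores, groups = groups, km = km,
                 logrank_p = km$p, cox_univariable = uni,
                 cox_multivariable = multi),
            class = "RiskStratification")
}

#' @export
print.RiskStratification <- function(x, ...) {
  cat(sprintf("RiskStratification: %d samples (%s)\n", length(x$scores),
              paste(sprintf("%s %d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  cat(sprintf("log-rank across tertiles: p = %.3g\n", x$logrank_p))
  u <- x$cox_univariable
  cat(sprintf("univariable Cox on score: HR = %.3f [%.3f, %.3f], p = %.3g\n",
              u$hr, u$lower, u$upper, u$p))
  invisible(x)
}

#' Pairwise score comparison across groups
#'
#' Two-sided pairwise t or Wilcoxon rank-sum tests of the score between all
#' group pairs, with optional Benjamini-Hochberg adjustment (off by
#' default; unadjusted pairwise reporting is the convention followed).
#'
#' @param scores Numeric vector.
#' @param labels Group label per sample; every group needs >= 2 samples.
#' @param test `"t"` or `"wilcoxon"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data.frame with `group1`, `group2`, `statistic`, `p` (and
#'   `p_adj` when adjusted).
#' @export
compare_score_by_group <- function(scores, labels, test = c("t", "wilcoxon"),
                                   adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  sizes <- table(labels)
  if (any(sizes < 2))
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", "))
  pairs <- utils::combn(levels(labels), 2)
  res <- apply(pairs, 2, function(pr) {
    a <- scores[labels == pr[1]]
    b <- scores[labels == pr[2]]
    ht <- if (test == "t") stats::t.test(a, b)
          else suppressWarnings(stats::wilcox.test(a, b))
    c(statistic = unname(ht$statistic), p = ht$p.value)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = res["statistic", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}
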