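# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and, where the package delegates to survival /
# glmnet, those packages too).

# Exact intertumor score: mean over ALL region combinations (one region per
# patient) of the cross-patient sample SD. Returns per-gene mean and the SD
# over combinations (for Monte-Carlo error bars). Feasible for R^P small.
enum_intertumor <- function(expr, map) {
  cols <- split(seq_len(nrow(map)), map$patient_id)
  combos <- expand.grid(lapply(cols, function(idx) idx), KEEP.OUT.ATTRS = FALSE)
  per_combo <- apply(as.matrix(combos), 1L, function(pick) {
    sub <- expr[, pick, drop = FALSE]
    apply(sub, 1L, stats::sd)
  })
  if (is.null(dim(per_combo))) per_combo <- matrix(per_combo, nrow = 1)
  list(mean = rowMeans(per_combo),
       sd = apply(per_combo, 1L, stats::sd))
}

# Exact 1-D k-means by dynamic programming over the sorted values
# (optimal clusters are contiguous in sorted order). Returns cluster labels
# in the original order.
dp_kmeans_1d <- function(x, k) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  # cost of putting xs[i..j] in one cluster
  seg_cost <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  cut <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- seg_cost(1, j)
  if (k > 1) {
    for (kk in 2:k) {
      for (j in kk:n) {
        for (i in kk:j) {
          c_ <- cost[kk - 1, i - 1] + seg_cost(i, j)
          if (c_ < cost[kk, j]) { cost[kk, j] <- c_; cut[kk, j] <- i }
        }
      }
    }
  }
  labels_sorted <- integer(n)
  j <- n
  for (kk in k:1) {
    i <- if (kk == 1) 1L else cut[kk, j]
    labels_sorted[i:j] <- kk
    j <- i - 1L
    if (j < 1) break
  }
  labels <- integer(n)
  labels[ord] <- labels_sorted
  labels
}

# Concordance of a labelling: fraction of patients whose regions share one label
concordance_of_labels <- function(labels, map) {
  idx <- split(seq_len(nrow(map)), map$patient_id)
  mean(vapply(idx, function(i) length(unique(labels[i])) == 1L, logical(1)))
}

# Hypergeometric upper tail P(X >= k) by direct enumeration with choose()
hyper_enum_geq <- function(N, K, n, k) {
  lo <- max(0, K + n - N)
  hi <- min(K, n)
  if (k > hi) stop("k out of range")
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# Hand-coded two-group log-rank chi-square (hypergeometric variance)
logrank_2group <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(all(group %in% 1:2))
  ts <- sort(unique(time[event == 1]))
  OE <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    OE <- OE + d1 - d * n1 / n_t
    if (n_t > 1)
      V <- V + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
  }
  (OE)^2 / V
}

# Breslow partial-likelihood score vector at beta (no ties assumed)
cox_score_breslow <- function(X, time, event, beta) {
  lp <- drop(X %*% beta)
  w <- exp(lp)
  U <- numeric(ncol(X))
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    U <- U + X[i, ] - colSums(X[risk, , drop = FALSE] * w[risk]) / sum(w[risk])
  }
  U
}
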