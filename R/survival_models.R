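#' Univariable Cox proportional hazards fit
#'
#' Maximum partial-likelihood fit (Efron tie handling) of survival on a
#' single covariate, with Wald confidence interval and p-value.
#'
#' @param x Numeric covariate vector (e.g. one gene's log2 expression).
#' @param time,event Follow-up time (> 0) and 0/1 event indicator.
#' @param name Covariate name used in the output.
#' @return A `CoxFit` data.frame with one row: `term`, `coef`, `hr`,
#'   `lower`, `upper`, `p`, `n`, `n_events`; the model log partial
#'   likelihood is attached as attribute `loglik`.
#' @export
cox_univariable <- function(x, time, event, name = "x") {
  if (sum(event) < 2) stop("need at least 2 events")
  if (length(unique(x)) < 2) stop("degenerate covariate: '", name, "' is constant")
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  cox_fit_table(fit, terms = name)
}

cox_fit_table <- function(fit, terms = NULL) {
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  out <- data.frame(
    term = if (is.null(terms)) rownames(co) else terms,
    coef = co[, "coef"],
    hr = co[, "exp(coef)"],
    lower = ci[, "lower .95"],
    upper = ci[, "upper .95"],
    p = co[, "Pr(>|z|)"],
    n = s$n, n_events = s$nevent,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "loglik") <- fit$loglik[length(fit$loglik)]
  attr(out, "fit") <- fit
  class(out) <- c("CoxFit", "data.frame")
  out
}

#' Multivariable Cox proportional hazards fit
#'
#' Joint fit of survival on several covariates (numeric or categorical;
#' factors are expanded against their first level). Exactly collinear
#' columns are an error naming the offending terms.
#'
#' @param X Data.frame of covariates (rows = samples).
#' @param time,event Follow-up time and 0/1 event indicator.
#' @return A `CoxFit` data.frame, one row per model term.
#' @export
cox_multivariable <- function(X, time, event) {
  X <- as.data.frame(X)
  if (ncol(X) == 0) stop("empty covariate set: no model to fit")
  if (nrow(X) <= ncol(X)) stop("need more samples than covariates")
  if (sum(event) < 2) stop("need at least 2 events")
  X[] <- lapply(X, function(col) if (is.character(col)) factor(col) else col)
  mm <- stats::model.matrix(~ ., data = X)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("collinear covariate column(s): ", paste(dropped, collapse = ", "))
  }
  df <- cbind(X, .time = time, .event = event)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(X)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  cox_fit_table(fit)
}

#' Lasso-penalized Cox regression at a fixed penalty
#'
#' L1-penalized Cox partial-likelihood fit (coordinate descent via
#' \pkg{glmnet}) at penalty `lambda`. Predictors are standardized to unit
#' variance internally; coefficients are returned on the original (log2
#' expression) scale. The selected set is the genes with nonzero
#' coefficients.
#'
#' @param X Numeric matrix, samples in rows, genes in columns.
#' @param time,event Follow-up time and 0/1 event indicator.
#' @param lambda Penalty (>= 0); the paper-scale tuning parameter of
#'   \pkg{glmnet}.
#' @param standardize Standardize columns before penalization (default TRUE).
#' @return A `LassoPath` list: `lambda`, `coef` (named, all genes),
#'   `selected` (nonzero genes), `standardize`.
#' @export
lasso_cox <- function(X, time, event, lambda, standardize = TRUE) {
  if (lambda < 0) stop("lambda must be >= 0")
  y <- survival::Surv(time, event)
  fit <- glmnet::glmnet(X, y, family = "cox", standardize = standardize,
                        thresh = 1e-12, nlambda = 100)
  beta <- drop(as.matrix(stats::coef(fit, s = lambda, exact = TRUE,
                                     x = X, y = y,
                                     standardize = standardize,
                                     thresh = 1e-12)))
  names(beta) <- colnames(X)
  structure(list(lambda = lambda, coef = beta,
                 selected = names(beta)[beta != 0],
                 standardize = standardize),
            class = "LassoPath")
}

#' @export
print.LassoPath <- function(x, ...) {
  cat(sprintf("LassoPath: lambda = %g, %d of %d genes selected\n",
              x$lambda, length(x$selected), length(x$coef)))
  invisible(x)
}

#' Kaplan-Meier curves and the k-group log-rank test
#'
#' @param groups Group label per sample (>= 2 non-empty groups).
#' @param time,event Follow-up time and 0/1 event indicator.
#' @return A `KMLogrank` list: `curves` (data.frame of per-group step
#'   functions: `group`, `time`, `n_risk`, `n_event`, `surv`), `chisq`,
#'   `df`, `p`.
#' @export
km_logrank <- function(groups, time, event) {
  if (!is.factor(groups)) groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  empty <- levels(groups)[tabulate(groups, nlevels(groups)) == 0]
  if (length(empty)) stop("group(s) with zero samples: ", paste(empty, collapse = ", "))
  sf <- survival::survfit(survival::Surv(time, event) ~ groups)
  strata_names <- sub("^groups=", "", names(sf$strata))
  curves <- data.frame(
    group = rep(strata_names, sf$strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    surv = sf$surv, stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- length(sd_$n) - 1
  structure(list(curves = curves, chisq = unname(sd_$chisq), df = df,
                 p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE)),
            class = "KMLogrank")
}

#' @export
print.KMLogrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.3f on %d df, p = %.3g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}
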