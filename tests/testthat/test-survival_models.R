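# shared small survival fixture without ties
make_surv <- function(n, beta = 0, seed = 1, censor = 0.25) {
  set.seed(seed)
  x <- rnorm(n)
  tm <- rexp(n, 0.05 * exp(beta * x))
  cn <- if (censor > 0) rexp(n, 0.05 * censor / (1 - censor)) else rep(Inf, n)
  list(x = x, time = pmin(tm, cn), event = as.integer(tm <= cn))
}

test_that("univariable Cox rejects degenerate inputs", {
  d <- make_surv(50)
  expect_error(cox_univariable(rep(1, 50), d$time, d$event), "degenerate")
  expect_error(cox_univariable(d$x, d$time, rep(0, 50)), "2 events")
})

test_that("univariable Cox fit structure satisfies its invariants", {
  d <- make_surv(120, beta = 0.5, seed = 3)
  fit <- cox_univariable(d$x, d$time, d$event, name = "geneX")
  expect_s3_class(fit, "CoxFit")
  expect_equal(fit$term, "geneX")
  expect_equal(fit$hr, exp(fit$coef))
  expect_lt(fit$lower, fit$upper)
  expect_gt(fit$p, 0); expect_lte(fit$p, 1)
  expect_equal(fit$n_events, sum(d$event))
})

test_that("two-group data with true HR = 2 is recovered on average", {
  hrs <- vapply(1:50, function(r) {
    set.seed(400 + r)
    x <- rep(0:1, each = 200)
    tm <- rexp(400, 0.05 * 2^x)
    fit <- cox_univariable(x, tm, rep(1L, 400))
    fit$hr
  }, numeric(1))
  expect_lt(abs(mean(hrs) - 2) / 2, 0.2)
})

test_that("null covariate p-values are uniform", {
  pvals <- vapply(1:200, function(r) {
    d <- make_surv(500, beta = 0, seed = 7000 + r)
    cox_univariable(d$x, d$time, d$event)$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Cox score test on a binary split equals the log-rank statistic", {
  for (s in 1:5) {
    set.seed(90 + s)
    x <- rbinom(60, 1, 0.5)
    tm <- rexp(60, 0.05 * exp(0.4 * x)) * runif(60, 0.99, 1.01)
    ev <- rbinom(60, 1, 0.8)
    fit <- survival::coxph(survival::Surv(tm, ev) ~ x)
    oracle <- logrank_2group(tm, ev, x)
    expect_equal(unname(fit$score), oracle, tolerance = 1e-10)
    expect_equal(km_logrank(x, tm, ev)$chisq, oracle, tolerance = 1e-10)
  }
})

test_that("multivariable Cox flags collinearity and recovers planted effects", {
  cfg <- sim_config(n_genes = 20, n_prognostic = 3, beta = 0.4)
  sv <- simulate_survival_cohort(cfg, n = 500, seed = 55)
  score <- drop(crossprod(unclass(sv$cohort$expr), sv$truth$beta))
  noise <- matrix(rnorm(1000), 500, 2,
                  dimnames = list(NULL, c("noise1", "noise2")))
  X <- data.frame(score = score, noise)
  fit <- cox_multivariable(X, sv$cohort$clinical$time, sv$cohort$clinical$event)
  expect_gt(fit$hr[fit$term == "score"], 1)
  expect_lt(fit$p[fit$term == "score"], 1e-6)
  expect_true(all(abs(log(fit$hr[fit$term != "score"])) < 0.2))

  X2 <- cbind(X, score_copy = X$score)
  expect_error(cox_multivariable(X2, sv$cohort$clinical$time,
                                 sv$cohort$clinical$event), "collinear")
  expect_error(cox_multivariable(X[, integer(0)], sv$cohort$clinical$time,
                                 sv$cohort$clinical$event), "empty covariate")
})

test_that("lasso-Cox at lambda = 0 matches the unpenalized fit", {
  set.seed(12)
  n <- 150
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
  tm <- rexp(n, 0.05 * exp(X %*% c(0.5, -0.4, 0.3, 0, 0)))
  ev <- rbinom(n, 1, 0.85)
  path <- lasso_cox(X, tm, ev, lambda = 0)
  ref <- cox_multivariable(as.data.frame(X), tm, ev)
  expect_lt(max(abs(path$coef - setNames(ref$coef, ref$term))), 1e-4)
})

test_that("lasso-Cox shrinkage limits and input checks", {
  set.seed(13)
  n <- 100
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("g", 1:10)))
  tm <- rexp(n, 0.05)
  ev <- rep(1L, n)
  expect_error(lasso_cox(X, tm, ev, lambda = -1), ">= 0")
  path <- lasso_cox(X, tm, ev, lambda = 50)
  expect_equal(length(path$selected), 0L)
})

test_that("lasso solution satisfies the KKT conditions at lambda", {
  set.seed(14)
  n <- 200; p <- 12
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  tm <- rexp(n, 0.05 * exp(X %*% c(0.7, -0.6, 0.5, rep(0, p - 3)))) *
    runif(n, 0.99, 1.01)
  ev <- rbinom(n, 1, 0.85)
  lam <- 0.06
  path <- lasso_cox(X, tm, ev, lam, standardize = FALSE)
  g <- cox_score_breslow(X, tm, ev, path$coef) / n
  active <- path$coef != 0
  expect_true(all(abs(g[active] - lam * sign(path$coef[active])) < 1e-6))
  expect_true(all(abs(g[!active]) <= lam + 1e-6))
})

test_that("lasso path recovers planted genes among noise at some lambda", {
  hits <- logical(10)
  fps <- integer(10)
  for (s in 1:10) {
    set.seed(600 + s)
    n <- 300; p <- 100
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
    beta <- c(rep(0.6, 3), rep(0, p - 3))
    tm <- rexp(n, 0.05 * exp(X %*% beta))
    ev <- rbinom(n, 1, 0.8)
    for (lam in c(0.20, 0.15, 0.10, 0.07, 0.05)) {
      sel <- lasso_cox(X, tm, ev, lam)$selected
      if (all(paste0("g", 1:3) %in% sel) && length(sel) - 3 <= 5) {
        hits[s] <- TRUE
        fps[s] <- length(sel) - 3
        break
      }
    }
  }
  expect_true(all(hits))
  expect_true(all(fps <= 5))
})

test_that("Kaplan-Meier / log-rank behave on degenerate and k-group input", {
  tm <- c(5, 8, 12, 20, 33, 40)
  ev <- c(1, 0, 1, 1, 0, 1)
  # two identical groups: statistic 0, p 1
  res <- km_logrank(rep(c("a", "b"), each = 6), rep(tm, 2), rep(ev, 2))
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)

  # three groups: chi-square on 2 degrees of freedom
  set.seed(3)
  g3 <- rep(c("a", "b", "c"), each = 20)
  t3 <- rexp(60, 0.05); e3 <- rbinom(60, 1, 0.8)
  expect_equal(km_logrank(g3, t3, e3)$df, 2)

  expect_error(km_logrank(factor(rep("a", 6), levels = c("a", "b")), tm, ev),
               "zero samples")
  expect_error(km_logrank(rep("a", 6), tm, ev), "at least 2 groups")
})

test_that("log-rank p is consistent with an exhaustive permutation reference", {
  tm <- c(3, 6, 9, 14, 25, 31)
  ev <- c(1, 1, 0, 1, 1, 1)
  grp <- c(1, 1, 1, 2, 2, 2)
  obs <- km_logrank(grp, tm, ev)$chisq
  expect_equal(obs, logrank_2group(tm, ev, grp), tolerance = 1e-10)
  splits <- utils::combn(6, 3)
  perm_stats <- apply(splits, 2, function(idx) {
    g <- rep(2, 6); g[idx] <- 1
    logrank_2group(tm, ev, g)
  })
  perm_p <- mean(perm_stats >= obs - 1e-12)
  asym_p <- km_logrank(grp, tm, ev)$p
  expect_lt(abs(perm_p - asym_p), 0.2)
})

test_that("KM estimate equals the empirical survival function without censoring", {
  set.seed(6)
  tm <- sort(rexp(40, 0.1))
  res <- km_logrank(rep(c("a", "b"), 20), tm, rep(1L, 40))
  a <- res$curves[res$curves$group == "a", ]
  emp <- vapply(a$time, function(t) mean(tm[rep(c(TRUE, FALSE), 20)] > t),
                numeric(1))
  expect_equal(a$surv, emp)
})
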