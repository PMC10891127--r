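toy_signature <- function(genes, coefs) {
  structure(list(genes = genes, coef = setNames(coefs, genes),
                 lambda = 0.06,
                 provenance = c(input = length(genes))),
            class = "Signature")
}

test_that("risk scores are the stated dot product and are linear", {
  m <- expression_matrix(matrix(c(4, 10, 2, 6), 2, 2,
                                dimnames = list(c("g1", "g2"), c("s1", "s2"))),
                         "log2")
  sig <- toy_signature(c("g1", "g2"), c(0.5, -0.2))
  sc <- score_samples(sig, m)
  expect_equal(unname(sc["s1"]), 0.5 * 4 - 0.2 * 10)  # = 0
  expect_equal(unname(sc["s2"]), 0.5 * 2 - 0.2 * 6)

  # linearity in the expression profile
  m_sum <- expression_matrix(
    matrix(unclass(m)[, 1] + unclass(m)[, 2],
           dimnames = list(c("g1", "g2"), "sum")), "log2")
  expect_equal(unname(score_samples(sig, m_sum)), unname(sc["s1"] + sc["s2"]))

  # doubling one coefficient doubles that gene's contribution
  sig2 <- toy_signature(c("g1", "g2"), c(1.0, -0.2))
  expect_equal(score_samples(sig2, m) - sc,
               setNames(0.5 * unclass(m)["g1", ], c("s1", "s2")))

  # gene order within the signature does not matter
  sig_r <- toy_signature(c("g2", "g1"), c(-0.2, 0.5))
  expect_equal(score_samples(sig_r, m), sc)

  sig0 <- toy_signature(c("g1", "g2"), c(0, 0))
  expect_equal(unname(score_samples(sig0, m)), c(0, 0))
})

test_that("scoring validates the scale and the gene universe", {
  m_counts <- expression_matrix(matrix(1:4, 2, 2,
    dimnames = list(c("g1", "g2"), c("s1", "s2"))), "counts")
  sig <- toy_signature(c("g1", "g2"), c(1, 1))
  expect_error(score_samples(sig, m_counts), "log2")

  m <- expression_matrix(matrix(c(1, 2, 3, 4), 2, 2,
    dimnames = list(c("g1", "g3"), c("s1", "s2"))), "log2")
  expect_error(score_samples(sig, m), "g2")
  expect_warning(sc <- score_samples(sig, m, impute_missing = "mean"),
                 "mean-imputing")
  expect_equal(unname(sc),
               unname(unclass(m)["g1", ] + colMeans(unclass(m))))
})

test_that("tertile stratification splits ranks as documented", {
  s9 <- setNames(sample(9), paste0("s", 1:9))
  g9 <- tertile_stratify(s9)
  expect_equal(as.integer(table(g9)), rep(3L, 3))
  expect_true(all(s9[g9 == "high"] > max(s9[g9 == "low"])))

  g10 <- tertile_stratify(rnorm(10))
  expect_equal(sort(as.integer(table(g10))), c(3L, 3L, 4L))

  expect_error(tertile_stratify(c(1, 2)), "at least 3")
  expect_warning(g_eq <- tertile_stratify(rep(5, 6)), "identical")
  expect_equal(length(unique(g_eq)), 1L)

  # ties broken by stable sample order
  g_t <- tertile_stratify(c(1, 1, 1, 1, 1, 2))
  expect_equal(as.character(g_t),
               c("low", "low", "intermediate", "intermediate", "high", "high"))
})

test_that("pairwise group comparisons cover all pairs with both tests", {
  set.seed(15)
  sc <- c(rnorm(50), rnorm(50, 3), rnorm(50, 6))
  lab <- rep(c("lo", "mid", "hi"), each = 50)
  res_t <- compare_score_by_group(sc, lab, test = "t")
  expect_equal(nrow(res_t), 3L)
  expect_true(all(res_t$p < 1e-6))
  res_w <- compare_score_by_group(sc, lab, test = "wilcoxon")
  expect_true(all(res_w$p < 1e-6))

  # identical groups: t statistic 0, p = 1
  a <- rnorm(20)
  res_id <- compare_score_by_group(c(a, a), rep(c("x", "y"), each = 20))
  expect_equal(res_id$statistic, 0)
  expect_equal(res_id$p, 1)

  res_bh <- compare_score_by_group(sc, lab, adjust = "BH")
  expect_true("p_adj" %in% names(res_bh))
  expect_error(compare_score_by_group(c(1, 2, 3), c("a", "a", "b")),
               "singleton")
})

test_that("discovery filter chain keeps monotone provenance and finds planted genes", {
  cfg <- sim_config(n_genes = 500, n_prognostic = 15, beta = 0.15)
  sim <- simulate_multiregion(cfg, seed = 41)
  sv <- simulate_survival_cohort(cfg, sim$truth, n = 250, seed = 42)
  sig <- suppressMessages(
    run_discovery(sim$cohort, sv$cohort, B = 50, seed = 43))
  expect_s3_class(sig, "Signature")
  expect_true(all(diff(sig$provenance) <= 0))
  expect_equal(unname(sig$provenance["input"]), 500)
  expect_equal(unname(sig$provenance["expression_filter"]), 250)
  expect_equal(unname(sig$provenance["lasso"]), length(sig$genes))
  expect_true(all(is.finite(sig$coef)) && all(sig$coef != 0))
  planted <- names(sv$truth$beta)[sv$truth$beta != 0]
  expect_gt(mean(sig$genes %in% planted), 0.5)
})

test_that("degenerate parameters fail at the lasso step by name", {
  cfg <- sim_config(n_genes = 200, n_prognostic = 10)
  sim <- simulate_multiregion(cfg, seed = 51)
  sv <- simulate_survival_cohort(cfg, sim$truth, n = 150, seed = 52)
  expect_error(
    suppressMessages(run_discovery(sim$cohort, sv$cohort, p_cutoff = 1,
                                   concordance_cutoff = 0, lambda = 1e4,
                                   B = 20, seed = 53)),
    "step 5")
})

test_that("signature evaluation assembles the full battery", {
  cfg <- sim_config(n_genes = 100, n_prognostic = 10, beta = 0.3)
  sv <- simulate_survival_cohort(cfg, n = 200, seed = 61)
  planted <- names(sv$truth$beta)[sv$truth$beta != 0]
  sig <- toy_signature(planted, sv$truth$beta[planted])
  ev <- evaluate_signature(sig, sv$cohort,
                           covariates = c("age", "sex", "stage", "histology"))
  expect_s3_class(ev, "RiskStratification")
  expect_equal(length(ev$scores), 200L)
  expect_true(all(abs(diff(as.integer(table(ev$groups)))) <= 1))
  expect_gt(ev$cox_univariable$hr, 1)
  expect_lt(ev$cox_univariable$p, 0.01)
  expect_true("score" %in% ev$cox_multivariable$term)

  # constant covariate is dropped with a warning, absent one skipped
  sv$cohort$clinical$flat <- 1
  expect_warning(
    ev2 <- evaluate_signature(sig, sv$cohort, covariates = c("age", "flat")),
    "constant")
  expect_false("flat" %in% ev2$cox_multivariable$term)
  expect_warning(
    evaluate_signature(sig, sv$cohort, covariates = "nope"),
    "not in clinical")
})

test_that("signatures round-trip through the two-column serialization", {
  sig <- toy_signature(c("gB", "gA"), c(0.25, -0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$genes, sig$genes)
  expect_equal(back$coef, sig$coef)
})
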