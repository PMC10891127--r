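#' Simulation configuration for synthetic cohorts
#'
#' Defines the generative model used throughout the test bench: a
#' multi-region cohort of `n_patients` tumors with `regions_per_patient`
#' samples each, genes partitioned into three classes, and survival driven
#' by a Cox model on a subset of the clonal genes plus clinical covariates.
#'
#' Gene classes, on the log2 expression scale:
#' * **clonal** — patient effect `N(mu_g, sd_between^2)` with small region
#'   noise `N(0, sd_within^2)`: consistent within a tumor, variable between
#'   tumors (what the Q4 quadrant should capture);
#' * **subclonal** — the reverse (small between-patient, large
#'   within-patient variation);
#' * **null** — small on both axes.
#'
#' Gene means `mu_g` are drawn once per gene from `N(mean_log2, sd_log2^2)`
#' so a median-expression filter has signal to act on.
#'
#' @param n_patients Number of patients in the multi-region cohort.
#' @param regions_per_patient Regions sampled per tumor (>= 2).
#' @param n_genes Total genes simulated.
#' @param frac_clonal,frac_subclonal,frac_null Gene-class fractions (sum 1).
#' @param mean_log2,sd_log2 Mean and SD of the per-gene baseline `mu_g`.
#' @param sd_between Named vector: between-patient SD per class.
#' @param sd_within Named vector: within-patient (region) SD per class.
#' @param n_prognostic Number of clonal genes given a nonzero log-hazard
#'   effect; default `min(40, number of clonal genes)`.
#' @param beta Log hazard ratio per unit log2 expression for each prognostic
#'   gene (recycled to length `n_prognostic`).
#' @param baseline_hazard Exponential baseline hazard, per day.
#' @param censoring_rate Target fraction censored, in \[0, 1).
#' @param age_effect,sex_effect,stage_effect,histology_effect Log-hazard
#'   contributions of the simulated clinical covariates (per year over 65;
#'   male vs female; stage II/III vs I; biphasic vs epithelioid).
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(n_patients = 26,
                       regions_per_patient = 3,
                       n_genes = 2000,
                       frac_clonal = 0.15,
                       frac_subclonal = 0.15,
                       frac_null = 0.70,
                       mean_log2 = 6,
                       sd_log2 = 2,
                       sd_between = c(clonal = 2, subclonal = 0.2, null = 0.6),
                       sd_within = c(clonal = 0.2, subclonal = 2, null = 0.6),
                       n_prognostic = NULL,
                       beta = 0.2,
                       baseline_hazard = 5e-4,
                       censoring_rate = 0.3,
                       age_effect = 0.02,
                       sex_effect = 0.1,
                       stage_effect = c(II = 0.3, III = 0.6),
                       histology_effect = 0.4) {
  fr <- c(frac_clonal, frac_subclonal, frac_null)
  if (abs(sum(fr) - 1) > 1e-8) stop("gene-class fractions must sum to 1")
  if (any(fr < 0)) stop("gene-class fractions must be non-negative")
  cls <- c("clonal", "subclonal", "null")
  if (!all(cls %in% names(sd_between)) || !all(cls %in% names(sd_within)))
    stop("sd_between and sd_within need entries for clonal, subclonal, null")
  if (any(sd_between < 0) || any(sd_within < 0)) stop("SDs must be >= 0")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must lie in [0, 1)")
  if (regions_per_patient < 2) stop("regions_per_patient must be >= 2")
  if (is.null(n_prognostic))
    n_prognostic <- min(40, round(frac_clonal * n_genes))
  if (n_prognostic > ceiling(frac_clonal * n_genes))
    stop("n_prognostic exceeds the number of clonal genes")
  structure(list(
    n_patients = n_patients, regions_per_patient = regions_per_patient,
    n_genes = n_genes,
    fractions = c(clonal = frac_clonal, subclonal = frac_subclonal, null = frac_null),
    mean_log2 = mean_log2, sd_log2 = sd_log2,
    sd_between = sd_between[cls], sd_within = sd_within[cls],
    n_prognostic = n_prognostic, beta = rep_len(beta, n_prognostic),
    baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
    age_effect = age_effect, sex_effect = sex_effect,
    stage_effect = stage_effect, histology_effect = histology_effect),
    class = "SimulationConfig")
}

region_labels <- function(r) {
  if (r == 3) c("superior", "lateral", "inferior") else paste0("region", seq_len(r))
}

# gene class labels and per-gene baselines shared by both generators
gene_truth <- function(cfg) {
  g <- cfg$n_genes
  n_cl <- round(cfg$fractions["clonal"] * g)
  n_sub <- round(cfg$fractions["subclonal"] * g)
  classes <- rep("null", g)
  classes[seq_len(n_cl)] <- "clonal"
  if (n_sub > 0) classes[n_cl + seq_len(n_sub)] <- "subclonal"
  genes <- sprintf("gene%04d", seq_len(g))
  mu <- stats::rnorm(g, cfg$mean_log2, cfg$sd_log2)
  beta <- stats::setNames(numeric(g), genes)
  beta[seq_len(cfg$n_prognostic)] <- cfg$beta  # prognostic genes are clonal
  list(genes = genes, classes = stats::setNames(classes, genes),
       mu = stats::setNames(mu, genes), beta = beta)
}

#' Simulate a multi-region cohort with known gene classes
#'
#' @param cfg A [sim_config()] object.
#' @param seed Integer seed; the matrix is bit-reproducible given the seed.
#' @return A list with `cohort` (a `MultiRegionCohort`, log2 scale) and
#'   `truth` (a `GroundTruth`: per-gene class, baseline mean `mu`, true
#'   log-hazard `beta`, and the per-patient clonal effects).
#' @export
simulate_multiregion <- function(cfg = sim_config(), seed = 1) {
  if (cfg$regions_per_patient < 2) stop("regions_per_patient must be >= 2")
  set.seed(seed)
  tr <- gene_truth(cfg)
  p <- cfg$n_patients; r <- cfg$regions_per_patient; g <- cfg$n_genes
  sd_b <- cfg$sd_between[tr$classes]
  sd_w <- cfg$sd_within[tr$classes]
  # patient effects: g x p
  pat_eff <- tr$mu + matrix(stats::rnorm(g * p, 0, sd_b), g, p)
  vals <- pat_eff[, rep(seq_len(p), each = r)] +
    matrix(stats::rnorm(g * p * r, 0, sd_w), g, p * r)
  patients <- sprintf("P%02d", seq_len(p))
  regs <- region_labels(r)
  map <- data.frame(
    sample_id = paste(rep(patients, each = r), rep(regs, p), sep = "_"),
    patient_id = rep(patients, each = r),
    region = rep(regs, p), stringsAsFactors = FALSE)
  dimnames(vals) <- list(tr$genes, map$sample_id)
  colnames(pat_eff) <- patients
  cohort <- multiregion_cohort(expression_matrix(vals, "log2"), map)
  truth <- structure(list(classes = tr$classes, mu = tr$mu, beta = tr$beta,
                          patient_effects = pat_eff, config = cfg),
                     class = "GroundTruth")
  list(cohort = cohort, truth = truth)
}

#' Simulate a single-region survival cohort from the same gene model
#'
#' Draws one sample per patient from the gene model in `truth` (or a fresh
#' [gene model] when `truth` is `NULL`), then survival times from an
#' exponential-baseline Cox model: hazard
#' `baseline_hazard * exp(sum(beta_g * (x_g - mu_g)) + clinical effects)`,
#' with independent exponential censoring calibrated to the target censoring
#' rate.
#'
#' @param cfg A [sim_config()].
#' @param truth Optional `GroundTruth` from [simulate_multiregion()]; reused
#'   so the survival cohort shares gene identities, classes and effects.
#' @param n Number of patients (samples) in the cohort.
#' @param seed Integer seed.
#' @return A list with `cohort` (a `SurvivalCohort`) and `truth` (with the
#'   per-sample true linear predictor attached as `lp`).
#' @export
simulate_survival_cohort <- function(cfg = sim_config(), truth = NULL,
                                     n = 300, seed = 1) {
  set.seed(seed)
  if (is.null(truth)) {
    tr <- gene_truth(cfg)
    truth <- structure(list(classes = tr$classes, mu = tr$mu, beta = tr$beta,
                            config = cfg), class = "GroundTruth")
  }
  g <- length(truth$classes)
  sd_b <- cfg$sd_between[truth$classes]
  sd_w <- cfg$sd_within[truth$classes]
  # one region per patient: patient effect + one region draw
  vals <- truth$mu +
    matrix(stats::rnorm(g * n, 0, sd_b), g, n) +
    matrix(stats::rnorm(g * n, 0, sd_w), g, n)
  samples <- sprintf("S%04d", seq_len(n))
  dimnames(vals) <- list(names(truth$classes), samples)

  age <- pmin(pmax(round(stats::rnorm(n, 68, 8)), 35), 85)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.69, 0.31))
  stage <- sample(c("I", "II", "III"), n, replace = TRUE,
                  prob = c(0.46, 0.35, 0.19))
  histology <- sample(c("epithelioid", "biphasic"), n, replace = TRUE,
                      prob = c(0.65, 0.35))
  clin_lp <- cfg$age_effect * (age - 68) +
    cfg$sex_effect * (sex == "male") +
    ifelse(stage == "II", cfg$stage_effect["II"],
           ifelse(stage == "III", cfg$stage_effect["III"], 0)) +
    cfg$histology_effect * (histology == "biphasic")
  clin_lp <- clin_lp - mean(clin_lp)
  lp <- drop(crossprod(vals - truth$mu, truth$beta)) + clin_lp

  t_event <- stats::rexp(n, rate = cfg$baseline_hazard * exp(lp))
  if (cfg$censoring_rate > 0) {
    cens_rate <- cfg$baseline_hazard *
      cfg$censoring_rate / (1 - cfg$censoring_rate)
    t_cens <- stats::rexp(n, rate = cens_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  event <- as.integer(t_event <= t_cens)
  if (all(event == 0)) warning("all observations censored under this configuration")
  clinical <- data.frame(
    sample_id = samples,
    time = pmax(pmin(t_event, t_cens), .Machine$double.eps),
    event = event, age = age, sex = sex, stage = stage,
    histology = histology, stringsAsFactors = FALSE)
  cohort <- structure(list(expr = expression_matrix(vals, "log2"),
                           clinical = clinical), class = "SurvivalCohort")
  truth$lp <- stats::setNames(lp, samples)
  list(cohort = cohort, truth = truth)
}

#' Simulate a copy-number call matrix with band-level events
#'
#' Each chromosome band carries per-sample Bernoulli amplification and
#' deletion events at the given rates; all genes on a band share its call.
#' When both an amplification and a deletion are drawn for the same band and
#' sample, the amplification wins (logged via message).
#'
#' @param band_map Named character vector mapping gene id to band; genes
#'   absent from the map get all-zero calls.
#' @param amp_rates,del_rates Named numeric vectors (per band), rates in
#'   \[0, 1\].
#' @param n_samples Number of samples (columns).
#' @param seed Integer seed.
#' @return Integer matrix (genes x samples) with values in \{-1, 0, +1\}.
#' @export
simulate_cnv <- function(band_map, amp_rates, del_rates, n_samples, seed = 1) {
  if (any(amp_rates < 0 | amp_rates > 1) || any(del_rates < 0 | del_rates > 1))
    stop("amplification/deletion rates must lie in [0, 1]")
  set.seed(seed)
  bands <- sort(unique(band_map))
  miss <- setdiff(bands, names(amp_rates))
  if (length(miss)) stop("missing amp rate for band(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(bands, names(del_rates))
  if (length(miss)) stop("missing del rate for band(s): ", paste(miss, collapse = ", "))
  amp <- matrix(stats::rbinom(length(bands) * n_samples, 1, amp_rates[bands]),
                length(bands), n_samples)
  del <- matrix(stats::rbinom(length(bands) * n_samples, 1, del_rates[bands]),
                length(bands), n_samples)
  clash <- sum(amp == 1 & del == 1)
  if (clash > 0)
    message(sprintf("%d overlapping amp/del draws resolved amplification-first", clash))
  band_calls <- amp - (del == 1 & amp == 0)
  rownames(band_calls) <- bands
  genes <- names(band_map)
  out <- matrix(0L, length(genes), n_samples,
                dimnames = list(genes, sprintf("S%04d", seq_len(n_samples))))
  mapped <- genes[band_map %in% bands]
  out[mapped, ] <- band_calls[band_map[mapped], ]
  storage.mode(out) <- "integer"
  out
}
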