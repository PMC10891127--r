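# Small fixture builders shared across test files.

# Multi-region cohort from a genes x (patients*regions) value matrix.
# `region_values` is a list: one genes x regions matrix per patient, or a
# single-gene numeric vector per patient.
toy_multiregion <- function(region_values, gene_ids = NULL) {
  mats <- lapply(region_values, function(v) {
    if (is.null(dim(v))) matrix(v, nrow = 1) else v
  })
  n_genes <- nrow(mats[[1]])
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n_genes))
  patients <- sprintf("P%02d", seq_along(mats))
  vals <- do.call(cbind, mats)
  map <- data.frame(
    sample_id = unlist(Map(function(p, m) paste0(p, "_r", seq_len(ncol(m))),
                           patients, mats), use.names = FALSE),
    patient_id = rep(patients, vapply(mats, ncol, 1L)),
    region = unlist(lapply(mats, function(m) paste0("r", seq_len(ncol(m)))),
                    use.names = FALSE),
    stringsAsFactors = FALSE)
  dimnames(vals) <- list(gene_ids, map$sample_id)
  multiregion_cohort(expression_matrix(vals, "log2"), map)
}

# Write a small expression TSV and return its path
write_expr_tsv <- function(lines, path = withr::local_tempfile(fileext = ".tsv",
                                                               .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# Survival cohort straight from components
toy_survival_cohort <- function(expr, time, event, ...) {
  clin <- data.frame(sample_id = colnames(expr), time = time, event = event,
                     ..., stringsAsFactors = FALSE)
  align_cohort(expr, clin)
}
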