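#' Construct a validated expression matrix
#'
#' An `ExpressionMatrix` is a plain numeric matrix (genes in rows, samples in
#' columns) carrying a `scale_tag` attribute that records the measurement
#' scale. Values must be non-negative unless the matrix is already on the
#' log2 scale.
#'
#' @param values Numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids).
#' @param scale_tag One of `"counts"`, `"fpkm"`, `"rsem"`, `"log2"`.
#' @return A matrix of class `ExpressionMatrix` with a `scale_tag` attribute.
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))), "counts")
#' scale_tag(m)
#' @export
expression_matrix <- function(values,
                              scale_tag = c("counts", "fpkm", "rsem", "log2")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (scale_tag != "log2" && any(values < 0))
    stop("negative values are not allowed on the '", scale_tag, "' scale")
  structure(values, scale_tag = scale_tag,
            class = c("ExpressionMatrix", class(values)))
}

#' @rdname expression_matrix
#' @param m An `ExpressionMatrix`.
#' @export
scale_tag <- function(m) {
  tag <- attr(m, "scale_tag")
  if (is.null(tag)) stop("matrix has no scale_tag; use expression_matrix()")
  tag
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s scale]\n",
              nrow(x), ncol(x), scale_tag(x)))
  invisible(x)
}

# `[` keeps the class and tag so subsetting stays an ExpressionMatrix
# (unless dimensions are dropped).
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, scale_tag = attr(x, "scale_tag"), class = class(x))
  out
}

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a genes-by-samples expression table
#'
#' Reads a delimited text file (TSV by default, CSV by extension) whose first
#' column holds gene ids and whose header row holds sample ids. Duplicate
#' gene ids are collapsed by keeping the row with the highest median
#' expression; duplicate sample ids are an error, as is any non-numeric cell.
#'
#' @param path File path.
#' @param scale_tag Scale of the stored values (see [expression_matrix()]).
#' @param sep Field separator; inferred from the file extension by default.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, scale_tag = "counts", sep = infer_sep(path)) {
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character", comment.char = "")
  gene_ids <- df[[1L]]
  vals <- matrix(NA_real_, nrow(df), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   col[bad[1L]], gene_ids[bad[1L]], sample_ids[j]))
    vals[, j] <- num
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    med <- apply(vals, 1L, stats::median)
    keep <- rep(TRUE, nrow(vals))
    for (g in dup) {
      idx <- which(gene_ids == g)
      keep[idx] <- FALSE
      keep[idx[which.max(med[idx])]] <- TRUE
    }
    message(sprintf("collapsed %d duplicated gene id(s) by max-median row", length(dup)))
    vals <- vals[keep, , drop = FALSE]
  }
  m <- expression_matrix(vals, scale_tag)
  message(sprintf("read expression: %d genes x %d samples from %s",
                  nrow(m), ncol(m), path))
  m
}

#' Write an expression matrix to a delimited text file
#'
#' @inheritParams read_expression
#' @param m An `ExpressionMatrix`.
#' @param gene_col Name for the gene-id column.
#' @export
write_expression <- function(m, path, sep = infer_sep(path), gene_col = "gene_id") {
  df <- data.frame(rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- gene_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  message(sprintf("wrote expression: %d genes x %d samples to %s",
                  nrow(m), ncol(m), path))
  invisible(path)
}

#' Read a sample-to-(patient, region) map
#'
#' The file must have columns `sample_id`, `patient_id`, `region` (header
#' required, extra columns ignored). Each sample may belong to exactly one
#' patient.
#'
#' @param path File path.
#' @param sep Field separator; inferred from the extension by default.
#' @return A data.frame with columns `sample_id`, `patient_id`, `region`.
#' @export
read_sample_map <- function(path, sep = infer_sep(path)) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_sample_map(df)
}

validate_sample_map <- function(df) {
  need <- c("sample_id", "patient_id", "region")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample map lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  if (anyDuplicated(df$sample_id))
    stop("sample map: duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df
}

#' Read a clinical table
#'
#' Requires columns `sample_id`, `time` (days, strictly positive) and `event`
#' (0/1). Any further columns are kept as clinical covariates (age, sex,
#' stage, histology, asbestos exposure, ...).
#'
#' @inheritParams read_sample_map
#' @return A validated data.frame.
#' @export
read_clinical <- function(path, sep = infer_sep(path)) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_clinical(df)
}

validate_clinical <- function(df) {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("clinical table: duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!is.numeric(df$time) || any(!is.finite(df$time)) || any(df$time <= 0))
    stop("clinical table: 'time' must be finite and strictly positive")
  if (!all(df$event %in% c(0, 1)))
    stop("clinical table: 'event' must be 0/1")
  df
}

#' Read a gene-by-sample copy-number call matrix
#'
#' Same layout as [read_expression()]; values may be discrete calls
#' (-1/0/+1) or real-valued segment means.
#'
#' @inheritParams read_expression
#' @return A numeric matrix, genes in rows.
#' @export
read_cnv <- function(path, sep = infer_sep(path)) {
  m <- read_expression(path, scale_tag = "log2", sep = sep)  # allow negatives
  out <- unclass(m)
  attr(out, "scale_tag") <- NULL
  out
}

#' Median-of-library-size normalization and log2 transform
#'
#' Rescales every sample (column) so that its total equals the cohort median
#' total, then applies `log2(x + pseudocount)`. After rescaling, all column
#' sums of the pre-log matrix equal the median library size. The pseudocount
#' (default 1) maps zero counts to 0 on the log2 scale.
#'
#' @param m An `ExpressionMatrix` on a linear scale (`counts`, `fpkm`, `rsem`).
#' @param pseudocount Added before the log2 transform.
#' @param library_normalize If `FALSE`, skip the library-size rescaling and
#'   only log-transform (for inputs already normalized upstream).
#' @return An `ExpressionMatrix` with `scale_tag = "log2"`.
#' @examples
#' m <- expression_matrix(matrix(c(10, 90, 30, 270), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), "counts")
#' normalize_and_log(m)
#' @export
normalize_and_log <- function(m, pseudocount = 1, library_normalize = TRUE) {
  if (scale_tag(m) == "log2")
    stop("matrix is already log2-scaled")
  vals <- unclass(m)
  if (library_normalize) {
    lib <- colSums(vals)
    zero <- which(lib == 0)
    if (length(zero))
      stop("sample(s) with zero total signal: ",
           paste(colnames(vals)[zero], collapse = ", "))
    vals <- sweep(vals, 2L, stats::median(lib) / lib, `*`)
  }
  expression_matrix(log2(vals + pseudocount), "log2")
}

#' Join an expression matrix to clinical follow-up
#'
#' Intersects the expression samples with the clinical table, optionally
#' excluding very short survivors (e.g. peri-operative deaths with overall
#' survival under 30 days), and returns a `SurvivalCohort`.
#'
#' @param m An `ExpressionMatrix`.
#' @param clinical A clinical data.frame (see [read_clinical()]).
#' @param exclude_short_survivors_days If non-`NULL`, samples with
#'   `time < exclude_short_survivors_days` are dropped.
#' @return A `SurvivalCohort`: list with `expr` (genes x samples) and
#'   `clinical` (one row per retained sample, same order as the columns).
#' @export
align_cohort <- function(m, clinical, exclude_short_survivors_days = NULL) {
  clinical <- validate_clinical(clinical)
  shared <- intersect(colnames(m), clinical$sample_id)
  if (!length(shared))
    stop("no samples shared between expression matrix and clinical table")
  n_expr_only <- ncol(m) - length(shared)
  n_clin_only <- nrow(clinical) - length(shared)
  clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  if (!is.null(exclude_short_survivors_days)) {
    keep <- clinical$time >= exclude_short_survivors_days
    message(sprintf("excluded %d sample(s) with survival < %s days",
                    sum(!keep), format(exclude_short_survivors_days)))
    clinical <- clinical[keep, , drop = FALSE]
    shared <- clinical$sample_id
    if (!length(shared)) stop("no samples left after short-survivor exclusion")
  }
  message(sprintf(
    "aligned cohort: %d samples kept (%d expression-only, %d clinical-only dropped)",
    length(shared), n_expr_only, n_clin_only))
  rownames(clinical) <- NULL
  structure(list(expr = m[, shared, drop = FALSE], clinical = clinical),
            class = "SurvivalCohort")
}

#' @export
print.SurvivalCohort <- function(x, ...) {
  cat(sprintf("SurvivalCohort: %d genes x %d samples, %d events\n",
              nrow(x$expr), ncol(x$expr), sum(x$clinical$event)))
  invisible(x)
}

#' Bundle an expression matrix with its multi-region sample map
#'
#' A `MultiRegionCohort` holds a (log2-scaled, typically) expression matrix
#' together with the sample-to-(patient, region) map, restricted and
#' reordered to their common samples. It is the substrate for the
#' heterogeneity and concordance scores.
#'
#' @param m An `ExpressionMatrix`.
#' @param sample_map Data.frame with `sample_id`, `patient_id`, `region`.
#' @return A `MultiRegionCohort`: list with `expr` and `map`.
#' @export
multiregion_cohort <- function(m, sample_map) {
  sample_map <- validate_sample_map(sample_map)
  shared <- intersect(colnames(m), sample_map$sample_id)
  if (!length(shared))
    stop("no samples shared between expression matrix and sample map")
  sample_map <- sample_map[match(shared, sample_map$sample_id), , drop = FALSE]
  rownames(sample_map) <- NULL
  n_regions <- table(sample_map$patient_id)
  if (any(n_regions < 2))
    warning("patient(s) with a single region: ",
            paste(names(n_regions)[n_regions < 2], collapse = ", "),
            " (heterogeneity scores require >= 2 regions)")
  structure(list(expr = m[, shared, drop = FALSE], map = sample_map),
            class = "MultiRegionCohort")
}

#' @export
print.MultiRegionCohort <- function(x, ...) {
  cat(sprintf("MultiRegionCohort: %d genes, %d patients, %d region-samples\n",
              nrow(x$expr), length(unique(x$map$patient_id)), ncol(x$expr)))
  invisible(x)
}

# sample column indices of x$expr per patient, in map order
patient_columns <- function(cohort) {
  split(seq_len(nrow(cohort$map)), cohort$map$patient_id)
}
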