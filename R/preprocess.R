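#' Restrict a dataset to an age range
#'
#' Keeps samples with `min_age <= age <= max_age` (both bounds inclusive).
#' The default window excludes developmental samples, whose expression
#' changes reflect brain maturation rather than aging.
#'
#' @param expr expression matrix (samples aligned with `meta`).
#' @param meta metadata with age column.
#' @param min_age,max_age inclusive bounds in years.
#' @return list with filtered `expr` and `meta`.
#' @export
filter_age <- function(expr, meta, min_age = 20, max_age = 80) {
  stopifnot(ncol(expr) == nrow(meta))
  keep <- meta$age >= min_age & meta$age <= max_age
  if (!any(keep)) stop("no samples remain after age filtering")
  n_drop <- sum(!keep)
  if (n_drop) log_info("age filter: dropped %d of %d samples", n_drop, length(keep))
  list(expr = expr[, keep, drop = FALSE], meta = meta[keep, , drop = FALSE])
}

#' Summarize probe-level expression to gene level
#'
#' Probes mapping to more than one gene are removed to avoid duplicated
#' signal; when several probes map to one gene their values are averaged
#' (arithmetic mean per sample).
#'
#' @param probe_expr probe-by-sample matrix.
#' @param probe_map data.frame with columns `probe_id`, `gene_id` (one row
#'   per mapping; a probe with several rows maps to several genes).
#' @return gene-by-sample matrix.
#' @export
summarize_probes <- function(probe_expr, probe_map) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  missing <- setdiff(rownames(probe_expr), probe_map$probe_id)
  if (length(missing))
    stop("probes absent from the map: ", paste(head(missing, 5), collapse = ", "))
  n_genes_per_probe <- tapply(probe_map$gene_id, probe_map$probe_id,
                              function(g) length(unique(g)))
  multi <- names(n_genes_per_probe)[n_genes_per_probe > 1]
  if (length(multi))
    log_info("removed %d multi-gene probes", length(multi))
  keep_map <- probe_map[!(probe_map$probe_id %in% multi) &
                          probe_map$probe_id %in% rownames(probe_expr), ]
  if (!nrow(keep_map)) stop("no probes survive summarization")
  sub <- probe_expr[keep_map$probe_id, , drop = FALSE]
  out <- rowsum(sub, group = keep_map$gene_id) /
    as.vector(table(keep_map$gene_id)[sort(unique(keep_map$gene_id))])
  out[sort(unique(keep_map$gene_id)), , drop = FALSE]
}

#' Quantile normalization
#'
#' Forces every sample (column) onto the common reference distribution given
#' by the row means of the column-sorted matrix. Ties within a column
#' receive the mean of the reference values spanned by their tied ranks, the
#' convention of the standard microarray implementation.
#'
#' @param expr numeric matrix, no missing values.
#' @return matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(expr) {
  validate_expression(expr)
  if (ncol(expr) == 1) return(expr)
  ref <- rowMeans(apply(expr, 2, sort))
  cs0 <- c(0, cumsum(ref))
  out <- apply(expr, 2, function(col) {
    r <- rank(col, ties.method = "average")
    tie_n <- ave(col, col, FUN = length)
    a <- r - (tie_n - 1) / 2  # first and last rank of each tie run
    b <- r + (tie_n - 1) / 2
    (cs0[b + 1] - cs0[a]) / tie_n
  })
  dimnames(out) <- dimnames(expr)
  out
}

# Build a dummy-coded design matrix for the named covariates. Character
# covariates become factors with sorted levels (first-level reference);
# numeric covariates enter as-is. Errors on single-level factors and
# rank-deficient designs.
build_design <- function(meta, covariates, extra = NULL) {
  if (length(covariates)) {
    absent <- setdiff(covariates, names(meta))
    if (length(absent))
      stop("covariates absent from metadata: ", paste(absent, collapse = ", "))
  }
  df <- data.frame(row.names = seq_len(nrow(meta)))
  for (cv in covariates) {
    v <- meta[[cv]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v, levels = sort(unique(as.character(v))))
      if (nlevels(v) < 2)
        stop("covariate '", cv, "' has a single level")
    }
    df[[cv]] <- v
  }
  X <- if (ncol(df)) model.matrix(~ ., data = df)
       else matrix(1, nrow(meta), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(extra)) {
    X <- cbind(X[, 1, drop = FALSE], extra, X[, -1, drop = FALSE])
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Remove covariate effects by per-gene regression
#'
#' Fits, for every gene, ordinary least squares of expression on an
#' intercept plus the named covariates (categorical covariates dummy-coded)
#' and returns the residuals. Age is deliberately not part of this model:
#' the corrected matrix feeds the grouped variability statistic, which must
#' retain the age signal. With `keep_intercept` (default) the fitted
#' intercept is added back so values stay on the log2 scale; the downstream
#' IQR statistics are shift-invariant either way.
#'
#' @param expr expression matrix aligned with `meta`.
#' @param meta metadata data.frame.
#' @param covariates character vector of metadata column names.
#' @param keep_intercept add the per-gene intercept back to the residuals.
#' @return corrected expression matrix.
#' @export
correct_covariates <- function(expr, meta, covariates,
                               keep_intercept = TRUE) {
  stopifnot(ncol(expr) == nrow(meta))
  if (!length(covariates)) {
    if (keep_intercept) return(expr)
    return(expr - rowMeans(expr))
  }
  X <- build_design(meta, covariates)
  fit <- lm.fit(X, t(expr))
  res <- t(fit$residuals)
  if (keep_intercept) {
    b0 <- if (is.matrix(fit$coefficients)) fit$coefficients["(Intercept)", ]
          else fit$coefficients["(Intercept)"]
    res <- res + b0
  }
  dimnames(res) <- dimnames(expr)
  res
}
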