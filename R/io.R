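#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix of log2 expression values with
#' unique gene identifiers as row names and unique sample identifiers as
#' column names.
#'
#' @param expr numeric matrix, genes in rows, samples in columns.
#' @param require_finite error on missing/non-finite values (the state every
#'   post-preprocessing stage assumes).
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_expression <- function(expr, require_finite = TRUE) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene row names and sample column names")
  dup <- unique(rownames(expr)[duplicated(rownames(expr))])
  if (length(dup))
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  dup <- unique(colnames(expr)[duplicated(colnames(expr))])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  if (require_finite && !all(is.finite(expr)))
    stop("expression matrix contains missing or non-finite values")
  invisible(expr)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample identifiers and
#' gene identifiers in the first column. Decimal separator is ".", no quoting.
#'
#' @param path file path.
#' @return numeric matrix with gene row names and sample column names.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV needs a gene id column and >=1 sample")
  genes <- df[[1L]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene ids in ", path, ": ", paste(dup, collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(genes, colnames(vals))
  validate_expression(num, require_finite = FALSE)
  num
}

#' Write an expression matrix as TSV
#'
#' @param expr numeric matrix with dimnames.
#' @param path output path.
#' @param id_column header for the gene id column.
#' @export
write_expression <- function(expr, path, id_column = "gene_id") {
  validate_expression(expr, require_finite = FALSE)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from TSV
#'
#' Requires `sample_id` and a numeric `age` column (years); any further
#' columns (sex, race, batch, pmi, rin, ph, ...) are retained as covariates.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("sample_id column required")
  if (!"age" %in% names(df)) stop("age required")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  df$age <- as.numeric(df$age)
  if (anyNA(df$age)) stop("non-numeric age values in metadata")
  df
}

#' Write sample metadata as TSV
#' @param meta data.frame with sample_id column.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an expression matrix and metadata on shared samples
#'
#' Both are restricted to the intersection of sample ids, in the expression
#' matrix's column order; dropped counts are logged to standard error.
#'
#' @param expr expression matrix.
#' @param meta metadata data.frame with sample_id.
#' @return list with elements `expr` and `meta`.
#' @export
align_samples <- function(expr, meta) {
  shared <- intersect(colnames(expr), meta$sample_id)
  if (!length(shared)) stop("no shared sample ids between expression and metadata")
  shared <- colnames(expr)[colnames(expr) %in% shared]
  n_drop_e <- ncol(expr) - length(shared)
  n_drop_m <- nrow(meta) - length(shared)
  if (n_drop_e || n_drop_m)
    log_info("align: dropped %d expression and %d metadata samples",
             n_drop_e, n_drop_m)
  list(expr = expr[, shared, drop = FALSE],
       meta = meta[match(shared, meta$sample_id), , drop = FALSE])
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description,
#' then member genes. Within-set duplicates are removed (logged).
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions in
#'   `attr(,"description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    log_warn("empty gene set file: %s", path)
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate set ids in GMT")
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    u <- unique(members)
    if (length(u) < length(members))
      log_info("GMT set '%s': removed %d duplicate members",
               f[1L], length(members) - length(u))
    u
  })
  names(sets) <- ids
  attr(sets, "description") <- setNames(desc, ids)
  sets
}

#' Write a gene-set collection to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(description) && id %in% names(description))
      description[[id]] else "na"
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Default analysis configuration
#'
#' Central defaults shared by the pipeline stages: the age power transform,
#' the young/old group definitions, the resampling depth of the grouped null,
#' and the FDR threshold.
#'
#' @param age_transform_exponent power applied to age in the mean model.
#' @param young_range,old_range inclusive age ranges (years) of the two
#'   groups; must be disjoint and within \[20, 80\].
#' @param n_resamples size of the young-group subsampling null.
#' @param fdr_threshold Benjamini-Hochberg q cutoff for calling genes.
#' @param set_size_distribution,set_size_gsea \[min, max\] gene-set sizes for
#'   the pathway distribution summary and for preranked GSEA.
#' @param seed root random seed (NULL: use the session stream).
#' @return list of validated settings.
#' @export
analysis_config <- function(age_transform_exponent = 0.25,
                            young_range = c(20, 40), old_range = c(60, 80),
                            n_resamples = 10000, fdr_threshold = 0.05,
                            set_size_distribution = c(5, 500),
                            set_size_gsea = c(10, 500), seed = NULL) {
  if (young_range[2] >= old_range[1])
    stop("young and old age ranges must not overlap")
  if (young_range[1] < 20 || old_range[2] > 80)
    stop("group ranges must lie within [20, 80]")
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("fdr_threshold must be in (0, 1)")
  list(age_transform_exponent = age_transform_exponent,
       young_range = young_range, old_range = old_range,
       n_resamples = as.integer(n_resamples), fdr_threshold = fdr_threshold,
       set_size_distribution = set_size_distribution,
       set_size_gsea = set_size_gsea, seed = seed)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and lines
#' starting with `#` ignored. Numeric-looking values are converted; values
#' with commas become vectors.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}
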