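# Shared fixture builders; everything is generated in code at test time.

fix_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

fix_meta <- function(ages, samples = NULL, ...) {
  if (is.null(samples)) samples <- sprintf("s%d", seq_along(ages))
  data.frame(sample_id = samples, age = ages, ..., stringsAsFactors = FALSE)
}

write_tsv_tmp <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent type-7 quantile: direct interpolation of order statistics.
oracle_quantile7 <- function(x, q) {
  xs <- sort(unname(x))
  n <- length(xs)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracle_iqr <- function(x) oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25)
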