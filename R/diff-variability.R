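# Row-wise sort of a matrix in one C-level pass (rows stay rows).
row_sort <- function(m) {
  matrix(m[order(row(m), m)], nrow = nrow(m), byrow = TRUE)
}

# Type-7 IQR of every row of a row-sorted matrix with k columns.
row_iqr_sorted <- function(s, k = ncol(s)) {
  h <- (k - 1) * c(0.25, 0.75) + 1
  lo <- floor(h); hi <- ceiling(h); g <- h - lo
  q25 <- s[, lo[1]] + g[1] * (s[, hi[1]] - s[, lo[1]])
  q75 <- s[, lo[2]] + g[2] * (s[, hi[2]] - s[, lo[2]])
  q75 - q25
}

#' Continuous differential variability: residual-rank correlation
#'
#' For each gene, fits the differential-expression model (intercept +
#' age^exponent + covariates), takes the absolute residuals as the per-sample
#' variability signal, and computes the Spearman correlation between
#' |residuals| and age. A positive value means the spread around the age
#' trend grows with age. P-values use the t approximation and are
#' FDR-adjusted. Genes with zero residuals (exact fits) are degenerate:
#' estimate 0, p 1.
#'
#' @param expr expression matrix aligned with `meta`.
#' @param meta metadata with age.
#' @param covariates metadata columns adjusted for in the mean model.
#' @param age_exponent power applied to age in the mean model.
#' @return data.frame: gene_id, dvar_rho, p_value, q_value, degenerate.
#' @export
dvar_continuous <- function(expr, meta, covariates = character(),
                            age_exponent = 0.25) {
  if (nrow(meta) < 10) stop("need at least 10 samples")
  fit <- fit_gene_model(expr, meta, covariates, age_exponent)
  absres <- abs(fit$residuals)
  n <- ncol(absres)
  ry <- rank(meta$age)
  cy <- ry - mean(ry)
  syy <- sum(cy^2)
  rx <- t(apply(absres, 1, rank))
  cx <- rx - rowMeans(rx)
  sxx <- rowSums(cx^2)
  # Exact fits leave residuals at floating-point noise scale; their ranks
  # carry no information, so flag genes whose residual spread is negligible
  # relative to the expression spread (or whose |residual| ranks are tied).
  expr_scale <- apply(expr, 1, function(v) max(abs(v - mean(v))))
  res_scale <- apply(absres, 1, max)
  degenerate <- sxx < 1e-12 |
    res_scale <= 1e-8 * pmax(expr_scale, .Machine$double.eps)
  rho <- ifelse(degenerate, 0, as.vector(cx %*% cy) / sqrt(sxx * syy))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- ifelse(degenerate, 1, 2 * pt(-abs(tt), df = n - 2))
  data.frame(gene_id = rownames(expr), dvar_rho = rho, p_value = pval,
             q_value = bh_fdr(pval), degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subsampling null distribution of the young-group IQR
#'
#' Draws `B` without-replacement subsamples of `subsample_size` from the
#' young group's values and records each IQR. When the number of distinct
#' subsets is at most `exhaustive_limit`, all subsets are enumerated instead
#' (flagged in `attr(,"exhaustive")`), giving exact tail fractions.
#'
#' @param young_values numeric vector of young-group expression values.
#' @param subsample_size draw size (the old-group size).
#' @param B number of random subsamples.
#' @param seed random seed.
#' @param exhaustive_limit enumerate all subsets when their count is at most
#'   this.
#' @return numeric vector of null IQRs with attribute `exhaustive`.
#' @export
null_iqr_distribution <- function(young_values, subsample_size, B = 10000,
                                  seed = NULL, exhaustive_limit = 50000) {
  ny <- length(young_values)
  if (subsample_size < 2) stop("subsample size must be >= 2")
  if (subsample_size > ny) stop("subsample size exceeds young group size")
  n_subsets <- choose(ny, subsample_size)
  if (n_subsets <= exhaustive_limit) {
    idx <- combn(ny, subsample_size)
    vals <- matrix(young_values[idx], ncol = nrow(idx), byrow = TRUE)
    out <- row_iqr_sorted(row_sort(vals))
    attr(out, "exhaustive") <- TRUE
    return(out)
  }
  out <- with_seed(seed, {
    idx <- vapply(seq_len(B), function(b) sample.int(ny, subsample_size),
                  integer(subsample_size))
    vals <- matrix(young_values[idx], nrow = B, byrow = TRUE)
    row_iqr_sorted(row_sort(vals))
  })
  attr(out, "exhaustive") <- FALSE
  out
}

#' Grouped differential variability: IQR with a subsampling null
#'
#' Compares expression variability between a young and an old age group via
#' the interquartile range. To adjust for the groups' unequal sizes, the
#' young group's IQR is characterized by its null distribution over
#' without-replacement subsamples of the old-group size. The statistic is
#' the fractional change
#' \deqn{\Delta var(IQR) = (IQR_{old} - \overline{IQR}_{young}) /
#'   \overline{IQR}_{young}}
#' where the bar denotes the mean over the null draws. The empirical
#' p-value doubles the smaller tail fraction of the null at IQR_old, with
#' add-one correction in sampled mode (exact fractions in exhaustive mode).
#' Middle-aged samples fall outside both groups and are ignored by design.
#'
#' One set of subsample index vectors is shared by all genes in a run, so
#' the whole matrix is processed vectorized; each gene's null remains a
#' valid subsampling distribution and the run is deterministic given `seed`.
#'
#' The input should already be covariate-corrected (with age \emph{not}
#' regressed out). Genes whose null-mean IQR is zero are flagged degenerate
#' and excluded from the FDR adjustment.
#'
#' @param expr covariate-corrected expression matrix aligned with `meta`.
#' @param meta metadata with age.
#' @param young_range,old_range inclusive age ranges (years).
#' @param B number of subsamples of the young group.
#' @param seed random seed.
#' @param exhaustive_limit switch to full subset enumeration when the number
#'   of distinct subsets is at most this.
#' @param fdr_threshold q cutoff used for the direction label.
#' @return data.frame: gene_id, iqr_old, iqr_young_mean, dvar_iqr,
#'   p_empirical, q_value, n_resamples, null quantile columns, degenerate.
#'   Attribute `exhaustive` records the null mode.
#' @export
dvar_grouped <- function(expr, meta, young_range = c(20, 40),
                         old_range = c(60, 80), B = 10000, seed = NULL,
                         exhaustive_limit = 50000, fdr_threshold = 0.05) {
  stopifnot(ncol(expr) == nrow(meta))
  young <- which(meta$age >= young_range[1] & meta$age <= young_range[2])
  old <- which(meta$age >= old_range[1] & meta$age <= old_range[2])
  ny <- length(young); k <- length(old)
  if (ny < 4 || k < 4) stop("each age group needs at least 4 samples")
  if (k > ny) stop("old group larger than young group")
  G <- nrow(expr)
  Yy <- expr[, young, drop = FALSE]
  Yo <- expr[, old, drop = FALSE]
  iqr_old <- row_iqr_sorted(row_sort(Yo), k)

  n_subsets <- choose(ny, k)
  exhaustive <- n_subsets <= exhaustive_limit
  idx_mat <- if (exhaustive) combn(ny, k)
             else with_seed(seed, vapply(seq_len(B), function(b)
               sample.int(ny, k), integer(k)))
  Buse <- ncol(idx_mat)

  cnt_ge <- cnt_le <- numeric(G)
  null_sum <- numeric(G)
  keep_null <- as.numeric(G) * Buse <= 5e7
  null_store <- if (keep_null) matrix(NA_real_, G, Buse) else NULL
  for (b in seq_len(Buse)) {
    iqr_b <- row_iqr_sorted(row_sort(Yy[, idx_mat[, b], drop = FALSE]), k)
    cnt_ge <- cnt_ge + (iqr_b >= iqr_old)
    cnt_le <- cnt_le + (iqr_b <= iqr_old)
    null_sum <- null_sum + iqr_b
    if (keep_null) null_store[, b] <- iqr_b
  }
  iqr_young_mean <- null_sum / Buse
  degenerate <- iqr_young_mean <= 0
  if (any(degenerate))
    log_warn("%d genes with zero young-group IQR excluded from FDR",
             sum(degenerate))
  dvar <- ifelse(degenerate, NA_real_,
                 (iqr_old - iqr_young_mean) / iqr_young_mean)
  p_emp <- if (exhaustive) {
    pmin(1, 2 * pmin(cnt_ge, cnt_le) / Buse)
  } else {
    pmin(1, 2 * pmin((1 + cnt_ge) / (Buse + 1), (1 + cnt_le) / (Buse + 1)))
  }
  p_emp[degenerate] <- NA_real_
  qv <- rep(NA_real_, G)
  qv[!degenerate] <- bh_fdr(p_emp[!degenerate])

  nullq <- if (keep_null) {
    t(apply(null_store, 1, quantile_type7, q = c(0.05, 0.25, 0.5, 0.75, 0.95)))
  } else matrix(NA_real_, G, 5)
  colnames(nullq) <- paste0("null_iqr_q", c("05", "25", "50", "75", "95"))

  out <- data.frame(
    gene_id = rownames(expr), iqr_old = iqr_old,
    iqr_young_mean = iqr_young_mean, dvar_iqr = dvar,
    p_empirical = p_emp, q_value = qv, n_resamples = Buse,
    nullq,
    direction = ifelse(is.na(qv) | qv > fdr_threshold, "null",
                       ifelse(dvar > 0, "increase",
                              ifelse(dvar < 0, "decrease", "null"))),
    degenerate = degenerate, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "exhaustive") <- exhaustive
  out
}

#' Classify and summarize differential-variability results
#'
#' Labels each gene increase/decrease/null from the sign of its variability
#' measure and the FDR threshold (inclusive), and summarizes the
#' transcriptome-wide shift: fraction of genes with a positive measure,
#' median, skewness, and a Wilcoxon signed-rank test of median zero.
#'
#' @param results data.frame from \code{\link{dvar_continuous}} (column
#'   `dvar_rho`) or \code{\link{dvar_grouped}} (column `dvar_iqr`).
#' @param fdr_threshold q-value cutoff.
#' @return list with `counts`, `genes` per class, and `summary` (list:
#'   fraction_positive, median_dvar, skewness, wilcoxon_p, all_zero flag).
#' @export
dv_classify <- function(results, fdr_threshold = 0.05) {
  col <- intersect(c("dvar_rho", "dvar_iqr"), names(results))
  if (!length(col)) stop("no variability measure column found")
  dvar <- results[[col[1]]]
  qv <- results$q_value
  lab <- ifelse(is.na(qv) | is.na(dvar) | qv > fdr_threshold, "null",
                ifelse(dvar > 0, "increase",
                       ifelse(dvar < 0, "decrease", "null")))
  ok <- !is.na(dvar)
  d <- dvar[ok]
  all_zero <- all(d == 0)
  summary <- list(
    fraction_positive = mean(d > 0),
    median_dvar = median(d),
    skewness = if (length(unique(d)) > 1) skewness_g1(d) else NA_real_,
    wilcoxon_p = if (all_zero) NA_real_ else
      suppressWarnings(wilcox.test(d, mu = 0)$p.value),
    all_zero = all_zero)
  if (all_zero) log_warn("all variability measures are exactly zero")
  list(counts = c(increase = sum(lab == "increase"),
                  decrease = sum(lab == "decrease"),
                  null = sum(lab == "null")),
       genes = split(results$gene_id,
                     factor(lab, c("increase", "decrease", "null"))),
       summary = summary)
}
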