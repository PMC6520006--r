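#' Linear-interpolation quantile (type 7)
#'
#' Order-statistic interpolation at index h = (n-1)q + 1, the default
#' convention of most statistical environments. The grouped variability
#' statistic depends on this convention, so it is fixed package-wide.
#'
#' @param x numeric vector, finite values.
#' @param q probabilities in \[0, 1\].
#' @return quantile values, unnamed.
#' @export
quantile_type7 <- function(x, q) {
  if (!length(x)) stop("empty vector")
  if (!all(is.finite(x))) stop("non-finite values")
  if (any(q < 0 | q > 1)) stop("q outside [0, 1]")
  unname(quantile(x, probs = q, type = 7, names = FALSE))
}

#' Interquartile range (type-7 quantiles)
#'
#' 75th minus 25th percentile; the robust spread measure used by the grouped
#' differential-variability statistic.
#'
#' @param x numeric vector of length >= 2.
#' @return non-negative scalar.
#' @export
iqr <- function(x) {
  if (length(x) < 2) stop("iqr needs at least 2 values")
  qs <- quantile_type7(x, c(0.25, 0.75))
  qs[2] - qs[1]
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average-ranked vectors; two-sided p from the t
#' approximation on n - 2 degrees of freedom (used for all n; the group
#' sizes in this pipeline are >= 22). A constant input yields a degenerate
#' result with estimate 0 and p 1.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with estimate, p_value, n, degenerate.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    return(list(estimate = 0, p_value = 1, n = n, degenerate = TRUE))
  rho <- cor(rx, ry)
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(estimate = rho, p_value = 2 * pt(-abs(tt), df = n - 2),
       n = n, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: q(i) = min over j >= i (in sorted order) of p(j) m / j,
#' capped at 1, returned in the input order.
#'
#' @param p p-values in \[0, 1\]; NAs propagate.
#' @return q-values.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities not exceeding
#' that of the observed table (with the customary relative tolerance for
#' floating-point ties). The reported estimate is the sample odds ratio
#' ad/bc; infinite or zero ratios are flagged degenerate.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with estimate (odds ratio), p_value, n (table total),
#'   degenerate.
#' @export
fisher_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; c2 <- b + d; n <- sum(tab)
  if (n == 0) stop("empty table")
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, c1, c2, r1)
  p_obs <- probs[match(a, support)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c_)
  list(estimate = or, p_value = p, n = n,
       degenerate = !is.finite(or))
}

#' Moment coefficient of skewness (g1)
#'
#' m3 / m2^(3/2) with central moments mk = mean((x - mean(x))^k); no
#' small-sample bias correction.
#'
#' @param x numeric vector, n >= 3, non-constant.
#' @return scalar skewness.
#' @export
skewness_g1 <- function(x) {
  if (length(x) < 3) stop("need n >= 3")
  cx <- x - mean(x)
  m2 <- mean(cx^2)
  if (m2 == 0) stop("constant input")
  mean(cx^3) / m2^1.5
}

#' Shapiro-Wilk normality testing on repeated subsamples
#'
#' For distributions with more observations than the Shapiro-Wilk test
#' accepts, draw without-replacement subsamples of a fixed size and test
#' each. A subsample size larger than the data is clipped (logged).
#'
#' @param x numeric vector.
#' @param subsample_size draw size per repeat (default 5000, the test's
#'   upper limit).
#' @param n_repeats number of subsamples.
#' @param seed random seed.
#' @return data.frame with one row per repeat: estimate (W), p_value, n,
#'   degenerate.
#' @export
normality_subsample_test <- function(x, subsample_size = 5000,
                                     n_repeats = 20, seed = NULL) {
  m <- length(x)
  if (subsample_size > m) {
    log_info("subsample size %d clipped to data size %d", subsample_size, m)
    subsample_size <- m
  }
  if (subsample_size < 3) stop("need subsample size >= 3")
  with_seed(seed, {
    res <- lapply(seq_len(n_repeats), function(i) {
      s <- x[sample.int(m, subsample_size)]
      if (var(s) == 0)
        return(data.frame(estimate = NA_real_, p_value = NA_real_,
                          n = subsample_size, degenerate = TRUE))
      sw <- shapiro.test(s)
      data.frame(estimate = unname(sw$statistic), p_value = sw$p.value,
                 n = subsample_size, degenerate = FALSE)
    })
    do.call(rbind, res)
  })
}
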