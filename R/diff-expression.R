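#' Per-gene differential expression on power-transformed age
#'
#' Fits, for every gene, ordinary least squares of expression on an
#' intercept, age^exponent and the named covariates. Age enters as
#' age^0.25 by default, compressing the fast changes at young ages relative
#' to the slow changes at old ages and the uneven sampling density. The age
#' coefficient beta1 is the differential-expression measure; its two-sided
#' t-test p-value is FDR-adjusted across genes. Residuals are retained for
#' the continuous differential-variability stage.
#'
#' @param expr expression matrix aligned with `meta`.
#' @param meta metadata with age (years) and any covariates used.
#' @param covariates metadata columns to adjust for (dummy-coded if
#'   categorical).
#' @param age_exponent power applied to age (1 for untransformed age).
#' @param fdr_threshold q cutoff used for the direction label.
#' @return object of class `de_fit`: list with `table` (data.frame gene_id,
#'   beta0, beta1, se, p_value, q_value, direction, degenerate), `residuals`
#'   (gene-by-sample matrix) and `design`.
#' @export
fit_gene_model <- function(expr, meta, covariates = character(),
                           age_exponent = 0.25, fdr_threshold = 0.05) {
  stopifnot(ncol(expr) == nrow(meta))
  age_t <- meta$age^age_exponent
  X <- build_design(meta, covariates, extra = cbind(age_t = age_t))
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("more design columns than samples allow")
  fit <- lm.fit(X, t(expr))
  coefs <- fit$coefficients
  res <- t(fit$residuals)
  rss <- rowSums(res^2)
  df_res <- n - p
  sigma2 <- rss / df_res
  XtXinv <- solve(crossprod(X))
  se1 <- sqrt(sigma2 * XtXinv[2, 2])
  beta1 <- coefs["age_t", ]
  perfect <- sigma2 < 1e-24  # exact fit: no residual noise
  tstat <- beta1 / se1
  tstat[perfect] <- ifelse(abs(beta1[perfect]) > 1e-12, Inf, 0)
  pval <- 2 * pt(-abs(tstat), df = df_res)
  degenerate <- perfect & abs(beta1) <= 1e-12
  zero_var <- apply(expr, 1, function(x) var(x) == 0)
  if (any(zero_var)) {
    beta1[zero_var] <- 0
    pval[zero_var] <- 1
    degenerate[zero_var] <- TRUE
    log_info("%d zero-variance genes set degenerate", sum(zero_var))
  }
  qval <- bh_fdr(pval)
  tab <- data.frame(
    gene_id = rownames(expr), beta0 = coefs["(Intercept)", ],
    beta1 = beta1, se = se1, p_value = pval, q_value = qval,
    direction = ifelse(qval <= fdr_threshold & beta1 > 0, "up",
                       ifelse(qval <= fdr_threshold & beta1 < 0, "down",
                              "null")),
    degenerate = degenerate, row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, residuals = res, design = X,
                 age_exponent = age_exponent),
            class = "de_fit")
}

#' Classify differential-expression results at an FDR threshold
#'
#' A gene is "up" when beta1 > 0 and q <= threshold, "down" when beta1 < 0
#' and q <= threshold (the threshold is inclusive), otherwise "null".
#'
#' @param fit a `de_fit` from \code{\link{fit_gene_model}} or its table.
#' @param fdr_threshold q-value cutoff.
#' @return list with `counts` (named up/down/null) and `genes` (lists of
#'   gene ids per class).
#' @export
de_classify <- function(fit, fdr_threshold = 0.05) {
  tab <- if (inherits(fit, "de_fit")) fit$table else fit
  dir <- ifelse(tab$q_value <= fdr_threshold & tab$beta1 > 0, "up",
                ifelse(tab$q_value <= fdr_threshold & tab$beta1 < 0, "down",
                       "null"))
  list(counts = c(up = sum(dir == "up"), down = sum(dir == "down"),
                  null = sum(dir == "null")),
       genes = split(tab$gene_id, factor(dir, c("up", "down", "null"))))
}
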