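#' Association between mean change and variability change
#'
#' For each gene, computes the difference in means between the old group and
#' the expectation over young subsamples (Delta mean), and the matching
#' difference in IQRs (Delta IQR), using the same subsampling scheme as the
#' grouped variability statistic. The two signs are cross-tabulated
#' (exact zeros fall in the negative cell, logged) and tested for
#' association with Fisher's exact test; an odds ratio near 1 means the
#' change in variability is not confounded by the change in level.
#'
#' @param expr covariate-corrected expression matrix aligned with `meta`.
#' @param meta metadata with age.
#' @param young_range,old_range inclusive age ranges (years).
#' @param B number of young-group subsamples.
#' @param seed random seed.
#' @return list with `table` (per gene: dmean, diqr), `contingency`
#'   (2x2 counts), `fisher` (test result list).
#' @export
mean_var_association <- function(expr, meta, young_range = c(20, 40),
                                 old_range = c(60, 80), B = 10000,
                                 seed = NULL) {
  stopifnot(ncol(expr) == nrow(meta))
  young <- which(meta$age >= young_range[1] & meta$age <= young_range[2])
  old <- which(meta$age >= old_range[1] & meta$age <= old_range[2])
  ny <- length(young); k <- length(old)
  if (ny < 4 || k < 4) stop("each age group needs at least 4 samples")
  G <- nrow(expr)
  Yy <- expr[, young, drop = FALSE]
  Yo <- expr[, old, drop = FALSE]
  mean_old <- rowMeans(Yo)
  iqr_old <- row_iqr_sorted(row_sort(Yo), k)
  mean_sum <- iqr_sum <- numeric(G)
  with_seed(seed, {
    for (b in seq_len(B)) {
      sub <- Yy[, sample.int(ny, k), drop = FALSE]
      mean_sum <- mean_sum + rowMeans(sub)
      iqr_sum <- iqr_sum + row_iqr_sorted(row_sort(sub), k)
    }
  })
  dmean <- mean_old - mean_sum / B
  diqr <- iqr_old - iqr_sum / B
  n_zero <- sum(dmean == 0) + sum(diqr == 0)
  if (n_zero) log_info("%d exact zero differences assigned to negative cell",
                       n_zero)
  tab <- table(factor(dmean > 0, c(TRUE, FALSE)),
               factor(diqr > 0, c(TRUE, FALSE)))
  contingency <- matrix(as.integer(tab), 2, 2,
                        dimnames = list(dmean = c("pos", "neg"),
                                        diqr = c("pos", "neg")))
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0))
    log_warn("degenerate margin in the mean-variability table; p = 1")
  list(table = data.frame(gene_id = rownames(expr), dmean = dmean,
                          diqr = diqr, row.names = NULL,
                          stringsAsFactors = FALSE),
       contingency = contingency,
       fisher = fisher_2x2(contingency))
}

#' Overlap of two gene lists against a universe
#'
#' Jaccard similarity plus Fisher's exact test on the 2x2 membership table.
#'
#' @param list_a,list_b character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return list: n_a, n_b, n_common, universe_size, jaccard, fisher,
#'   contingency.
#' @export
overlap_test <- function(list_a, list_b, universe) {
  a <- unique(list_a); b <- unique(list_b); u <- unique(universe)
  off <- setdiff(c(a, b), u)
  if (length(off))
    stop("genes outside the universe: ", paste(head(off, 5), collapse = ", "))
  n_common <- length(intersect(a, b))
  n_a <- length(a); n_b <- length(b)
  jac <- if (n_a + n_b - n_common == 0) NA_real_
         else n_common / (n_a + n_b - n_common)
  tab <- matrix(c(n_common, n_a - n_common,
                  n_b - n_common, length(u) - n_a - n_b + n_common),
                2, 2, byrow = TRUE,
                dimnames = list(in_a = c("yes", "no"),
                                in_b = c("yes", "no")))
  list(n_a = n_a, n_b = n_b, n_common = n_common,
       universe_size = length(u), jaccard = jac,
       contingency = tab, fisher = fisher_2x2(tab))
}

#' Correlate a variability measure with an external per-gene score
#'
#' Spearman correlation over the genes shared by the two named vectors,
#' optionally on the absolute value of the variability measure (to test
#' association with the magnitude rather than direction of change).
#'
#' @param dvar named numeric vector of variability measures.
#' @param external_score named numeric vector of external scores.
#' @param use_absolute correlate |dvar| instead of dvar.
#' @return Spearman test result (list with estimate, p_value, n,
#'   degenerate) plus `n_shared`.
#' @export
score_correlation <- function(dvar, external_score, use_absolute = FALSE) {
  shared <- intersect(names(dvar), names(external_score))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  x <- dvar[shared]
  if (use_absolute) x <- abs(x)
  out <- spearman_test(x, external_score[shared])
  out$n_shared <- length(shared)
  out
}

#' Cell type-specific genes by standardized effect size
#'
#' Standardizes each gene's expression across samples (z-scores) and defines
#' a cell type's effect size for a gene as the mean z over that type's
#' samples. A gene is specific to a type when the effect size exceeds the
#' threshold; with the default threshold of 2 the resulting lists are
#' expected to be disjoint (a warning is raised otherwise). Constant genes
#' are skipped (logged).
#'
#' @param expr gene-by-sample expression matrix.
#' @param labels per-sample cell-type labels (length = columns of `expr`).
#' @param threshold effect-size cutoff.
#' @return named list of gene-id vectors, one per cell type; effect sizes in
#'   `attr(,"effect_size")`.
#' @export
celltype_specific_genes <- function(expr, labels, threshold = 2) {
  stopifnot(ncol(expr) == length(labels))
  labels <- as.character(labels)
  types <- sort(unique(labels))
  if (length(types) < 2) stop("need at least 2 cell types")
  sds <- apply(expr, 1, sd)
  constant <- sds == 0
  if (any(constant))
    log_info("skipped %d constant genes", sum(constant))
  z <- (expr[!constant, , drop = FALSE] -
          rowMeans(expr[!constant, , drop = FALSE])) / sds[!constant]
  eff <- vapply(types, function(ty)
    rowMeans(z[, labels == ty, drop = FALSE]), numeric(nrow(z)))
  if (nrow(z) == 1) eff <- matrix(eff, nrow = 1,
                                  dimnames = list(rownames(z), types))
  hits <- eff > threshold
  n_assigned <- rowSums(hits)
  if (any(n_assigned > 1))
    log_warn("%d genes exceed the threshold in more than one cell type",
             sum(n_assigned > 1))
  out <- lapply(types, function(ty) rownames(z)[hits[, ty]])
  names(out) <- types
  attr(out, "effect_size") <- eff
  out
}
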