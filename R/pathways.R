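#' Filter a gene-set collection against a scored universe
#'
#' Set membership is first intersected with the universe (genes that carry a
#' score), then sets outside \[min_size, max_size\] on the intersected size
#' are dropped.
#'
#' @param sets named list of character vectors.
#' @param min_size,max_size inclusive size bounds after intersection.
#' @param universe character vector of scored gene ids.
#' @return filtered collection (possibly empty, with a warning).
#' @export
filter_gene_sets <- function(sets, min_size, max_size, universe) {
  out <- lapply(sets, function(m) intersect(m, universe))
  sizes <- lengths(out)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) log_warn("no gene sets survive the size filter")
  n_drop <- sum(!keep)
  if (n_drop) log_info("size filter dropped %d of %d sets", n_drop, length(sets))
  out <- out[keep]
  attr(out, "description") <- attr(sets, "description")[names(out)]
  out
}

#' Per-pathway distribution of variability measures
#'
#' For each gene set, summarizes the distribution of the per-gene
#' variability measure (median and quartiles), and reports two
#' collection-level quantities: the fraction of sets whose median is
#' strictly positive and the mean of the set medians. Output rows are
#' sorted by ascending median.
#'
#' @param scores named numeric vector of per-gene variability measures.
#' @param sets gene-set collection (already size-filtered as desired).
#' @return list with `summary` (data.frame set_id, n_scored, q1,
#'   median_dvar, q3), `fraction_median_positive`, `mean_of_medians`.
#' @export
pathway_distribution <- function(scores, sets) {
  if (!length(sets)) stop("no gene sets supplied")
  rows <- lapply(names(sets), function(id) {
    v <- scores[intersect(sets[[id]], names(scores))]
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(set_id = id, n_scored = 0L, q1 = NA_real_,
                        median_dvar = NA_real_, q3 = NA_real_))
    qs <- quantile_type7(v, c(0.25, 0.5, 0.75))
    data.frame(set_id = id, n_scored = length(v), q1 = qs[1],
               median_dvar = qs[2], q3 = qs[3])
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$median_dvar), , drop = FALSE]
  rownames(tab) <- NULL
  med <- tab$median_dvar[!is.na(tab$median_dvar)]
  list(summary = tab,
       fraction_median_positive = mean(med > 0),
       mean_of_medians = mean(med))
}

# Enrichment score of one set by the weighted running-sum statistic.
# hit_pos: sorted positions of set members in the descending score ranking;
# w_abs: |score|^weight at every position. Only positions adjacent to hits
# can be extrema, so the running sum is evaluated there.
gsea_es <- function(hit_pos, w_abs, N) {
  nh <- length(hit_pos)
  nr <- sum(w_abs[hit_pos])
  if (nr == 0) return(NA_real_)
  miss_dec <- 1 / (N - nh)
  hit_cum <- cumsum(w_abs[hit_pos]) / nr
  miss_before <- (hit_pos - seq_len(nh)) * miss_dec
  at_hit <- hit_cum - miss_before            # running sum just after each hit
  before_hit <- c(0, hit_cum[-nh]) - miss_before  # just before each hit
  cand <- c(at_hit, before_hit)
  cand[which.max(abs(cand))]
}

#' Preranked gene set enrichment on per-gene scores
#'
#' Genes are ranked by decreasing score (ties broken by gene id for
#' determinism). The enrichment score is the maximum deviation of the
#' classic weighted running sum: hits increment by |score|^weight
#' (normalized to sum 1 within the set), misses decrement by 1/(N - set
#' size). The null is by gene-label permutation (random sets of the same
#' size); NES divides ES by the mean |null ES| of matching sign; empirical
#' p-values use add-one correction within the same-sign null; q by BH.
#'
#' @param scores named numeric vector (e.g. per-gene variability measures).
#' @param sets gene-set collection, already filtered against the scored
#'   universe.
#' @param n_perm number of permutations.
#' @param weight exponent on |score| for hit increments (0 = unweighted).
#' @param seed random seed.
#' @return data.frame: set_id, size, es, nes, p_value, q_value, n_perm.
#' @export
gsea_preranked <- function(scores, sets, n_perm = 1000, weight = 1,
                           seed = NULL) {
  if (!length(sets)) stop("no gene sets supplied")
  if (anyDuplicated(names(scores))) stop("duplicate gene ids in scores")
  if (!all(is.finite(scores))) stop("scores must be finite")
  ord <- order(-scores, names(scores))
  genes <- names(scores)[ord]
  s <- scores[ord]
  N <- length(s)
  w_abs <- abs(s)^weight

  res <- lapply(names(sets), function(id) {
    pos <- sort(match(intersect(sets[[id]], genes), genes))
    nh <- length(pos)
    if (nh == 0 || nh == N) return(NULL)
    es <- gsea_es(pos, w_abs, N)
    if (is.na(es)) {
      log_warn("set '%s' degenerate (all member scores zero), skipped", id)
      return(NULL)
    }
    data.frame(set_id = id, size = nh, es = es, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) stop("no usable gene sets")

  with_seed(seed, {
    sizes <- sort(unique(res$size))
    null_by_size <- lapply(sizes, function(nh)
      vapply(seq_len(n_perm), function(p)
        gsea_es(sort(sample.int(N, nh)), w_abs, N), numeric(1)))
    names(null_by_size) <- as.character(sizes)
    stats <- t(vapply(seq_len(nrow(res)), function(i) {
      es <- res$es[i]
      null <- null_by_size[[as.character(res$size[i])]]
      same <- null[sign(null) == sign(es)]
      if (!length(same)) return(c(NA_real_, NA_real_))
      nes <- es / mean(abs(same))
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      c(nes, p)
    }, numeric(2)))
    res$nes <- stats[, 1]
    res$p_value <- stats[, 2]
    res$q_value <- bh_fdr(res$p_value)
    res$n_perm <- n_perm
    rownames(res) <- NULL
    res
  })
}
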