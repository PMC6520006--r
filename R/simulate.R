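#' Configuration for the synthetic expression generator
#'
#' Defaults emulate the study conditions the pipeline targets: ~147 brain
#' samples aged 20-80 with uneven age density (53 young in \[20,40\],
#' 72 middle-aged, 22 old in \[60,80\]), per-gene linear trends in age^0.25,
#' an age-dependent residual scale carrying the planted variability signal,
#' 19 technical batches and sex/race/PMI/RIN/pH covariate effects.
#'
#' The variability trend of a planted gene follows one of two shapes. With
#' `trend_shape = "linear"` the residual SD is sigma0 (1 + gamma (age-20)/60);
#' with `"step"` it is sigma0 below `step_age` and sigma0 (1 + gamma) above.
#' `"mixed"` assigns shapes at random. gamma > 0 plants an increase in
#' variability, -1 < gamma < 0 a decrease.
#'
#' @param n_genes number of genes.
#' @param n_samples number of samples.
#' @param age_bin_weights sampling weights of the \[20,40\], (40,60),
#'   \[60,80\] age bins; must sum to 1.
#' @param quota if TRUE, per-bin sample counts (and per-class gene counts)
#'   are exact; otherwise multinomial.
#' @param beta0_mean,beta0_sd baseline log2 expression distribution.
#' @param frac_de fraction of genes with a non-zero age slope.
#' @param beta1_sd SD of the planted slope (per unit age^0.25) for DE genes.
#' @param sigma0_meanlog,sigma0_sdlog log-normal parameters of the baseline
#'   residual SD (log2 units).
#' @param frac_dv fraction of genes with an age-dependent residual scale.
#' @param frac_dv_increase fraction of DV genes whose variability increases.
#' @param gamma_up_range,gamma_down_range uniform ranges of the variance
#'   trend coefficient for increasing / decreasing genes; decreasing gammas
#'   must stay above -1 so the SD stays positive.
#' @param trend_shape "linear", "step", or "mixed".
#' @param step_age switch age of the step shape (years).
#' @param n_batches number of technical batches.
#' @param batch_sd SD of additive per-(gene, batch) effects (log2 units).
#' @param sex_sd,race_sd SD of per-(gene, level) categorical effects.
#' @param pmi_sd,rin_sd,ph_sd SD of per-gene slopes on the standardized
#'   continuous covariates.
#' @param seed root random seed; the full dataset is deterministic given it.
#' @return validated configuration list.
#' @export
simulation_config <- function(n_genes = 1000, n_samples = 147,
                              age_bin_weights = c(53, 72, 22) / 147,
                              quota = TRUE,
                              beta0_mean = 7, beta0_sd = 1,
                              frac_de = 0.1, beta1_sd = 0.5,
                              sigma0_meanlog = log(0.3), sigma0_sdlog = 0.25,
                              frac_dv = 0.1, frac_dv_increase = 0.5,
                              gamma_up_range = c(1, 3),
                              gamma_down_range = c(-0.7, -0.3),
                              trend_shape = c("linear", "step", "mixed"),
                              step_age = 50,
                              n_batches = 19, batch_sd = 0.3,
                              sex_sd = 0.2, race_sd = 0.1,
                              pmi_sd = 0.1, rin_sd = 0.1, ph_sd = 0.1,
                              seed = NULL) {
  trend_shape <- match.arg(trend_shape)
  stopifnot(n_genes >= 1, n_samples >= 4)
  if (abs(sum(age_bin_weights) - 1) > 1e-8) stop("age bin weights must sum to 1")
  for (f in c(frac_de, frac_dv, frac_dv_increase))
    if (f < 0 || f > 1) stop("fractions must be in [0, 1]")
  if (any(gamma_down_range <= -1)) stop("gamma must stay > -1")
  as.list(environment())
}

# exact per-bin counts by largest remainder, preserving the total
quota_counts <- function(n, weights) {
  raw <- n * weights
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Simulate an expression dataset with planted mean and variance trends
#'
#' Generates Y_gj = beta0_g + beta1_g age_j^0.25 + batch + covariates +
#' eps_gj with eps_gj ~ Normal(0, sigma_gj^2), where sigma_gj follows the
#' per-gene variability trend in \code{\link{simulation_config}}. Ages are
#' drawn uniformly within the three age bins.
#'
#' @param cfg configuration from \code{\link{simulation_config}}.
#' @return list with `expr` (matrix), `meta` (data.frame), `truth`
#'   (data.frame with beta1_true, gamma_true, trend_shape, de, dv labels).
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  with_seed(cfg$seed, {
    G <- cfg$n_genes; n <- cfg$n_samples
    bins <- rbind(c(20, 40), c(40, 60), c(60, 80))
    if (cfg$quota) {
      cnt <- quota_counts(n, cfg$age_bin_weights)
    } else {
      bin_of <- sample.int(3, n, replace = TRUE, prob = cfg$age_bin_weights)
      cnt <- tabulate(bin_of, 3)
    }
    ages <- unlist(lapply(1:3, function(b)
      runif(cnt[b], bins[b, 1], bins[b, 2])))
    ages <- sample(ages)  # shuffle so sample order carries no age structure

    sample_id <- sprintf("s%03d", seq_len(n))
    meta <- data.frame(
      sample_id = sample_id, age = ages,
      sex = sample(c("F", "M"), n, replace = TRUE),
      race = sample(c("AA", "AS", "CAUC", "HISP"), n, replace = TRUE,
                    prob = c(0.35, 0.05, 0.45, 0.15)),
      batch = sprintf("b%02d", sample.int(cfg$n_batches, n, replace = TRUE)),
      pmi = runif(n, 5, 40), rin = runif(n, 5, 9.5),
      ph = rnorm(n, 6.5, 0.25), stringsAsFactors = FALSE)

    gene_id <- sprintf("g%04d", seq_len(G))
    beta0 <- rnorm(G, cfg$beta0_mean, cfg$beta0_sd)
    sigma0 <- rlnorm(G, cfg$sigma0_meanlog, cfg$sigma0_sdlog)

    pick <- function(frac) {
      k <- if (cfg$quota) round(frac * G) else rbinom(1, G, frac)
      sample.int(G, k)
    }
    de_idx <- pick(cfg$frac_de)
    beta1 <- numeric(G)
    beta1[de_idx] <- rnorm(length(de_idx), 0, cfg$beta1_sd)

    dv_idx <- pick(cfg$frac_dv)
    n_up <- if (cfg$quota) round(cfg$frac_dv_increase * length(dv_idx))
            else rbinom(1, length(dv_idx), cfg$frac_dv_increase)
    up_idx <- dv_idx[seq_len(n_up)]
    down_idx <- setdiff(dv_idx, up_idx)
    gamma <- numeric(G)
    gamma[up_idx] <- runif(length(up_idx), cfg$gamma_up_range[1],
                           cfg$gamma_up_range[2])
    gamma[down_idx] <- runif(length(down_idx), cfg$gamma_down_range[1],
                             cfg$gamma_down_range[2])
    shape <- rep("linear", G)
    if (cfg$trend_shape == "step") shape[] <- "step"
    if (cfg$trend_shape == "mixed")
      shape[dv_idx] <- sample(c("linear", "step"), length(dv_idx),
                              replace = TRUE)

    # residual SD per gene x sample
    frac_lin <- (ages - 20) / 60
    step_on <- as.numeric(ages >= cfg$step_age)
    mult <- matrix(1, G, n)
    lin_g <- which(shape == "linear" & gamma != 0)
    if (length(lin_g))
      mult[lin_g, ] <- 1 + outer(gamma[lin_g], frac_lin)
    stp_g <- which(shape == "step" & gamma != 0)
    if (length(stp_g))
      mult[stp_g, ] <- 1 + outer(gamma[stp_g], step_on)
    sig <- sigma0 * mult
    if (any(sig <= 0)) stop("residual SD <= 0; check gamma ranges")

    Y <- outer(beta0, rep(1, n)) + outer(beta1, ages^0.25) +
      matrix(rnorm(G * n, 0, sig), G, n)

    add_cat <- function(labels, sd) {
      if (sd <= 0) return(NULL)
      lev <- sort(unique(labels))
      eff <- matrix(rnorm(G * length(lev), 0, sd), G, length(lev))
      eff[, match(labels, lev), drop = FALSE]
    }
    add_num <- function(x, sd) {
      if (sd <= 0) return(NULL)
      outer(rnorm(G, 0, sd), as.numeric(scale(x)))
    }
    for (eff in list(add_cat(meta$batch, cfg$batch_sd),
                     add_cat(meta$sex, cfg$sex_sd),
                     add_cat(meta$race, cfg$race_sd),
                     add_num(meta$pmi, cfg$pmi_sd),
                     add_num(meta$rin, cfg$rin_sd),
                     add_num(meta$ph, cfg$ph_sd)))
      if (!is.null(eff)) Y <- Y + eff

    dimnames(Y) <- list(gene_id, sample_id)
    truth <- data.frame(
      gene_id = gene_id, beta1_true = beta1, gamma_true = gamma,
      trend_shape = ifelse(gamma == 0, "none", shape),
      de = ifelse(beta1 > 0, "up", ifelse(beta1 < 0, "down", "null")),
      dv = ifelse(gamma > 0, "increase",
                  ifelse(gamma < 0, "decrease", "null")),
      stringsAsFactors = FALSE)
    list(expr = Y, meta = meta, truth = truth)
  })
}

#' Simulate a gene-set collection
#'
#' Sets are drawn without replacement within each set; sizes uniform in
#' `size_range`. With `overlap_fraction > 0` that fraction of each set is
#' drawn from a shared core pool, inducing between-set overlap structure.
#'
#' @param n_sets number of sets.
#' @param size_range integer \[min, max\] set sizes.
#' @param universe character vector of gene ids to draw from.
#' @param overlap_fraction fraction of each set drawn from a shared pool.
#' @param seed random seed.
#' @return named list of character vectors (a gene-set collection).
#' @export
simulate_gene_sets <- function(n_sets, size_range, universe,
                               overlap_fraction = 0, seed = NULL) {
  if (max(size_range) > length(universe))
    stop("set size range exceeds universe size")
  if (n_sets == 0) {
    out <- list(); attr(out, "description") <- character(0); return(out)
  }
  with_seed(seed, {
    core <- sample(universe, max(1, ceiling(0.1 * length(universe))))
    sets <- lapply(seq_len(n_sets), function(i) {
      sz <- if (size_range[1] == size_range[2]) size_range[1]
            else sample(seq(size_range[1], size_range[2]), 1)
      n_core <- min(round(overlap_fraction * sz), length(core))
      m <- c(sample(core, n_core),
             sample(setdiff(universe, core), sz - n_core))
      sample(m)
    })
    names(sets) <- sprintf("set%03d", seq_len(n_sets))
    attr(sets, "description") <- setNames(rep("simulated", n_sets), names(sets))
    sets
  })
}
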