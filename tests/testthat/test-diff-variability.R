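# ages with a fixed young/old split used across the grouped tests
grouped_meta <- function(n_young = 10, n_old = 6, n_mid = 0, seed = 1) {
  set.seed(seed)
  fix_meta(c(runif(n_young, 20, 40), runif(n_mid, 41, 59),
             runif(n_old, 60, 80)))
}

test_that("an exact fit gives a degenerate continuous result", {
  meta <- fix_meta(seq(20, 80, length.out = 15))
  m <- fix_expr(rbind(1 + 2 * meta$age^0.25, rnorm(15)))
  res <- dvar_continuous(m, meta)
  expect_true(res$degenerate[1])
  expect_equal(res$dvar_rho[1], 0)
  expect_equal(res$p_value[1], 1)
  expect_false(res$degenerate[2])
})

test_that("reversing the age axis flips the continuous measure's sign", {
  set.seed(41)
  meta <- fix_meta(runif(30, 20, 80))
  m <- fix_expr(matrix(rnorm(150), 5, 30))
  res <- dvar_continuous(m, meta)
  meta_rev <- meta
  meta_rev$age <- 100 - meta$age
  # refit on the reversed ages: the mean model changes, so compare pure
  # rank antisymmetry on fixed residuals instead
  absres <- abs(fit_gene_model(m, meta)$residuals)
  fwd <- apply(absres, 1, function(r) spearman_test(r, meta$age)$estimate)
  rev <- apply(absres, 1, function(r) spearman_test(r, 100 - meta$age)$estimate)
  expect_equal(rev, -fwd, tolerance = 1e-12)
})

test_that("planted linear variance trends are detected as positive", {
  cfg <- simulation_config(n_genes = 200, n_samples = 147, frac_de = 0,
                           frac_dv = 1, frac_dv_increase = 1,
                           gamma_up_range = c(2, 2), trend_shape = "linear",
                           batch_sd = 0, sex_sd = 0, race_sd = 0,
                           pmi_sd = 0, rin_sd = 0, ph_sd = 0, seed = 42)
  sim <- simulate_dataset(cfg)
  res <- dvar_continuous(sim$expr, sim$meta)
  expect_gt(mean(res$dvar_rho > 0), 0.9)
})

test_that("the young-IQR null collapses when the subsample is the group", {
  y <- c(5, 1, 9, 2, 7)
  null <- null_iqr_distribution(y, 5, B = 20, seed = 3)
  expect_true(all(null == iqr(y)))
})

test_that("exhaustive mode enumerates every subset exactly", {
  set.seed(44)
  y <- sample(1:100, 10)
  null <- null_iqr_distribution(y, 4, exhaustive_limit = 300)
  expect_true(attr(null, "exhaustive"))
  expect_length(null, choose(10, 4))
  # independent oracle: bitmask enumeration + direct interpolation IQR
  oracle <- c()
  for (mask in 0:(2^10 - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:9)) > 0)
    if (length(idx) == 4) oracle <- c(oracle, oracle_iqr(y[idx]))
  }
  expect_equal(sort(null), sort(oracle), tolerance = 1e-12)
})

test_that("sampled null is deterministic in the seed", {
  y <- rnorm(30)
  n1 <- null_iqr_distribution(y, 10, B = 50, seed = 5, exhaustive_limit = 10)
  n2 <- null_iqr_distribution(y, 10, B = 50, seed = 5, exhaustive_limit = 10)
  n3 <- null_iqr_distribution(y, 10, B = 50, seed = 6, exhaustive_limit = 10)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
  expect_error(null_iqr_distribution(y, 1), ">= 2")
})

test_that("grouped statistics are exactly location- and scale-invariant", {
  set.seed(45)
  meta <- grouped_meta(12, 8)
  m <- fix_expr(matrix(rnorm(100), 5, 20))
  base <- dvar_grouped(m, meta, B = 200, seed = 9, exhaustive_limit = 0)
  shifted <- dvar_grouped(m + 100, meta, B = 200, seed = 9,
                          exhaustive_limit = 0)
  scaled <- m
  scaled[2, ] <- scaled[2, ] * 7.5
  scl <- dvar_grouped(scaled, meta, B = 200, seed = 9, exhaustive_limit = 0)
  for (col in c("dvar_iqr", "p_empirical")) {
    expect_equal(shifted[[col]], base[[col]], tolerance = 1e-12)
    expect_equal(scl[[col]], base[[col]], tolerance = 1e-12)
  }
})

test_that("continuous statistics are exactly location- and scale-invariant", {
  set.seed(46)
  meta <- fix_meta(runif(30, 20, 80))
  m <- fix_expr(matrix(rnorm(150), 5, 30))
  base <- dvar_continuous(m, meta)
  shifted <- dvar_continuous(m + 50, meta)
  scaled <- dvar_continuous(m * 3, meta)
  expect_equal(shifted$dvar_rho, base$dvar_rho, tolerance = 1e-10)
  expect_equal(scaled$dvar_rho, base$dvar_rho, tolerance = 1e-10)
  expect_equal(scaled$p_value, base$p_value, tolerance = 1e-10)
})

test_that("grouped empirical p in exhaustive mode equals the subset oracle", {
  set.seed(47)
  meta <- grouped_meta(10, 4)
  m <- fix_expr(matrix(rnorm(3 * 14), 3, 14))
  res <- dvar_grouped(m, meta, exhaustive_limit = 500)
  expect_true(attr(res, "exhaustive"))
  young_cols <- which(meta$age <= 40)
  old_cols <- which(meta$age >= 60)
  for (g in 1:3) {
    yv <- m[g, young_cols]
    obs <- oracle_iqr(m[g, old_cols])
    nulls <- combn(yv, 4, oracle_iqr)
    p_or <- min(1, 2 * min(mean(nulls >= obs), mean(nulls <= obs)))
    expect_equal(res$p_empirical[g], p_or, tolerance = 1e-12)
    expect_equal(res$dvar_iqr[g], (obs - mean(nulls)) / mean(nulls),
                 tolerance = 1e-12)
  }
})

test_that("dvar(IQR) equals zero when old IQR matches the null mean, bounded below by -1", {
  set.seed(48)
  meta <- grouped_meta(8, 8)
  m <- fix_expr(matrix(rnorm(80), 5, 16))
  res <- dvar_grouped(m, meta, B = 300, seed = 2, exhaustive_limit = 0)
  expect_true(all(res$dvar_iqr >= -1))
  # synthetic check of the formula identity
  expect_equal((2.5 - 2.5) / 2.5, 0)
  manual <- (res$iqr_old - res$iqr_young_mean) / res$iqr_young_mean
  expect_equal(res$dvar_iqr, manual, tolerance = 1e-12)
})

test_that("step heteroscedasticity with doubled SD yields mean dvar near 1", {
  cfg <- simulation_config(n_genes = 300, n_samples = 147, frac_de = 0,
                           frac_dv = 1, frac_dv_increase = 1,
                           gamma_up_range = c(1, 1), trend_shape = "step",
                           batch_sd = 0, sex_sd = 0, race_sd = 0,
                           pmi_sd = 0, rin_sd = 0, ph_sd = 0, seed = 49)
  sim <- simulate_dataset(cfg)
  res <- dvar_grouped(sim$expr, sim$meta, B = 300, seed = 50)
  expect_lt(abs(mean(res$dvar_iqr) - 1), 0.2)
})

test_that("degenerate genes (zero young IQR) are excluded from FDR", {
  meta <- grouped_meta(8, 6)
  m <- fix_expr(rbind(rep(3, 14), rnorm(14)))
  expect_message(res <- dvar_grouped(m, meta, B = 100, seed = 1,
                                     exhaustive_limit = 0), "excluded")
  expect_true(res$degenerate[1])
  expect_true(is.na(res$q_value[1]))
  expect_false(is.na(res$q_value[2]))
})

test_that("middle-aged samples do not influence the grouped statistic", {
  set.seed(51)
  meta <- grouped_meta(10, 6, n_mid = 5)
  m <- fix_expr(matrix(rnorm(105), 5, 21))
  base <- dvar_grouped(m, meta, B = 100, seed = 4, exhaustive_limit = 0)
  m2 <- m
  mid <- which(meta$age > 40 & meta$age < 60)
  m2[, mid] <- m2[, mid] + matrix(rnorm(5 * length(mid), 0, 10), 5)
  pert <- dvar_grouped(m2, meta, B = 100, seed = 4, exhaustive_limit = 0)
  expect_equal(pert$dvar_iqr, base$dvar_iqr, tolerance = 1e-12)
  expect_equal(pert$p_empirical, base$p_empirical, tolerance = 1e-12)
})

test_that("dv_classify summarizes direction, shift and labels", {
  res <- data.frame(gene_id = sprintf("g%d", 1:6),
                    dvar_iqr = c(0.5, -0.4, 0.3, 0.1, -0.2, 0.6),
                    q_value = c(0.01, 0.02, 0.5, 0.9, 0.04, 0.05))
  cls <- dv_classify(res, 0.05)
  # inclusive q <= 0.05: g1, g6 increase; g2, g5 decrease; g3, g4 null
  expect_equal(unname(cls$counts), c(2, 2, 2))
  expect_equal(cls$summary$fraction_positive, 4 / 6)
  expect_equal(cls$summary$median_dvar, median(res$dvar_iqr))
  zeros <- data.frame(gene_id = "a", dvar_rho = 0, q_value = 1)
  expect_message(z <- dv_classify(zeros), "zero")
  expect_true(z$summary$all_zero)
  expect_equal(z$summary$fraction_positive, 0)
})

test_that("a planted 2:1 increase:decrease mixture shows in significant calls", {
  cfg <- simulation_config(n_genes = 600, n_samples = 147, frac_de = 0,
                           frac_dv = 0.5, frac_dv_increase = 2 / 3,
                           gamma_up_range = c(2, 3),
                           gamma_down_range = c(-0.75, -0.6),
                           trend_shape = "step", batch_sd = 0, sex_sd = 0,
                           race_sd = 0, pmi_sd = 0, rin_sd = 0, ph_sd = 0,
                           seed = 52)
  sim <- simulate_dataset(cfg)
  res <- dvar_grouped(sim$expr, sim$meta, B = 500, seed = 53)
  cls <- dv_classify(res, 0.05)
  ratio <- cls$counts[["increase"]] / cls$counts[["decrease"]]
  expect_gt(cls$counts[["decrease"]], 10)
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.5)
})
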