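test_that("age filter is inclusive at both bounds", {
  m <- fix_expr(matrix(1:10, 2, 5))
  meta <- fix_meta(c(5, 20, 45, 80, 91))
  out <- filter_age(m, meta)
  expect_equal(out$meta$age, c(20, 45, 80))
  expect_equal(ncol(out$expr), 3)
  in_range <- filter_age(m, fix_meta(c(21, 30, 40, 60, 79)))
  expect_identical(in_range$expr, m)
  expect_error(filter_age(m, fix_meta(c(1, 2, 3, 4, 5))), "no samples")
})

test_that("probe summarization drops multi-gene probes and averages", {
  pe <- fix_expr(rbind(p1 = c(2, 4), p2 = c(4, 8), p3 = c(100, 100)),
                 genes = c("p1", "p2", "p3"))
  pmap <- data.frame(probe_id = c("p1", "p2", "p3", "p3"),
                     gene_id = c("g1", "g1", "g1", "g2"))
  out <- summarize_probes(pe, pmap)
  expect_equal(rownames(out), "g1")
  expect_equal(unname(out["g1", ]), c(3, 6))
  # one-to-one map renames rows, keeps values
  pmap2 <- data.frame(probe_id = c("p1", "p2", "p3"),
                      gene_id = c("gA", "gB", "gC"))
  out2 <- summarize_probes(pe, pmap2)
  expect_equal(unname(out2[c("gA", "gB", "gC"), ]), unname(pe))
  expect_error(summarize_probes(pe, pmap2[1:2, ]), "absent")
})

test_that("quantile normalization matches the hand-computed reference", {
  m <- fix_expr(cbind(c(2, 4, 6), c(1, 5, 9)))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(1.5, 4.5, 7.5))
  expect_equal(unname(out[, 2]), c(1.5, 4.5, 7.5))
})

test_that("quantile normalization: equal distributions unchanged, single column unchanged", {
  m <- fix_expr(cbind(c(3, 1, 2), c(1, 2, 3)))
  out <- quantile_normalize(m)
  expect_equal(out, m)
  one <- fix_expr(matrix(c(5, 1, 3), 3, 1))
  expect_identical(quantile_normalize(one), one)
})

test_that("quantile normalization is idempotent and equalizes sorted columns", {
  set.seed(1)
  m <- fix_expr(matrix(rnorm(300), 30, 10))
  q1 <- quantile_normalize(m)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  sorted <- apply(q1, 2, sort)
  expect_true(max(abs(sorted - sorted[, 1])) < 1e-12)
  expect_equal(sum(q1), sum(m), tolerance = 1e-8)
})

test_that("quantile normalization agrees with the limma reference on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(2)
  m <- fix_expr(matrix(rnorm(200), 20, 10))
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-10)
})

test_that("quantile normalization averages reference values across ties", {
  m <- fix_expr(cbind(c(1, 1, 5), c(2, 4, 6)))
  out <- quantile_normalize(m)
  ref <- rowMeans(cbind(sort(m[, 1]), sort(m[, 2])))
  expect_equal(unname(out[1:2, 1]), rep(mean(ref[1:2]), 2))
  expect_equal(unname(out[3, 1]), unname(ref[3]))
})

test_that("covariate correction handles the empty and exact-fit cases", {
  m <- fix_expr(matrix(rnorm(40), 4, 10))
  meta <- fix_meta(runif(10, 20, 80), pmi = runif(10, 5, 40))
  expect_identical(correct_covariates(m, meta, character()), m)
  centered <- correct_covariates(m, meta, character(), keep_intercept = FALSE)
  expect_equal(rowMeans(centered), setNames(rep(0, 4), rownames(m)),
               tolerance = 1e-12)
  # expression exactly linear in PMI -> residuals zero (+ intercept if kept)
  lin <- fix_expr(rbind(2 + 3 * meta$pmi, -1 + 0.5 * meta$pmi))
  res <- correct_covariates(lin, meta, "pmi", keep_intercept = FALSE)
  expect_equal(max(abs(res)), 0, tolerance = 1e-9)
  res2 <- correct_covariates(lin, meta, "pmi", keep_intercept = TRUE)
  expect_equal(unname(res2[, 1]), c(2, -1), tolerance = 1e-9)
})

test_that("covariate correction removes planted batch structure", {
  cfg <- simulation_config(n_genes = 100, n_samples = 147, frac_de = 0,
                           frac_dv = 0, batch_sd = 1, sex_sd = 0, race_sd = 0,
                           pmi_sd = 0, rin_sd = 0, ph_sd = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  batch_spread <- function(m) {
    mean(apply(m, 1, function(x)
      var(tapply(x, sim$meta$batch, mean))))
  }
  before <- batch_spread(sim$expr)
  after <- batch_spread(correct_covariates(sim$expr, sim$meta, "batch"))
  expect_gt(before, 0.5)     # planted scale 1 across 19 batches
  expect_lt(after, before / 20)
})

test_that("residuals are orthogonal to every design column, order-invariant", {
  set.seed(3)
  meta <- fix_meta(runif(30, 20, 80), sex = sample(c("F", "M"), 30, TRUE),
                   pmi = runif(30, 5, 40))
  m <- fix_expr(matrix(rnorm(150), 5, 30))
  res <- correct_covariates(m, meta, c("sex", "pmi"), keep_intercept = FALSE)
  X <- model.matrix(~ factor(meta$sex) + meta$pmi)
  expect_lt(max(abs(res %*% X)), 1e-8)
  res_swapped <- correct_covariates(m, meta, c("pmi", "sex"),
                                    keep_intercept = FALSE)
  expect_equal(res, res_swapped, tolerance = 1e-10)
})

test_that("degenerate designs error with named columns", {
  meta <- fix_meta(runif(10, 20, 80), sex = rep("F", 10),
                   pmi = runif(10), pmi2 = NA)
  meta$pmi2 <- 2 * meta$pmi
  m <- fix_expr(matrix(rnorm(20), 2, 10))
  expect_error(correct_covariates(m, meta, "sex"), "single level")
  expect_error(correct_covariates(m, meta, c("pmi", "pmi2")), "pmi2")
})
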