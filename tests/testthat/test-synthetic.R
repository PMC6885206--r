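test_that("cohort dimensions, ids and label counts match the configuration", {
  cfg <- synthetic_config(n_samples = 450, n_genes = 2000,
                          n_signature_genes = 3, minority_fraction = 0.045,
                          shift = 2.0, true_log_hr = log(4.86), seed = 1)
  coh <- generate_cohort(cfg)
  expect_identical(dim(coh$expression), c(2000L, 450L))
  # binomial(450, 0.045): mean 20.25, sd 4.40; [12, 29] is the frozen
  # 2-SD band, comfortably inside the generator's 3-SD invariant
  expect_gte(sum(coh$true_labels), 12)
  expect_lte(sum(coh$true_labels), 29)
  expect_identical(colnames(coh$expression), coh$survival$sample)
  expect_false(anyDuplicated(coh$survival$sample) > 0)
  expect_true(all(coh$survival$time >= 0))
})

test_that("no planted effect means null two-sample t statistics", {
  coh <- generate_cohort(synthetic_config(n_genes = 400, shift = 0, seed = 3))
  g1 <- coh$true_labels == 1
  tstat <- apply(coh$expression, 1, function(x)
    t.test(x[g1], x[!g1])$statistic)
  expect_lt(abs(mean(tstat)), 0.15)
  expect_lt(abs(mean(abs(tstat) > 2) - 0.05), 0.05)
})

test_that("censoring switches behave as configured", {
  coh <- generate_cohort(synthetic_config(n_genes = 5, n_signature_genes = 3,
                                          censor_rate = 0, seed = 2))
  expect_true(all(coh$survival$event == 1))
})

test_that("identical config and seed reproduce bit-identical cohorts", {
  cfg <- synthetic_config(n_genes = 100, seed = 17)
  a <- generate_cohort(cfg); b <- generate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$survival, b$survival)
  p1 <- generate_paired_cohorts(cfg, synthetic_config(n_samples = 107,
                                                      n_genes = 100, seed = 18))
  p2 <- generate_paired_cohorts(cfg, synthetic_config(n_samples = 107,
                                                      n_genes = 100, seed = 18))
  expect_identical(p1$valid$expression, p2$valid$expression)
})

test_that("planted minority fraction is recovered in expectation", {
  fr <- vapply(1:100, function(s) {
    coh <- generate_cohort(synthetic_config(n_samples = 450, n_genes = 2,
                                            n_signature_genes = 2,
                                            seed = 7000 + s))
    mean(coh$true_labels)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.045), 0.005)
})

test_that("empirical hazard ratio approaches the configured truth", {
  coh <- generate_cohort(synthetic_config(n_samples = 5000, n_genes = 2,
                                          n_signature_genes = 2,
                                          censor_rate = 0, seed = 99))
  s <- coh$survival; g <- coh$true_labels
  hr_emp <- (sum(s$event[g == 1]) / sum(s$time[g == 1])) /
    (sum(s$event[g == 0]) / sum(s$time[g == 0]))
  expect_lt(abs(hr_emp / 4.86 - 1), 0.15)
})

test_that("paired cohorts share generating parameters and record batch truth", {
  ct <- synthetic_config(n_samples = 450, n_genes = 300, seed = 21)
  cv <- synthetic_config(n_samples = 107, n_genes = 300,
                         batch_gamma_sd = 0, batch_delta_shape = 0, seed = 22)
  pair <- generate_paired_cohorts(ct, cv)
  expect_identical(ncol(pair$train$expression), 450L)
  expect_identical(ncol(pair$valid$expression), 107L)
  # null batch effect: per-gene means agree within sampling error
  dm <- rowMeans(pair$valid$expression) - rowMeans(pair$train$expression)
  expect_lt(mean(abs(dm)), 3 * 0.5 / sqrt(107))
  expect_true(all(pair$valid$true_params$batch_gamma == 0))
  expect_true(all(pair$valid$true_params$batch_delta2 == 1))
  # with batch effects on, the truth is recorded and non-trivial
  cv2 <- synthetic_config(n_samples = 107, n_genes = 300, seed = 22)
  pair2 <- generate_paired_cohorts(ct, cv2)
  expect_gt(sd(pair2$valid$true_params$batch_gamma), 0.3)
  expect_gt(var(pair2$valid$true_params$batch_delta2), 0)
})

test_that("unfittable configurations are refused", {
  expect_error(synthetic_config(minority_fraction = 0.6), "minority_fraction")
  expect_error(synthetic_config(n_samples = 20, minority_fraction = 0.05),
               "unfittable")
  expect_error(synthetic_config(n_genes = 2, n_signature_genes = 3),
               "exceeds")
})

test_that("cohorts round-trip through the TSV writers", {
  coh <- generate_cohort(synthetic_config(n_genes = 20, n_samples = 30,
                                          minority_fraction = 0.2, seed = 5))
  paths <- write_cohort(coh, file.path(tempdir(), "coh"))
  back <- read_expression(paths[1])
  expect_equal(back, coh$expression, tolerance = 1e-12)
  surv <- read_survival(paths[2])
  expect_equal(surv$time, coh$survival$time, tolerance = 1e-12)
  expect_identical(surv$sample, coh$survival$sample)
})
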