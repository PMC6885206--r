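sig_cohort <- function(seed = 11) {
  generate_cohort(synthetic_config(n_genes = 50, seed = seed))
}

test_that("signature fit isolates the adverse minority at cohort scale", {
  coh <- sig_cohort()
  sig <- fit_signature(coh$expression, coh$survival,
                       genes = coh$signature_genes)
  expect_gte(sig$train$adverse_fraction, 0.03)
  expect_lte(sig$train$adverse_fraction, 0.08)
  expect_gt(sig$train$cox$hr, 2)
  expect_lt(sig$train$cox$p, 1e-3)
  # adverse calls line up with the planted minority
  lab <- sig$train$assignment$adverse
  expect_gt(mean(coh$true_labels[lab == 1] == 1), 0.9)
  expect_identical(nrow(sig$bic_table), 6L)
})

test_that("applying the model to its training matrix reproduces training labels", {
  coh <- sig_cohort(12)
  sig <- fit_signature(coh$expression, coh$survival,
                       genes = coh$signature_genes)
  a <- apply_signature(sig, coh$expression)
  expect_identical(a$adverse, sig$train$assignment$adverse)
  expect_equal(a$adverse_posterior, sig$train$assignment$adverse_posterior,
               tolerance = 1e-12)
  expect_error(apply_signature(sig, coh$expression[-1, , drop = FALSE]),
               "missing")
})

test_that("a sample equidistant between symmetric components is borderline", {
  pm <- structure(list(K = 2L, d = 2L, family = "EII", pro = c(.5, .5),
                       mean = cbind(c(0, 0), c(4, 4)), lambda = 1,
                       shape = c(1, 1), sigma2 = matrix(1, 2, 2),
                       loglik = 0, n_params = 7, n = 10, bic = 0,
                       converged = TRUE), class = "gmm")
  model <- structure(list(genes = c("gA", "gB"), mixture = pm,
                          adverse_cluster = 2L), class = "clustsig_model")
  x <- matrix(c(2, 2), 2, 1, dimnames = list(c("gA", "gB"), "mid"))
  a <- predict(model, x)
  expect_equal(a$adverse_posterior, 0.5, tolerance = 1e-12)
  expect_true(a$borderline)
  expect_identical(a$adverse, 0L)              # hard call requires > 0.5
})

test_that("serialization round-trips predictions exactly", {
  coh <- sig_cohort(13)
  sig <- fit_signature(coh$expression, coh$survival,
                       genes = coh$signature_genes)
  path <- tempfile(fileext = ".json")
  write_signature(sig, path)
  back <- read_signature(path)
  a1 <- apply_signature(sig, coh$expression)
  a2 <- apply_signature(back, coh$expression)
  expect_equal(a2$adverse_posterior, a1$adverse_posterior, tolerance = 1e-12)
  expect_identical(a2$adverse, a1$adverse)
  expect_identical(back$genes, sig$genes)
})

test_that("identical components trigger the adverse-tie fallback", {
  # two clean expression clusters with literally mirrored survival
  expr <- rbind(gA = c(rep(0, 4), rep(10, 4)),
                gB = c(rep(0, 4), rep(10, 4)))
  expr <- expr + matrix(rnorm(16, sd = 0.05), 2, 8)
  colnames(expr) <- paste0("s", 1:8)
  surv <- data.frame(sample = paste0("s", 1:8),
                     time = rep(c(1, 2, 3, 4), 2),
                     event = rep(c(1, 1, 0, 1), 2))
  expect_warning(
    sig <- fit_signature(expr, surv, families = "EII", restarts = 1L),
    "identical observed hazard")
  expect_identical(sig$adverse_cluster, 1L)
})

test_that("covariate adjustment reduces to and attenuates as expected", {
  coh <- sig_cohort(14)
  lab <- coh$true_labels
  un <- fit_cox(coh$survival, cbind(cluster = lab))
  adj0 <- adjusted_cox(coh$survival, lab, covariates = NULL)
  expect_equal(adj0$beta, un$beta, tolerance = 1e-10)
  # covariates independent of both cluster and hazard barely move the HR
  set.seed(3)
  noise <- data.frame(age = rnorm(450), stage = rbinom(450, 1, 0.4))
  adj1 <- adjusted_cox(coh$survival, lab, covariates = noise)
  expect_lt(abs(adj1$beta[1] - un$beta), 0.25)
  # a confounder correlated with cluster and hazard attenuates the effect
  set.seed(4)
  conf_cfg <- synthetic_config(
    n_genes = 10, seed = 15,
    covariate_spec = list(list(name = "tp53", prevalence = 0.15,
                               log_hr = 1.0)))
  coh2 <- generate_cohort(conf_cfg)
  conf <- as.integer(coh2$true_labels | (runif(450) < 0.10))
  surv2 <- coh2$survival
  surv2$time <- surv2$time * exp(-0.8 * conf)    # confounder shortens survival
  un2 <- fit_cox(surv2, cbind(cluster = coh2$true_labels))
  adj2 <- adjusted_cox(surv2, coh2$true_labels,
                       covariates = data.frame(conf = conf))
  expect_lt(adj2$beta[1], un2$beta[1])
  expect_error(adjusted_cox(surv2, coh2$true_labels,
                            covariates = data.frame(a = conf, b = conf)),
               "collinear")
})

test_that("sensitivity refits exclude named samples and keep bookkeeping", {
  coh <- sig_cohort(16)
  sig <- fit_signature(coh$expression, coh$survival,
                       genes = coh$signature_genes)
  a <- sig$train$assignment
  s0 <- sensitivity_drop(coh$survival, a, character(0))
  expect_equal(s0$full$beta, s0$dropped$beta, tolerance = 1e-10)
  # dropping one borderline-ish adverse sample moves the HR by < 2x
  adverse_ids <- a$sample[a$adverse == 1]
  worst <- adverse_ids[which.max(a$uncertainty[a$adverse == 1])]
  s1 <- sensitivity_drop(coh$survival, a, worst)
  expect_lt(abs(log(s1$dropped$hr) - log(s1$full$hr)), log(2))
  # dropping a non-adverse sample just rescales the fraction
  keep_id <- a$sample[a$adverse == 0][1]
  s2 <- sensitivity_drop(coh$survival, a, keep_id)
  expect_equal(s2$adverse_fraction, sum(a$adverse) / (nrow(a) - 1))
  expect_error(sensitivity_drop(coh$survival, a, adverse_ids), "all adverse")
  expect_error(sensitivity_drop(coh$survival, a, "nope"), "unknown sample")
})
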