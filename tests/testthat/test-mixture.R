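test_that("two well-separated tied groups recover the obvious split", {
  x <- c(0, 0, 0, 10, 10, 10)
  expect_warning(fit <- fit_mixture(x, K = 2, family = "E"),
                 "variance floor")
  expect_equal(sort(drop(fit$mean)), c(0, 10), tolerance = 1e-8)
  expect_equal(fit$pro, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(sort(tabulate(fit$classification, 2)), c(3L, 3L))
  expect_true(fit$degenerate)
})

test_that("single-component fit is the closed-form Gaussian MLE", {
  set.seed(4)
  x <- matrix(rnorm(60), ncol = 3)
  fit <- fit_mixture(x, K = 1, family = "VVI")
  expect_equal(drop(fit$mean), colMeans(x))
  # family-projected covariance: diagonal of the MLE (1/n) covariance
  expect_equal(drop(fit$sigma2), apply(x, 2, function(v) mean((v - mean(v))^2)))
  # loglik equals the direct Gaussian evaluation
  ll <- sum(vapply(1:3, function(j)
    sum(dnorm(x[, j], mean(x[, j]), sqrt(mean((x[, j] - mean(x[, j]))^2)),
              log = TRUE)), numeric(1)))
  expect_equal(fit$loglik, ll, tolerance = 1e-10)
})

test_that("BIC follows the 2*loglik - m*log(n) convention", {
  fit <- fit_mixture(matrix(c(0, 1), ncol = 1), K = 1, family = "E")
  # closed form: unit-variance-free Gaussian MLE on {0,1}: mu=.5, s2=.25
  ll <- sum(dnorm(c(0, 1), 0.5, 0.5, log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-10)
  expect_equal(ll, -1.45158, tolerance = 1e-5)
  expect_equal(bic(fit), 2 * ll - 2 * log(2), tolerance = 1e-10)
  expect_equal(bic(fit), -4.28945, tolerance = 1e-4)
  expect_identical(bic(fit), fit$bic)
})

test_that("VEI parameter recovery on simulated d=2 truth", {
  set.seed(42)
  n <- 2000
  lam_true <- c(1, 4); A_true <- c(2, 0.5)
  k <- rbinom(n, 1, 0.5) + 1
  x <- t(vapply(seq_len(n), function(i)
    rnorm(2, if (k[i] == 2) c(4, 4) else c(0, 0),
          sqrt(lam_true[k[i]] * A_true)), numeric(2)))
  fit <- fit_mixture(x, K = 2, family = "VEI")
  lam <- sort(fit$lambda)
  expect_lt(max(abs(lam - lam_true) / lam_true), 0.15)
  A <- fit$shape
  if (A[1] < A[2]) A <- rev(A)
  expect_lt(max(abs(A - A_true) / A_true), 0.10)
  expect_equal(prod(fit$shape), 1, tolerance = 1e-8)
})

test_that("every family satisfies its covariance constraint exactly", {
  set.seed(9)
  x <- rbind(matrix(rnorm(300, 0, 1), ncol = 3),
             matrix(rnorm(300, 3, 2), ncol = 3))
  for (fam in c("EII", "VII", "EEI", "VEI", "EVI", "VVI")) {
    fit <- fit_mixture(x, K = 2, family = fam)
    s2 <- fit$sigma2
    lam <- rep(fit$lambda, length.out = 2)
    if (fam %in% c("EII", "VII")) {
      # spherical: all dimensions identical within component
      expect_equal(s2[1, ], s2[2, ], info = fam)
      expect_equal(s2[2, ], s2[3, ], info = fam)
    }
    if (fam %in% c("EII", "EEI", "EVI")) {
      expect_length(fit$lambda, 1L)         # single shared volume
    }
    if (fam %in% c("EEI", "VEI")) {
      # shared shape vector of determinant 1, stored once for all components
      expect_equal(prod(fit$shape), 1, tolerance = 1e-8, info = fam)
      expect_equal(s2[, 1] / lam[1], fit$shape, tolerance = 1e-12, info = fam)
      expect_equal(s2[, 2] / lam[2], fit$shape, tolerance = 1e-12, info = fam)
    }
    if (fam %in% c("EVI", "VVI")) {
      expect_equal(apply(fit$shape, 2, prod), c(1, 1), tolerance = 1e-8,
                   info = fam)
    }
    # per-component covariance reconstructs from volume x shape
    shp <- if (is.matrix(fit$shape)) fit$shape else
      matrix(rep(fit$shape, length.out = 3), nrow = 3, ncol = 2)
    expect_equal(s2, shp %*% diag(lam), tolerance = 1e-12, info = fam)
    expect_equal(fit$n_params,
                 switch(fam, EII = 8L, VII = 9L, EEI = 10L, VEI = 11L,
                        EVI = 12L, VVI = 13L), info = fam)
  }
})

test_that("EM log-likelihood is non-decreasing for every family", {
  set.seed(21)
  x1 <- c(rnorm(80), rnorm(40, 3))
  x3 <- rbind(matrix(rnorm(240), ncol = 3), matrix(rnorm(120, 2), ncol = 3))
  for (fam in c("E", "V"))
    expect_true(all(diff(fit_mixture(x1, 2, fam)$loglik_trace) >= -1e-9),
                info = fam)
  for (fam in c("EII", "VII", "EEI", "VEI", "EVI", "VVI"))
    expect_true(all(diff(fit_mixture(x3, 2, fam)$loglik_trace) >= -1e-9),
                info = fam)
})

test_that("EM matches the exhaustive-partition oracle on tiny data", {
  set.seed(11)
  cases <- c(lapply(1:6, function(i) rnorm(sample(4:8, 1))),
             list(c(0.1, 0.2, 5.1, 5.3), c(-1, 0, 1, 9, 10, 11, 12)))
  for (x in cases) {
    for (fam in c("E", "V")) {
      oracle <- oracle_partition_loglik(x, fam)
      fit <- tryCatch(
        suppressWarnings(fit_mixture(x, 2, fam, nstart = 10)),
        error = function(e) NULL)
      if (is.null(fit) || fit$degenerate) next
      expect_gte(fit$loglik, oracle - 1e-6)
    }
  }
})

test_that("VVI fit agrees with the reference implementation", {
  library(mclust)
  set.seed(33)
  x <- rbind(matrix(rnorm(600, 0, 1), ncol = 3),
             matrix(rnorm(300, 4, 2), ncol = 3))
  ours <- fit_mixture(x, 2, "VVI")
  ref <- Mclust(x, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-4)
  expect_equal(ours$n_params, as.integer(nMclustParams("VVI", d = 3, G = 2)))
})

test_that("select_model picks by BIC and breaks ties toward parsimony", {
  set.seed(14)
  x <- rbind(matrix(rnorm(200), ncol = 2), matrix(rnorm(200, 4), ncol = 2))
  only <- select_model(x, 2, families = "EII")
  expect_identical(only$family, "EII")
  full <- select_model(x, 2)
  expect_identical(full$family, full$bic_table$family[1])
  expect_equal(nrow(full$bic_table), 6L)
  expect_true(all(diff(full$bic_table$bic) <= 1e-12))
  # equal-spread bimodal univariate data: E should beat V most of the time
  wins <- vapply(1:20, function(s) {
    set.seed(100 + s)
    y <- c(rnorm(250, 0, 1), rnorm(250, 4, 1))
    select_model(y, 2)$family
  }, "")
  expect_gt(mean(wins == "E"), 0.5)
})

test_that("posterior prediction is the frozen-parameter Bayes rule", {
  m <- fit_mixture(c(rnorm(50), rnorm(50, 10)), 2, "E")
  # symmetric midpoint between equal-variance components -> 0.5 each
  mid <- mean(m$mean)
  pr <- predict(m, mid)
  expect_equal(drop(pr$z), c(0.5, 0.5), tolerance = 1e-6)
  # logistic closed form for an equal-variance 2-GMM with unit variance
  pm <- structure(list(K = 2L, d = 1L, family = "E", pro = c(.5, .5),
                       mean = matrix(c(0, 10), 1, 2), lambda = 1, shape = 1,
                       sigma2 = matrix(1, 1, 2), loglik = 0, n_params = 4,
                       n = 2, bic = 0, converged = TRUE), class = "gmm")
  expect_equal(predict(pm, 0)$z[1, 1], 1 / (1 + exp(-50)), tolerance = 1e-12)
  # predicting training data reproduces converged responsibilities
  x <- c(rnorm(40), rnorm(40, 6))
  f <- fit_mixture(x, 2, "V")
  expect_equal(predict(f, x)$z, f$z, tolerance = 1e-12)
  expect_error(predict(f, matrix(1, 2, 2)), "dimension")
})

test_that("degenerate and invalid inputs are refused", {
  expect_error(fit_mixture(rep(1, 20), 2, "E"), "degenerate")
  expect_error(fit_mixture(rnorm(3), 4, "V"), "more observations")
  expect_error(fit_mixture(rnorm(10), 2, "EII"), "invalid for dimension")
  expect_error(fit_mixture(matrix(rnorm(20), ncol = 2), 2, "E"),
               "invalid for dimension")
  expect_error(fit_mixture(c(rnorm(5), NA), 2, "E"), "missing")
  expect_error(select_model(rnorm(10), 2, families = character(0)), "empty")
})
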