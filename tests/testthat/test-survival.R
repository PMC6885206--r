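test_that("Cox fit matches a 1-D grid-search oracle on the worked example", {
  surv <- data.frame(time = c(2, 4, 6, 8), event = c(1, 1, 1, 0))
  x <- matrix(c(1, 0, 1, 0), ncol = 1)
  fit <- fit_cox(surv, x, ties = "breslow")
  # Breslow partial log-likelihood of this dataset, maximized on a grid
  pl <- function(b) (b - log(2 * exp(b) + 2)) + (-log(exp(b) + 2)) +
    (b - log(exp(b) + 1))
  grid <- seq(-5, 5, by = 1e-4)
  b_oracle <- grid[which.max(pl(grid))]
  expect_equal(unname(fit$beta), b_oracle, tolerance = 1e-3)
  expect_equal(fit$hr, exp(fit$beta), tolerance = 0)
  expect_equal(fit$loglik, unname(pl(fit$beta)), tolerance = 1e-8)
  expect_lt(fit$ci_low, fit$hr); expect_gt(fit$ci_high, fit$hr)
  expect_equal(fit$n_events, 3L)
})

test_that("Breslow and Efron coincide without tied event times", {
  set.seed(5)
  n <- 80
  surv <- data.frame(time = rexp(n), event = rbinom(n, 1, 0.7))
  x <- cbind(a = rnorm(n), b = as.numeric(rbinom(n, 1, 0.4)))
  fb <- fit_cox(surv, x, ties = "breslow")
  fe <- fit_cox(surv, x, ties = "efron")
  expect_equal(fb$beta, fe$beta, tolerance = 1e-10)
  # score at the returned estimate is (numerically) zero
  expect_lt(sqrt(sum(cox_score(fb$beta, surv$time, surv$event, x)^2)), 1e-6)
})

test_that("null covariates give unbiased beta and uniform-ish p", {
  set.seed(6)
  reps <- 300
  out <- t(vapply(seq_len(reps), function(i) {
    n <- 60
    surv <- data.frame(time = rexp(n, 0.2), event = rbinom(n, 1, 0.8))
    x <- cbind(rnorm(n))
    f <- fit_cox(surv, x)
    c(f$beta, f$p)
  }, numeric(2)))
  expect_lt(abs(mean(out[, 1])), 0.05)
  expect_lt(abs(mean(out[, 2] < 0.05) - 0.05), 0.035)  # type-I error near nominal
})

test_that("monotone likelihood is flagged, not silently diverged", {
  # all events in group 1 strictly precede every group-0 time
  surv <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                     event = c(1, 1, 1, 0, 0, 0))
  x <- matrix(c(1, 1, 1, 0, 0, 0), ncol = 1)
  expect_warning(fit <- fit_cox(surv, x), "monotone|diverge")
  expect_true(any(fit$infinite))
})

test_that("degenerate Cox inputs error early", {
  surv <- data.frame(time = c(1, 2, 3), event = c(0, 0, 0))
  expect_error(fit_cox(surv, matrix(c(1, 0, 1), ncol = 1)), "zero events")
  surv$event <- c(1, 1, 0)
  expect_error(fit_cox(surv, matrix(1, 3, 1)), "constant")
  surv$event <- c(1, 2, 0)
  expect_error(fit_cox(surv, matrix(c(1, 0, 1), ncol = 1)), "0/1")
})

test_that("Kaplan-Meier estimates match the hand product-limit", {
  km <- km_estimate(data.frame(time = c(1, 2), event = c(1, 1)))
  expect_equal(km$survival, c(0.5, 0))
  # all censored: survival never drops
  km2 <- km_estimate(data.frame(time = 1:4, event = rep(0, 4)))
  expect_true(all(km2$survival == 1))
  # censoring between events removes the subject from later risk sets:
  # S(1) = 2/3, then the sole remaining subject dies at 3 -> S(3) = 0
  km3 <- km_estimate(data.frame(time = c(1, 2, 3), event = c(1, 0, 1)))
  expect_equal(km3$survival[km3$time == 1], 2 / 3)
  expect_equal(km3$survival[km3$time == 3], 0)
  expect_true(all(diff(km3$survival) <= 0))
})

test_that("without censoring KM equals the empirical survival function", {
  set.seed(8)
  tt <- rexp(40)
  km <- km_estimate(data.frame(time = tt, event = rep(1, 40)))
  emp <- vapply(km$time, function(s) mean(tt > s), numeric(1))
  expect_equal(km$survival, emp, tolerance = 1e-12)
})

test_that("km_estimate handles groups and refuses empty ones", {
  surv <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1))
  km <- km_estimate(surv, groups = c("a", "a", "b", "b"))
  expect_setequal(unique(km$group), c("a", "b"))
  expect_equal(km$survival[km$group == "a"], c(0.5, 0))
  expect_error(km_estimate(surv, groups = c("a", "a", NA, "b")), "missing")
  expect_error(km_estimate(surv, groups = c("a", "a")), "length")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.04, 0.5, 1.0)), c(0.12, 0.75, 1.0))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(10)
  for (i in 1:10) {
    p <- runif(sample(2:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_by_hand(p), tolerance = 1e-12)
    expect_true(all(q[order(p)] == cummax(q[order(p)]))) # order-preserving
  }
})
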