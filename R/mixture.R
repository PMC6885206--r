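#' Gaussian mixtures with geometric covariance parameterizations
#'
#' `fit_mixture()` fits a K-component Gaussian mixture by
#' expectation-maximization under one of the spherical/diagonal covariance
#' parameterizations used in model-based clustering. Each component
#' covariance is decomposed as \eqn{\Sigma_k = \lambda_k A_k} with
#' \eqn{\lambda_k > 0} a volume scalar and \eqn{A_k} a diagonal shape matrix
#' of determinant 1; the family code fixes which pieces are shared across
#' components:
#'
#' * `"E"` / `"V"` — univariate, equal / varying variance;
#' * `"EII"` / `"VII"` — spherical, equal / varying volume;
#' * `"EEI"` — diagonal, equal volume and shape;
#' * `"VEI"` — diagonal, varying volume, equal shape;
#' * `"EVI"` — diagonal, equal volume, varying shape;
#' * `"VVI"` — diagonal, varying volume and shape.
#'
#' Ellipsoidal (rotated) families are deliberately not fitted: the
#' diagonal families cover the univariate per-gene screen and the
#' multivariate signature model, and form a natural extension point.
#'
#' Initialization is deterministic by default: a hard K-group partition
#' from agglomerative Ward clustering of the data, so repeated fits of the
#' same data are identical without any seed. Additional seeded k-means
#' starts can be requested with `nstart`; the best log-likelihood wins.
#'
#' @param x numeric matrix (samples in rows) or vector; a vector or
#'   single-column matrix selects the univariate families.
#' @param K number of mixture components.
#' @param family covariance family code (see Details). Must be `"E"` or
#'   `"V"` for univariate data, one of the four-letter codes otherwise.
#' @param init initialization strategy: `"ward"` (deterministic,
#'   default) or `"kmeans"` (seeded).
#' @param nstart number of additional seeded k-means starts beyond the
#'   deterministic one.
#' @param seed integer seed for the k-means starts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param restarts how many fresh initializations to attempt when a
#'   component collapses or a variance hits the floor.
#' @param init_partition optional integer vector of starting hard labels
#'   in `1:K` (one per row); overrides `init`. Used by [select_model()]
#'   to share one deterministic initialization across families.
#'
#' @return An object of class `"gmm"`: a list with elements `K`, `d`,
#'   `family`, `pro` (mixing weights), `mean` (d x K), `lambda` (volume,
#'   scalar or length K), `shape` (d-vector or d x K, determinant 1),
#'   `sigma2` (d x K per-component diagonal variances), `loglik`,
#'   `loglik_trace`, `n_params`, `n`, `bic`, `converged`, `iter`, and the
#'   training-data assignment `z`, `classification`, `uncertainty`.
#' @examples
#' x <- c(rnorm(50, 0), rnorm(50, 6))
#' fit <- fit_mixture(x, K = 2, family = "E")
#' fit$mean
#' @seealso [select_model()], [predict.gmm()], [bic()]
#' @export
fit_mixture <- function(x, K = 2, family = NULL,
                        init = c("ward", "kmeans"),
                        nstart = 0, seed = 1L,
                        tol = 1e-8, max_iter = 500L, restarts = 5L,
                        init_partition = NULL) {
  x <- as_data_matrix(x)
  n <- nrow(x); d <- ncol(x)
  init <- match.arg(init)
  if (n <= K) stop("need more observations (", n, ") than components (", K, ")")
  if (anyNA(x) || any(!is.finite(x))) stop("missing or non-finite values in data")
  if (is.null(family)) family <- if (d == 1L) "V" else "VVI"
  check_family(family, d)
  data_var <- apply(x, 2L, stats::var)
  if (any(data_var <= 0)) stop("degenerate input: zero-variance dimension")

  if (K == 1L) return(gmm_single_component(x, family))

  inits <- list(list(method = init, seed = seed))
  n_extra <- nstart + restarts   # restarts are spare inits used on failure
  if (d == 1L && K == 2L && n <= 10L) {
    # tiny univariate samples: enumerate every bipartition as a start, so
    # the returned fit is the constrained global maximizer
    for (code in seq_len(2^(n - 1L) - 1L)) {
      part <- as.integer(intToBits(code))[seq_len(n)] + 1L
      inits[[length(inits) + 1L]] <- list(method = "given", part = part)
    }
    n_extra <- length(inits) - 1L
    nstart <- n_extra
  } else if (d == 1L && K == 2L) {
    # univariate restarts: contiguous splits of the sorted sample --
    # deterministic and far more diverse than repeated k-means starts
    cuts <- unique(round(seq(1, n - 1, length.out = min(n - 1, n_extra))))
    for (cut in cuts)
      inits[[length(inits) + 1L]] <- list(method = "cut", cut = cut)
    n_more <- n_extra - length(cuts)
    if (n_more > 0)
      for (r in seq_len(n_more))
        inits[[length(inits) + 1L]] <- list(method = "kmeans", seed = seed + r)
  } else {
    for (r in seq_len(n_extra))
      inits[[length(inits) + 1L]] <- list(method = "kmeans", seed = seed + r)
  }

  best <- NULL
  n_tried <- 0L
  n_planned <- 1L + nstart
  failures <- character(0)
  for (ini in inits) {
    if (n_tried >= n_planned && !is.null(best)) break
    n_tried <- n_tried + 1L
    z0 <- if (n_tried == 1L && !is.null(init_partition)) {
      partition_to_z(init_partition, n, K)
    } else if (identical(ini$method, "given")) {
      partition_to_z(ini$part, n, K)
    } else if (identical(ini$method, "cut")) {
      part <- integer(n)
      part[order(x[, 1L])] <- rep(1:2, c(ini$cut, n - ini$cut))
      partition_to_z(part, n, K)
    } else init_z(x, K, ini$method, ini$seed)
    fit <- tryCatch(
      em_gmm(x, K, family, z0, tol, max_iter, data_var),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failures <- c(failures, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    # a degenerate solution counts as a failed attempt: keep trying
    if (fit$degenerate && n_tried >= n_planned) n_planned <- n_planned + 1L
  }
  if (is.null(best))
    stop("mixture fit failed after ", length(inits), " initializations: ",
         paste(unique(failures), collapse = "; "))
  if (best$degenerate)
    warning("variance floor reached: component variance clamped at ",
            "1e-8 x data variance (tied or near-degenerate data)")
  best
}

## ---- internal EM machinery ----

as_data_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  x
}

gmm_families <- list(univariate = c("E", "V"),
                     multivariate = c("EII", "VII", "EEI", "VEI", "EVI", "VVI"))

check_family <- function(family, d) {
  ok <- if (d == 1L) gmm_families$univariate else gmm_families$multivariate
  if (!family %in% ok)
    stop("family '", family, "' invalid for dimension ", d,
         " (choose one of ", paste(ok, collapse = ", "), ")")
  invisible(family)
}

# parameter count: (K-1) weights + K*d means + covariance parameters
gmm_n_params <- function(family, d, K) {
  cov_p <- switch(family,
    E = 1L, V = K,
    EII = 1L, VII = K,
    EEI = d, VEI = K + (d - 1L),
    EVI = 1L + K * (d - 1L), VVI = K * d)
  (K - 1L) + K * d + cov_p
}

ward_partition <- function(x, K) {
  stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k = K)
}

partition_to_z <- function(cl, n, K) {
  stopifnot(length(cl) == n, all(cl %in% seq_len(K)))
  z <- matrix(0, n, K)
  z[cbind(seq_len(n), cl)] <- 1
  z
}

init_z <- function(x, K, method, seed) {
  n <- nrow(x)
  cl <- if (method == "ward") {
    ward_partition(x, K)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    stats::kmeans(x, centers = K, nstart = 1L, iter.max = 50L)$cluster
  }
  partition_to_z(cl, n, K)
}

# responsibility-weighted diagonal scatter, d x K
weighted_scatter <- function(x, z, mu) {
  d <- ncol(x); K <- ncol(z)
  W <- matrix(0, d, K)
  for (k in seq_len(K)) {
    dev <- sweep(x, 2L, mu[, k], "-")
    W[, k] <- colSums(z[, k] * dev^2)
  }
  W
}

geo_mean <- function(v) exp(mean(log(v)))

# covariance M-step under the family constraint; W is d x K scatter,
# nk component counts. Returns lambda, shape, per-component sigma2 (d x K).
mstep_covariance <- function(family, W, nk, n, d, shape_prev = NULL) {
  K <- length(nk)
  switch(family,
    E = {
      s2 <- sum(W) / n
      list(lambda = s2, shape = 1, sigma2 = matrix(s2, 1L, K))
    },
    V = {
      s2 <- as.numeric(W[1L, ] / nk)
      list(lambda = s2, shape = 1, sigma2 = matrix(s2, 1L, K))
    },
    EII = {
      lam <- sum(W) / (n * d)
      list(lambda = lam, shape = rep(1, d), sigma2 = matrix(lam, d, K))
    },
    VII = {
      lam <- colSums(W) / (nk * d)
      list(lambda = lam, shape = rep(1, d),
           sigma2 = matrix(rep(lam, each = d), d, K))
    },
    EEI = {
      S <- rowSums(W) / n
      lam <- geo_mean(S)
      list(lambda = lam, shape = S / lam,
           sigma2 = matrix(S, d, K))
    },
    VEI = {
      # no joint closed form: alternate volume and shape updates
      A <- if (is.null(shape_prev)) rep(1, d) else shape_prev
      lam <- rep(1, K)
      for (it in seq_len(100L)) {
        lam_new <- colSums(W / A) / (d * nk)
        Cm <- rowSums(sweep(W, 2L, lam_new, "/"))
        A_new <- Cm / geo_mean(Cm)
        delta <- max(abs(lam_new - lam) / (abs(lam) + 1e-300),
                     abs(A_new - A) / (abs(A) + 1e-300))
        lam <- lam_new; A <- A_new
        if (delta < 1e-8) break
      }
      list(lambda = lam, shape = A,
           sigma2 = outer(A, lam))
    },
    EVI = {
      gk <- apply(W, 2L, geo_mean)
      A <- sweep(W, 2L, gk, "/")
      lam <- sum(gk) / n
      list(lambda = lam, shape = A, sigma2 = lam * A)
    },
    VVI = {
      S <- sweep(W, 2L, nk, "/")
      lam <- apply(S, 2L, geo_mean)
      list(lambda = lam, shape = sweep(S, 2L, lam, "/"), sigma2 = S)
    },
    stop("unknown family ", family))
}

# log density of each observation under each component (n x K)
gmm_log_dens <- function(x, mu, sigma2) {
  n <- nrow(x); K <- ncol(mu)
  L <- matrix(0, n, K)
  for (k in seq_len(K)) {
    dev <- sweep(x, 2L, mu[, k], "-")
    L[, k] <- -0.5 * sum(log(2 * pi * sigma2[, k])) -
      0.5 * colSums(t(dev^2) / sigma2[, k])
  }
  L
}

log_row_sum_exp <- function(L) {
  m <- apply(L, 1L, max)
  m + log(rowSums(exp(L - m)))
}

# EM driver: the iteration loop (E-step, constrained M-step, volume
# clamp at the variance floor) lives in compiled code, as in the
# model-based-clustering reference implementations.
em_gmm <- function(x, K, family, z, tol, max_iter, data_var) {
  n <- nrow(x); d <- ncol(x)
  res <- em_diag_cpp(x, z, family, tol, max_iter, 1e-8 * data_var)
  if (identical(res$status, "collapse"))
    stop("component collapse: effective size below 1")
  shared_vol <- family %in% c("E", "EII", "EEI", "EVI")
  lambda <- if (shared_vol) res$lambda[1L] else as.numeric(res$lambda)
  shape <- switch(family,
    E = , V = 1,
    EII = , VII = rep(1, d),
    EEI = , VEI = as.numeric(res$shape[, 1L]),
    EVI = , VVI = res$shape)
  m <- gmm_n_params(family, d, K)
  structure(list(
    K = K, d = d, family = family, pro = as.numeric(res$pro),
    mean = res$mean,
    lambda = lambda, shape = shape, sigma2 = res$sigma2,
    loglik = res$loglik, loglik_trace = as.numeric(res$trace),
    n_params = m, n = n,
    bic = 2 * res$loglik - m * log(n), converged = res$converged,
    iter = res$iter, degenerate = res$degenerate,
    z = res$z,
    # ties.method = "first": max.col's default breaks exact posterior
    # ties randomly, which would silently break run reproducibility
    classification = max.col(res$z, ties.method = "first"),
    uncertainty = 1 - apply(res$z, 1L, max)), class = "gmm")
}

gmm_single_component <- function(x, family) {
  n <- nrow(x); d <- ncol(x)
  mu <- matrix(colMeans(x), d, 1L)
  W <- weighted_scatter(x, matrix(1, n, 1L), mu)
  cov <- mstep_covariance(family, W, n, n, d)
  L <- gmm_log_dens(x, mu, cov$sigma2)
  ll <- sum(L)
  m <- gmm_n_params(family, d, 1L)
  structure(list(
    K = 1L, d = d, family = family, pro = 1, mean = mu,
    lambda = cov$lambda, shape = cov$shape, sigma2 = cov$sigma2,
    loglik = ll, loglik_trace = ll, n_params = m, n = n,
    bic = 2 * ll - m * log(n), converged = TRUE, iter = 0L,
    degenerate = FALSE,
    z = matrix(1, n, 1L), classification = rep(1L, n),
    uncertainty = rep(0, n)), class = "gmm")
}

## ---- user-facing helpers ----

#' Bayesian information criterion of a fitted mixture
#'
#' Uses the model-based-clustering sign convention
#' \eqn{\mathrm{BIC} = 2\,\ell - m \log n} where \eqn{\ell} is the
#' log-likelihood and \eqn{m} the number of free parameters, so **larger is
#' better**. Note this is the opposite sign of [stats::BIC()], which
#' reports \eqn{-2\ell + m\log n} (smaller is better); the two differ only
#' by sign.
#'
#' @param model a `"gmm"` object from [fit_mixture()].
#' @return a single number, the BIC (to be maximized).
#' @export
bic <- function(model) {
  stopifnot(inherits(model, "gmm"))
  2 * model$loglik - model$n_params * log(model$n)
}

#' Fit several covariance families and keep the best by BIC
#'
#' Fits `K`-component mixtures under each requested covariance family and
#' returns the fit with the highest BIC (ties broken toward the family
#' with fewer parameters), together with the full comparison table.
#'
#' @inheritParams fit_mixture
#' @param families character vector of family codes; defaults to all
#'   families valid for the data dimension.
#' @param ... passed on to [fit_mixture()].
#' @return the winning `"gmm"` object, with the comparison
#'   `data.frame` attached as `$bic_table` (columns `family`, `loglik`,
#'   `n_params`, `bic`, `converged`, `error`).
#' @export
select_model <- function(x, K = 2, families = NULL, ...) {
  x <- as_data_matrix(x)
  d <- ncol(x)
  if (is.null(families))
    families <- if (d == 1L) gmm_families$univariate else gmm_families$multivariate
  if (!length(families)) stop("empty family set")
  for (f in families) check_family(f, d)
  # one deterministic initialization shared by every family fit
  dots <- list(...)
  if (is.null(dots$init_partition) && K > 1L && nrow(x) > K)
    dots$init_partition <- ward_partition(x, K)
  fits <- vector("list", length(families))
  names(fits) <- families
  tab <- data.frame(family = families, loglik = NA_real_,
                    n_params = NA_integer_, bic = NA_real_,
                    converged = NA, degenerate = NA, error = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(families)) {
    f <- families[i]
    res <- tryCatch(
      suppressWarnings(do.call(fit_mixture,
                               c(list(x = x, K = K, family = f), dots))),
      error = function(e) e)
    if (inherits(res, "error")) {
      tab$error[i] <- conditionMessage(res)
      next
    }
    fits[[i]] <- res
    tab$loglik[i] <- res$loglik
    tab$n_params[i] <- res$n_params
    tab$bic[i] <- res$bic
    tab$converged[i] <- res$converged
    tab$degenerate[i] <- res$degenerate
  }
  if (all(is.na(tab$bic)))
    stop("all family fits failed:\n",
         paste(sprintf("  %s: %s", tab$family, tab$error), collapse = "\n"))
  # floor-clamped fits have inflated likelihoods: never let them win
  # over an honest fit; ties -> fewer parameters
  ord <- order(!is.na(tab$bic) & tab$degenerate, -tab$bic, tab$n_params)
  best <- fits[[tab$family[ord[1L]]]]
  best$bic_table <- tab[ord, , drop = FALSE]
  rownames(best$bic_table) <- NULL
  best
}

#' Posterior component membership for new data
#'
#' Computes responsibilities under the frozen parameters of a fitted
#' mixture; no refitting takes place, so the result is deterministic.
#'
#' @param object a `"gmm"` object.
#' @param newdata numeric vector or matrix with the model's dimension.
#' @param ... ignored.
#' @return a list of class `"gmm_assignment"` with `z` (posterior matrix,
#'   rows sum to 1), `classification` (argmax component) and
#'   `uncertainty` (1 minus the maximum posterior).
#' @export
predict.gmm <- function(object, newdata, ...) {
  x <- as_data_matrix(newdata)
  if (ncol(x) != object$d)
    stop("newdata has dimension ", ncol(x), ", model expects ", object$d)
  L <- gmm_log_dens(x, object$mean, object$sigma2)
  Lp <- sweep(L, 2L, log(object$pro), "+")
  lse <- log_row_sum_exp(Lp)
  z <- exp(Lp - lse)
  structure(list(z = z,
                 classification = max.col(z, ties.method = "first"),
                 uncertainty = 1 - apply(z, 1L, max)),
            class = "gmm_assignment")
}

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d, family %s, d = %d, n = %d\n",
              x$K, x$family, x$d, x$n))
  cat(sprintf("  loglik %.4f, %d parameters, BIC %.4f (%s)\n",
              x$loglik, x$n_params, x$bic,
              if (isTRUE(x$converged)) "converged" else "max iterations"))
  cat("  weights:", paste(sprintf("%.3f", x$pro), collapse = " "), "\n")
  cat("  sizes:  ", paste(tabulate(x$classification, x$K), collapse = " "), "\n")
  invisible(x)
}

#' @export
logLik.gmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' Draw samples from a fitted mixture
#'
#' @param object a `"gmm"` object.
#' @param nsim number of samples.
#' @param seed optional integer seed.
#' @param ... ignored.
#' @return an `nsim` x d matrix with the generating component index in
#'   attribute `"component"`.
#' @export
simulate.gmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(object$K, nsim, replace = TRUE, prob = object$pro)
  out <- matrix(0, nsim, object$d)
  for (k in unique(comp)) {
    idx <- comp == k
    out[idx, ] <- matrix(stats::rnorm(sum(idx) * object$d,
                                      mean = rep(object$mean[, k], each = sum(idx)),
                                      sd = rep(sqrt(object$sigma2[, k]), each = sum(idx))),
                         ncol = object$d)
  }
  attr(out, "component") <- comp
  out
}
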