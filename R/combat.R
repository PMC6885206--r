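#' Parametric empirical-Bayes batch adjustment
#'
#' Removes gene-wise additive (location) and multiplicative (scale)
#' batch effects from a log-scale expression matrix by the parametric
#' empirical-Bayes procedure: each gene is standardized by its pooled
#' mean and variance, per-batch location/scale effects are estimated,
#' shrunk toward their across-gene priors (normal for location,
#' inverse-gamma for scale, both moment-matched), and removed before the
#' pooled scale is restored. This is the standard adjustment for placing
#' cohorts measured on different array platforms in a common space
#' before applying a frozen model.
#'
#' With `ref_batch` set, standardization uses the reference batch's
#' means/variances and the reference data are returned untouched, so the
#' other batches are mapped into the reference space — the natural mode
#' when a model trained on one cohort is transferred to another.
#'
#' @param expr gene x sample numeric matrix (log2 scale).
#' @param batch vector/factor of batch labels, one per column.
#' @param parametric only the parametric prior variant is implemented;
#'   `FALSE` errors.
#' @param ref_batch optional batch label to use as the reference space.
#' @param conv relative-change convergence for the coupled EB updates.
#' @param max_iter iteration cap for the EB fixed point.
#' @return list of class `"combat_adjustment"` with elements `adjusted`
#'   (matrix, same shape minus any zero-variance genes), `gamma_hat`,
#'   `delta2_hat` (per-gene per-batch estimates), `gamma_star`,
#'   `delta2_star` (EB-shrunk), `gamma_bar`, `tau2`, `a_prior`,
#'   `b_prior` (per-batch hyperparameters), `grand_mean`, `var_pooled`,
#'   `batch`, `ref_batch`, `dropped_genes`.
#' @export
combat_adjust <- function(expr, batch, parametric = TRUE,
                          ref_batch = NULL, conv = 1e-6, max_iter = 200L) {
  stopifnot(is.matrix(expr))
  if (!parametric) stop("only the parametric EB variant is implemented")
  if (any(!is.finite(expr))) stop("non-finite values in expression matrix")
  batch <- as.character(batch)
  if (length(batch) != ncol(expr))
    stop("batch labels (", length(batch), ") do not match samples (",
         ncol(expr), ")")
  levs <- unique(batch)
  nb <- table(factor(batch, levels = levs))
  if (any(nb < 2)) stop("every batch needs >= 2 samples; too small: ",
                        paste(names(nb)[nb < 2], collapse = ", "))
  if (!is.null(ref_batch) && !ref_batch %in% levs)
    stop("ref_batch '", ref_batch, "' not among batch labels")

  G <- nrow(expr); B <- length(levs); n <- ncol(expr)
  idx <- lapply(levs, function(b) which(batch == b))
  names(idx) <- levs

  # pooled (or reference) standardization
  batch_means <- vapply(idx, function(i) rowMeans(expr[, i, drop = FALSE]),
                        numeric(G))                                  # G x B
  if (is.null(ref_batch)) {
    grand_mean <- as.numeric(batch_means %*% (as.numeric(nb) / n))
    resid <- expr - batch_means[, match(batch, levs)]
    var_pooled <- rowSums(resid^2) / n
  } else {
    grand_mean <- batch_means[, ref_batch]
    i <- idx[[ref_batch]]
    var_pooled <- rowSums((expr[, i, drop = FALSE] - grand_mean)^2) /
      length(i)
  }
  dropped <- rownames(expr)[var_pooled <= 0]
  if (length(dropped)) {
    message("dropping ", length(dropped), " zero-variance gene(s)")
    keep <- var_pooled > 0
    expr <- expr[keep, , drop = FALSE]
    grand_mean <- grand_mean[keep]; var_pooled <- var_pooled[keep]
    batch_means <- batch_means[keep, , drop = FALSE]
    G <- nrow(expr)
  }

  if (B == 1L) {
    zero <- matrix(0, G, 1L, dimnames = list(rownames(expr), levs))
    return(structure(list(
      adjusted = expr, gamma_hat = zero, delta2_hat = zero + 1,
      gamma_star = zero, delta2_star = zero + 1,
      gamma_bar = stats::setNames(0, levs), tau2 = stats::setNames(0, levs),
      a_prior = stats::setNames(NA_real_, levs),
      b_prior = stats::setNames(NA_real_, levs),
      grand_mean = grand_mean, var_pooled = var_pooled,
      batch = batch, ref_batch = ref_batch, dropped_genes = dropped,
      n_iter = stats::setNames(0L, levs)), class = "combat_adjustment"))
  }

  sdat <- (expr - grand_mean) / sqrt(var_pooled)

  gamma_hat <- delta2_hat <- gamma_star <- delta2_star <-
    matrix(NA_real_, G, B, dimnames = list(rownames(expr), levs))
  gamma_bar <- tau2 <- a_prior <- b_prior <- stats::setNames(numeric(B), levs)
  n_iter <- stats::setNames(integer(B), levs)

  for (b in levs) {
    i <- idx[[b]]
    s <- sdat[, i, drop = FALSE]
    m <- length(i)
    g_hat <- rowMeans(s)
    d2_hat <- rowSums((s - g_hat)^2) / (m - 1)
    gamma_hat[, b] <- g_hat; delta2_hat[, b] <- d2_hat
    if (!is.null(ref_batch) && b == ref_batch) {
      gamma_star[, b] <- 0; delta2_star[, b] <- 1
      gamma_bar[b] <- 0; tau2[b] <- 0
      a_prior[b] <- NA_real_; b_prior[b] <- NA_real_
      next
    }
    gamma_bar[b] <- mean(g_hat)
    tau2[b] <- stats::var(g_hat)
    # moment-matched inverse-gamma prior on delta^2
    md <- mean(d2_hat); vd <- stats::var(d2_hat)
    a_prior[b] <- (2 * vd + md^2) / vd
    b_prior[b] <- (md * vd + md^3) / vd
    # coupled posterior fixed point
    g_star <- g_hat
    d2_star <- d2_hat
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (m * tau2[b] * g_hat + d2_star * gamma_bar[b]) /
        (m * tau2[b] + d2_star)
      sum2 <- rowSums((s - g_new)^2)
      d2_new <- (0.5 * sum2 + b_prior[b]) / (m / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_star) / (abs(g_star) + 1e-12),
                    abs(d2_new - d2_star) / (abs(d2_star) + 1e-12))
      g_star <- g_new; d2_star <- d2_new
      if (change < conv || it >= max_iter) break
    }
    n_iter[b] <- it
    gamma_star[, b] <- g_star
    delta2_star[, b] <- d2_star
  }

  adj <- sdat
  for (b in levs) {
    i <- idx[[b]]
    adj[, i] <- (sdat[, i, drop = FALSE] - gamma_star[, b]) /
      sqrt(delta2_star[, b])
  }
  adjusted <- adj * sqrt(var_pooled) + grand_mean
  if (!is.null(ref_batch))                  # reference data untouched
    adjusted[, idx[[ref_batch]]] <- expr[, idx[[ref_batch]]]

  structure(list(
    adjusted = adjusted, gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = gamma_star, delta2_star = delta2_star,
    gamma_bar = gamma_bar, tau2 = tau2, a_prior = a_prior,
    b_prior = b_prior, grand_mean = grand_mean, var_pooled = var_pooled,
    batch = batch, ref_batch = ref_batch, dropped_genes = dropped,
    n_iter = n_iter), class = "combat_adjustment")
}

#' @export
print.combat_adjustment <- function(x, ...) {
  levs <- colnames(x$gamma_hat)
  cat(sprintf("Empirical-Bayes batch adjustment: %d genes, %d samples, %d batch(es)\n",
              nrow(x$adjusted), ncol(x$adjusted), length(levs)))
  if (!is.null(x$ref_batch)) cat("  reference batch:", x$ref_batch, "\n")
  for (b in levs)
    cat(sprintf("  %s: n=%d, gamma_bar=%.3f, tau2=%.3f, IG(a=%.2f, b=%.2f)\n",
                b, sum(x$batch == b), x$gamma_bar[b], x$tau2[b],
                x$a_prior[b], x$b_prior[b]))
  if (length(x$dropped_genes))
    cat("  dropped zero-variance genes:", length(x$dropped_genes), "\n")
  invisible(x)
}
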