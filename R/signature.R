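#' Fit a multivariate expression signature model
#'
#' Fits a two-component multivariate Gaussian mixture on the selected
#' signature genes (BIC selection over the spherical/diagonal covariance
#' families, VEI among them), identifies the adverse component as the
#' one whose hard-labeled samples show the higher observed death hazard
#' (events per person-time — hazard, not size, is the defensible
#' criterion even though the adverse group is typically the minority),
#' and stores the training survival association. The resulting object
#' is frozen: applying it to a new cohort never refits.
#'
#' @param expr gene x sample log2 matrix restricted to (or containing)
#'   the signature genes.
#' @param surv training survival table.
#' @param genes character vector of signature gene ids (>= 2); defaults
#'   to all rows of `expr`.
#' @param K number of mixture components (2 for a minority-vs-rest
#'   signature).
#' @param families candidate covariance families; default all six
#'   diagonal/spherical codes.
#' @param ties Cox tie handling.
#' @param ... passed to [select_model()].
#' @return an object of class `"clustsig_model"`: list with `genes`
#'   (ordered ids, enforced at prediction), `mixture` (the `"gmm"`),
#'   `adverse_cluster` (component index), `bic_table`, `train` (list:
#'   `n`, `adverse_fraction`, `cox` of survival ~ cluster, `assignment`,
#'   sample ids).
#' @examples
#' \donttest{
#' coh <- generate_cohort(synthetic_config(n_samples = 200, n_genes = 50,
#'                                         seed = 7))
#' sig <- fit_signature(coh$expression, coh$survival, genes = coh$signature_genes)
#' print(sig)
#' }
#' @export
fit_signature <- function(expr, surv, genes = rownames(expr), K = 2,
                          families = NULL, ties = "efron", ...) {
  if (length(genes) < 2L) stop("need at least 2 signature genes")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("signature gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  al <- align_samples(expr[genes, , drop = FALSE], surv)
  x <- t(al$expr)                       # samples x genes
  fit <- select_model(x, K = K, families = families, ...)
  cl <- fit$classification
  sizes <- tabulate(cl, K)
  if (any(sizes == 0))
    stop("degenerate clustering: empty component\n",
         paste(utils::capture.output(print(fit$bic_table)), collapse = "\n"))
  haz <- vapply(seq_len(K), function(k)
    sum(al$surv$event[cl == k]) / max(sum(al$surv$time[cl == k]), 1e-300),
    numeric(1))
  if (max(haz) - min(haz) < 1e-12) {
    warning("components have identical observed hazard; ",
            "adverse cluster falls back to component order")
    adverse <- 1L
  } else adverse <- which.max(haz)
  lab <- as.integer(cl == adverse)
  cox <- fit_cox(al$surv, matrix(lab, ncol = 1L,
                                 dimnames = list(NULL, "cluster")),
                 ties = ties)
  structure(list(
    genes = genes,
    mixture = fit,
    adverse_cluster = adverse,
    bic_table = fit$bic_table,
    train = list(n = nrow(x),
                 n_adverse = sum(lab),
                 adverse_fraction = mean(lab),
                 cox = cox,
                 assignment = data.frame(
                   sample = rownames(x),
                   adverse_posterior = fit$z[, adverse],
                   adverse = lab,
                   uncertainty = fit$uncertainty,
                   stringsAsFactors = FALSE),
                 surv = al$surv)), class = "clustsig_model")
}

#' Apply a frozen signature model to a new cohort
#'
#' Computes posterior cluster membership for new samples under the
#' training-cohort parameters — no refitting. Samples are hard-called
#' adverse at posterior > 0.5; posteriors in the borderline band
#' (default \[0.4, 0.6\]) are flagged, since cases near the cluster
#' boundary deserve individual review.
#'
#' @param object a `"clustsig_model"`.
#' @param newdata gene x sample matrix containing all signature genes.
#' @param borderline posterior band flagged as borderline.
#' @param ... ignored.
#' @return `data.frame` of class `"signature_assignment"`: `sample`,
#'   `adverse_posterior`, `adverse` (0/1), `borderline`, `uncertainty`.
#' @export
predict.clustsig_model <- function(object, newdata,
                                   borderline = c(0.4, 0.6), ...) {
  stopifnot(is.matrix(newdata))
  missing <- setdiff(object$genes, rownames(newdata))
  if (length(missing))
    stop("signature gene(s) missing from new data: ",
         paste(missing, collapse = ", "))
  x <- t(newdata[object$genes, , drop = FALSE])  # enforce gene order
  pr <- predict(object$mixture, x)
  post <- pr$z[, object$adverse_cluster]
  out <- data.frame(sample = colnames(newdata),
                    adverse_posterior = post,
                    adverse = as.integer(post > 0.5),
                    borderline = post >= borderline[1L] & post <= borderline[2L],
                    uncertainty = pr$uncertainty,
                    stringsAsFactors = FALSE)
  class(out) <- c("signature_assignment", "data.frame")
  out
}

#' @rdname predict.clustsig_model
#' @param model a `"clustsig_model"`.
#' @param expr_new gene x sample matrix.
#' @export
apply_signature <- function(model, expr_new, borderline = c(0.4, 0.6)) {
  predict(model, expr_new, borderline = borderline)
}

#' Covariate-adjusted Cox model for a cluster assignment
#'
#' Multivariate Cox fit of survival on the adverse-cluster indicator
#' plus clinical/genetic covariates (e.g. age, Binet stage, IGHV
#' status, TP53/del17p, ATM/del11q, NOTCH1, SF3B1, BIRC3 in a CLL
#' setting), to assess whether the cluster effect is independent of
#' established prognostic factors. Complete cases only; the number of
#' dropped rows is reported.
#'
#' @param surv survival table.
#' @param cluster 0/1 adverse indicator per sample (or a
#'   `"signature_assignment"`).
#' @param covariates `data.frame` of covariate columns aligned with
#'   `surv`; `NULL` reduces to the unadjusted fit.
#' @param ties Cox tie handling.
#' @return a `"cox_fit"`; the first coefficient is the cluster effect.
#' @export
adjusted_cox <- function(surv, cluster, covariates = NULL, ties = "efron") {
  if (inherits(cluster, "signature_assignment")) cluster <- cluster$adverse
  surv <- validate_survival(surv)
  if (length(cluster) != nrow(surv))
    stop("cluster labels do not match survival table")
  design <- cbind(cluster = as.numeric(cluster))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    design <- cbind(design, as.matrix(covariates))
  }
  cc <- stats::complete.cases(design) & stats::complete.cases(surv[c("time", "event")])
  if (any(!cc)) message("dropping ", sum(!cc), " incomplete case(s)")
  design <- design[cc, , drop = FALSE]
  surv <- surv[cc, , drop = FALSE]
  qrd <- qr(cbind(1, design))
  if (qrd$rank < ncol(design) + 1L) {
    drop_cols <- colnames(design)[qrd$pivot[-seq_len(qrd$rank)] - 1L]
    stop("collinear covariate set: ", paste(drop_cols, collapse = ", "))
  }
  fit_cox(surv, design, ties = ties)
}

#' Refit the cluster survival model excluding named samples
#'
#' Sensitivity analysis for borderline cases: refits the
#' survival ~ adverse-cluster Cox model after removing the given
#' samples and reports it alongside the full fit.
#'
#' @param surv survival table with `sample` ids.
#' @param assignment a `"signature_assignment"` (or 0/1 vector aligned
#'   with `surv`).
#' @param drop_ids sample ids to exclude.
#' @param ties Cox tie handling.
#' @return list with `full` and `dropped` (`"cox_fit"`s), plus
#'   `adverse_fraction` recomputed over the remaining samples.
#' @export
sensitivity_drop <- function(surv, assignment, drop_ids, ties = "efron") {
  surv <- validate_survival(surv)
  lab <- if (is.data.frame(assignment)) {
    if (!all(c("sample", "adverse") %in% names(assignment)))
      stop("assignment needs 'sample' and 'adverse' columns")
    assignment$adverse[match(surv$sample, assignment$sample)]
  } else as.numeric(assignment)
  if (anyNA(lab)) stop("assignment does not cover all survival samples")
  bad <- setdiff(drop_ids, surv$sample)
  if (length(bad)) stop("unknown sample id(s): ", paste(bad, collapse = ", "))
  keep <- !(surv$sample %in% drop_ids)
  if (sum(lab[keep]) == 0) stop("dropping all adverse samples leaves nothing to test")
  full <- fit_cox(surv, cbind(cluster = lab), ties = ties)
  dropped <- fit_cox(surv[keep, , drop = FALSE],
                     cbind(cluster = lab[keep]), ties = ties)
  list(full = full, dropped = dropped,
       n_dropped = sum(!keep),
       adverse_fraction = mean(lab[keep]))
}

#' @export
print.clustsig_model <- function(x, ...) {
  cat("Expression signature model\n")
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  cat(sprintf("  mixture: K = %d, family %s (BIC %.2f)\n",
              x$mixture$K, x$mixture$family, x$mixture$bic))
  cat(sprintf("  adverse cluster: component %d, %d/%d samples (%.2f%%)\n",
              x$adverse_cluster, x$train$n_adverse, x$train$n,
              100 * x$train$adverse_fraction))
  cox <- x$train$cox
  cat(sprintf("  training survival: HR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              cox$hr, cox$ci_low, cox$ci_high, cox$p))
  invisible(x)
}

#' @export
summary.clustsig_model <- function(object, ...) {
  print(object)
  cat("\nFamily comparison (BIC, larger is better):\n")
  print(object$bic_table, row.names = FALSE)
  cat("\nTraining Cox fit:\n")
  print(object$train$cox)
  invisible(object)
}

#' @export
coef.clustsig_model <- function(object, ...) object$train$cox$beta

#' Kaplan-Meier curves by signature cluster
#'
#' @param x a `"clustsig_model"`.
#' @param col two colors for the majority and adverse groups.
#' @param ... passed to [graphics::plot()].
#' @export
plot.clustsig_model <- function(x, col = c("grey30", "firebrick"), ...) {
  surv <- x$train$surv
  lab <- factor(x$train$assignment$adverse, levels = c(0, 1),
                labels = c("majority", "adverse"))
  sf <- survival::survfit(survival::Surv(surv$time, surv$event) ~ lab)
  graphics::plot(sf, col = col, lwd = 2, xlab = "time",
                 ylab = "overall survival", ...)
  graphics::legend("bottomleft", legend = levels(lab), col = col, lwd = 2,
                   bty = "n")
  invisible(sf)
}

#' Serialize a signature model to JSON
#'
#' The JSON carries everything needed for frozen prediction (gene order,
#' mixture family, weights, means, volumes, shapes, component variances,
#' adverse component) at full double precision, so a save/load
#' round-trip reproduces posteriors bit-for-bit.
#'
#' @param model a `"clustsig_model"`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "clustsig_model"))
  mx <- model$mixture
  payload <- list(
    type = "clustsig_model", version = 1L,
    genes = model$genes,
    adverse_cluster = model$adverse_cluster,
    mixture = list(K = mx$K, d = mx$d, family = mx$family,
                   pro = mx$pro, mean = mx$mean,
                   lambda = mx$lambda, shape = mx$shape,
                   sigma2 = mx$sigma2,
                   loglik = mx$loglik, n_params = mx$n_params,
                   n = mx$n, bic = mx$bic),
    train = list(n = model$train$n, n_adverse = model$train$n_adverse,
                 adverse_fraction = model$train$adverse_fraction))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a signature model saved by [write_signature()]
#'
#' @param path JSON path.
#' @return a `"clustsig_model"` sufficient for prediction (training
#'   survival internals are not persisted).
#' @export
read_signature <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$type, "clustsig_model")) stop("not a signature model file")
  mx <- p$mixture
  d <- as.integer(mx$d); K <- as.integer(mx$K)
  mixture <- structure(list(
    K = K, d = d, family = mx$family, pro = as.numeric(mx$pro),
    mean = matrix(as.numeric(mx$mean), d, K),
    lambda = as.numeric(mx$lambda),
    shape = if (length(mx$shape) == d * K && mx$family %in% c("EVI", "VVI"))
      matrix(as.numeric(mx$shape), d, K) else as.numeric(mx$shape),
    sigma2 = matrix(as.numeric(mx$sigma2), d, K),
    loglik = mx$loglik, n_params = mx$n_params, n = mx$n,
    bic = mx$bic, converged = TRUE), class = "gmm")
  structure(list(genes = as.character(p$genes),
                 mixture = mixture,
                 adverse_cluster = as.integer(p$adverse_cluster),
                 bic_table = NULL,
                 train = p$train), class = "clustsig_model")
}
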