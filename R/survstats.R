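#' Cox proportional-hazards fit with Wald inference
#'
#' Fits a Cox model of right-censored survival on a design matrix by
#' maximum partial likelihood and reports hazard ratios with 95% Wald
#' confidence intervals, the style used for prognostic-marker reports
#' (HR, CI, p). Efron tie handling is the default; Breslow is available
#' for cross-checks. With no tied event times the two coincide.
#'
#' Monotone partial likelihoods (perfect separation, e.g. every event in
#' one group occurring before any other subject's entry) cannot yield a
#' finite maximizer; such coefficients are flagged in `$infinite` and a
#' warning is raised instead of silently reporting a diverged estimate.
#'
#' @param surv a survival table: `data.frame` with columns `time`
#'   (non-negative follow-up) and `event` (0 = censored, 1 = death), and
#'   optionally `sample` ids.
#' @param design numeric matrix or data.frame of covariates, one row per
#'   sample in `surv` order.
#' @param ties `"efron"` or `"breslow"`.
#' @return an object of class `"cox_fit"`: list with `beta`, `se`, `hr`
#'   (`exp(beta)`), `ci_low`/`ci_high` (95% Wald limits on the HR scale),
#'   `p` (Wald), `p_lrt` (likelihood-ratio p of the whole model — for a
#'   single covariate, the coefficient's LRT, whose null tail is better
#'   calibrated than Wald's when the covariate is a rare indicator),
#'   `loglik` (maximized partial log-likelihood), `loglik_null`, `ties`,
#'   `n`, `n_events`, `infinite` (logical per coefficient).
#' @examples
#' surv <- data.frame(time = c(2, 4, 6, 8), event = c(1, 1, 1, 0))
#' fit_cox(surv, design = matrix(c(1, 0, 1, 0), ncol = 1), ties = "breslow")
#' @export
fit_cox <- function(surv, design, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  surv <- validate_survival(surv)
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  if (nrow(design) != nrow(surv))
    stop("design has ", nrow(design), " rows but survival table has ", nrow(surv))
  if (sum(surv$event) < 1) stop("zero events: Cox model is not estimable")
  sds <- apply(design, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s) in design: ",
         paste(which(sds == 0), collapse = ", "))
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))

  fit <- withCallingHandlers(
    survival::coxph.fit(
      design, survival::Surv(surv$time, surv$event),
      strata = NULL, offset = NULL, init = NULL,
      control = survival::coxph.control(eps = 1e-10, iter.max = 50),
      weights = NULL, method = ties, rownames = NULL),
    # the fitter's own divergence warning is superseded by the explicit
    # monotone-likelihood diagnostic below
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients)
  se <- unname(sqrt(diag(as.matrix(fit$var))))
  infinite <- abs(beta) > 15 | se > 1e3
  if (any(infinite))
    warning("monotone partial likelihood: coefficient(s) ",
            paste(colnames(design)[infinite], collapse = ", "),
            " diverge to infinity; estimates unreliable")
  zcrit <- stats::qnorm(0.975)
  nm <- function(v) stats::setNames(v, colnames(design))
  structure(list(
    beta = nm(beta),
    se = nm(se),
    hr = nm(exp(beta)),
    ci_low = nm(exp(beta - zcrit * se)),
    ci_high = nm(exp(beta + zcrit * se)),
    p = nm(2 * stats::pnorm(-abs(beta / se))),
    p_lrt = stats::pchisq(2 * (fit$loglik[2L] - fit$loglik[1L]),
                          df = ncol(design), lower.tail = FALSE),
    loglik = unname(fit$loglik[2L]),
    loglik_null = unname(fit$loglik[1L]),
    ties = ties, n = nrow(surv), n_events = sum(surv$event),
    infinite = infinite), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional hazards (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tab <- data.frame(beta = x$beta, se = x$se, HR = x$hr,
                    lower95 = x$ci_low, upper95 = x$ci_high,
                    p = signif(x$p, digits))
  print(format(tab, digits = digits), ...)
  if (any(x$infinite)) cat("warning: coefficient(s) diverged (monotone likelihood)\n")
  invisible(x)
}

validate_survival <- function(surv) {
  surv <- as.data.frame(surv)
  if (!all(c("time", "event") %in% names(surv)))
    stop("survival table needs 'time' and 'event' columns")
  if (any(surv$time < 0)) stop("negative follow-up times")
  if (!all(surv$event %in% c(0, 1))) stop("event indicator must be 0/1")
  if ("sample" %in% names(surv) && anyDuplicated(surv$sample))
    stop("duplicated sample ids in survival table: ",
         paste(unique(surv$sample[duplicated(surv$sample)]), collapse = ", "))
  surv
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator of the survival function within each level of
#' a grouping vector, the estimator behind the familiar stratified
#' survival curves.
#'
#' @param surv survival table (`time`, `event` columns).
#' @param groups vector of group labels, one per row of `surv`; defaults
#'   to a single group.
#' @return a `data.frame` with one row per distinct observed time per
#'   group: `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (non-increasing within group, S(0) = 1 implicitly).
#' @export
km_estimate <- function(surv, groups = NULL) {
  surv <- validate_survival(surv)
  if (is.null(groups)) groups <- rep("all", nrow(surv))
  if (length(groups) != nrow(surv))
    stop("groups length does not match survival table")
  if (any(table(groups) == 0) || anyNA(groups)) stop("empty or missing group")
  g <- factor(groups)
  out <- do.call(rbind, lapply(levels(g), function(lev) {
    idx <- g == lev
    sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                            data = surv[idx, , drop = FALSE])
    data.frame(group = lev, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, n_censor = sf$n.censor,
               survival = sf$surv, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} \, m \, p_{(j)} / j}, capped at 1.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
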