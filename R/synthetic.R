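#' Configuration for a synthetic expression + survival cohort
#'
#' Collects the generating parameters of a simulated cohort carrying a
#' planted minority cluster: a small fraction of samples whose signature
#' genes are shifted on the log2 scale and whose death hazard is
#' multiplied by `exp(true_log_hr)`. Defaults mirror a realistic CLL
#' study: 450 samples, 2000 genes, a 3-gene signature shifted by 2.5
#' log2 units in ~4.5% of patients, hazard ratio 4.86, and exponential
#' follow-up on a scale of years with roughly 30% censoring.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param n_signature_genes how many genes carry the planted shift.
#' @param minority_fraction expected fraction of minority samples, in
#'   (0, 0.5); membership is drawn independently per sample.
#' @param shift mean log2 displacement of signature genes in the minority
#'   cluster; scalar or one value per signature gene.
#' @param noise_sd within-cluster gene-wise standard deviation (log2).
#' @param baseline_mean,baseline_sd distribution of gene-level baseline
#'   log2 intensities.
#' @param baseline_hazard majority-cluster death hazard (events per
#'   time-unit, years by convention).
#' @param true_log_hr log hazard ratio of minority vs majority.
#' @param censor_rate hazard of the independent exponential censoring
#'   process; 0 disables censoring.
#' @param shape Weibull shape of the survival times; 1 (default) gives
#'   the exponential, constant-hazard model.
#' @param batch_gamma_sd SD of the additive per-gene batch offsets
#'   applied to a paired validation cohort.
#' @param batch_delta_shape shape of the inverse-gamma multiplicative
#'   batch scale (rate fixed at shape - 1 so the mean scale is 1).
#' @param covariate_spec optional list of binary covariates, each a list
#'   with `name`, `prevalence`, `log_hr`.
#' @param seed integer seed; identical config + seed is bit-reproducible.
#' @return a list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_samples = 450L, n_genes = 2000L,
                             n_signature_genes = 3L,
                             minority_fraction = 0.045,
                             shift = 2.5, noise_sd = 0.5,
                             baseline_mean = 7, baseline_sd = 1.5,
                             baseline_hazard = 0.08,
                             true_log_hr = log(4.86),
                             censor_rate = 0.04,
                             shape = 1,
                             batch_gamma_sd = 0.5,
                             batch_delta_shape = 3,
                             covariate_spec = NULL,
                             seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_signature_genes = as.integer(n_signature_genes),
              minority_fraction = minority_fraction, shift = shift,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, baseline_hazard = baseline_hazard,
              true_log_hr = true_log_hr, censor_rate = censor_rate,
              shape = shape, batch_gamma_sd = batch_gamma_sd,
              batch_delta_shape = batch_delta_shape,
              covariate_spec = covariate_spec, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$minority_fraction <= 0 || cfg$minority_fraction >= 0.5)
    stop("minority_fraction must lie in (0, 0.5)")
  if (cfg$n_signature_genes > cfg$n_genes)
    stop("n_signature_genes exceeds n_genes")
  if (cfg$minority_fraction * cfg$n_samples < 2)
    stop("expected minority size below 2 samples: cluster unfittable")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$censor_rate < 0) stop("censor_rate must be non-negative")
  if (!length(cfg$shift) %in% c(1L, cfg$n_signature_genes))
    stop("shift must be scalar or one value per signature gene")
  invisible(cfg)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a synthetic cohort with a planted minority cluster
#'
#' Draws a gene x sample log2 expression matrix plus a right-censored
#' survival table with known ground truth. Minority membership is
#' Bernoulli(`minority_fraction`); signature genes get their minority
#' means shifted by `shift` while every other gene is identically
#' distributed across clusters. Survival times are Weibull with shape
#' `shape` (exponential by default) and hazard
#' `baseline_hazard * exp(true_log_hr * minority + covariate effects)`;
#' censoring is independent exponential(`censor_rate`), the observed time
#' is the minimum and `event` indicates death first. Deterministic
#' sub-seeds per block (labels, expression, survival, covariates) are
#' derived from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param sample_prefix,batch label plumbing for paired-cohort use.
#' @return a list of class `"synthetic_cohort"`: `expression` (gene x
#'   sample matrix, log2 scale), `survival` (data.frame: `sample`,
#'   `time`, `event`, covariates), `true_labels` (0 = majority,
#'   1 = minority), `signature_genes`, `true_params`, `batch`, `config`.
#' @export
generate_cohort <- function(config, sample_prefix = "S", batch = "batch1") {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  n <- config$n_samples; g <- config$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(g))
  sample_ids <- sprintf("%s%03d", sample_prefix, seq_len(n))
  sig_idx <- seq_len(config$n_signature_genes)
  shift <- rep(config$shift, length.out = config$n_signature_genes)

  labels <- with_seed(config$seed + 101L,
                      stats::rbinom(n, 1L, config$minority_fraction))
  baseline <- with_seed(config$seed + 202L,
                        stats::rnorm(g, config$baseline_mean, config$baseline_sd))
  expr <- with_seed(config$seed + 303L, {
    e <- matrix(stats::rnorm(g * n, mean = baseline, sd = config$noise_sd), g, n)
    if (any(labels == 1L))
      e[sig_idx, labels == 1L] <- e[sig_idx, labels == 1L] + shift
    e
  })
  dimnames(expr) <- list(gene_ids, sample_ids)

  covariates <- NULL
  cov_lp <- rep(0, n)
  if (length(config$covariate_spec)) {
    covariates <- with_seed(config$seed + 404L, {
      as.data.frame(lapply(config$covariate_spec, function(cv)
        stats::rbinom(n, 1L, cv$prevalence)),
        col.names = vapply(config$covariate_spec, `[[`, "", "name"))
    })
    for (j in seq_along(config$covariate_spec))
      cov_lp <- cov_lp + covariates[[j]] * config$covariate_spec[[j]]$log_hr
  }

  hazard <- config$baseline_hazard * exp(config$true_log_hr * labels + cov_lp)
  surv <- with_seed(config$seed + 505L, {
    # Weibull with shape a and this hazard scaling: S(t) = exp(-h * t^a)
    u <- stats::runif(n)
    death <- (-log(u) / hazard)^(1 / config$shape)
    cens <- if (config$censor_rate > 0)
      stats::rexp(n, config$censor_rate) else rep(Inf, n)
    data.frame(sample = sample_ids,
               time = pmin(death, cens),
               event = as.integer(death <= cens),
               stringsAsFactors = FALSE)
  })
  if (!is.null(covariates)) surv <- cbind(surv, covariates)

  structure(list(
    expression = expr, survival = surv, true_labels = labels,
    signature_genes = gene_ids[sig_idx],
    true_params = list(baseline = baseline, shift = shift,
                       hazard = hazard, labels = labels,
                       log_hr = config$true_log_hr),
    batch = stats::setNames(rep(batch, n), sample_ids),
    config = config), class = "synthetic_cohort")
}

#' Generate paired training and validation cohorts with batch effects
#'
#' Builds two cohorts that share gene-level generating parameters
#' (baseline means, signature shift, hazards) when `shared_params` is
#' `TRUE`, then perturbs the validation cohort with gene-wise batch
#' effects: additive offsets \eqn{\gamma_g \sim N(0,
#' \mathrm{batch\_gamma\_sd}^2)} and multiplicative noise scales
#' \eqn{\delta_g^2 \sim} inverse-gamma(`batch_delta_shape`, rate =
#' `batch_delta_shape` - 1), emulating the platform difference between
#' two microarray generations. The planted batch parameters are recorded
#' in `true_params$batch_gamma` / `true_params$batch_delta2` of the
#' validation cohort.
#'
#' @param config_train,config_valid [synthetic_config()]s for the two
#'   cohorts (e.g. 450 and 107 samples).
#' @param shared_params force identical gene-level generating
#'   distributions across cohorts (default `TRUE`).
#' @return list with elements `train` and `valid`, both
#'   `"synthetic_cohort"`, with `batch` labels `"train"`/`"valid"`.
#' @export
generate_paired_cohorts <- function(config_train, config_valid,
                                    shared_params = TRUE) {
  stopifnot(inherits(config_train, "synthetic_config"),
            inherits(config_valid, "synthetic_config"))
  if (shared_params) {
    for (f in c("baseline_mean", "baseline_sd", "noise_sd", "shift",
                "n_genes", "n_signature_genes", "baseline_hazard",
                "true_log_hr", "shape"))
      config_valid[[f]] <- config_train[[f]]
  }
  train <- generate_cohort(config_train, sample_prefix = "T", batch = "train")
  valid <- generate_cohort(config_valid, sample_prefix = "V", batch = "valid")
  if (shared_params) {
    # same per-gene baselines in both cohorts
    shift_v <- valid$expression - valid$true_params$baseline
    valid$expression <- shift_v + train$true_params$baseline
    valid$true_params$baseline <- train$true_params$baseline
  }
  g <- config_train$n_genes
  bseed <- config_valid$seed + 606L
  gamma <- with_seed(bseed, stats::rnorm(g, 0, max(config_valid$batch_gamma_sd, 1e-12)))
  if (config_valid$batch_gamma_sd == 0) gamma[] <- 0
  a <- config_valid$batch_delta_shape
  delta2 <- if (a > 1) {
    with_seed(bseed + 1L, 1 / stats::rgamma(g, shape = a, rate = a - 1))
  } else rep(1, g)
  centred <- valid$expression - valid$true_params$baseline
  valid$expression <- valid$true_params$baseline + sqrt(delta2) * centred + gamma
  valid$true_params$batch_gamma <- gamma
  valid$true_params$batch_delta2 <- delta2
  list(train = train, valid = valid)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes x %d samples, %d minority (%.1f%%)\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$true_labels), 100 * mean(x$true_labels)))
  cat(sprintf("  signature genes: %s (shift %s log2 units)\n",
              paste(x$signature_genes, collapse = ", "),
              paste(format(x$true_params$shift), collapse = "/")))
  cat(sprintf("  true HR %.2f, events %d/%d\n",
              exp(x$config$true_log_hr), sum(x$survival$event),
              nrow(x$survival)))
  invisible(x)
}

#' Write a synthetic cohort to tab-separated files
#'
#' Writes `<prefix>_expression.tsv` (gene ids in the first column,
#' sample ids as header), `<prefix>_survival.tsv` and
#' `<prefix>_truth.tsv`.
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param prefix path prefix for the three files.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  paths <- paste0(prefix, c("_expression.tsv", "_survival.tsv", "_truth.tsv"))
  write_expression(cohort$expression, paths[1L])
  utils::write.table(cohort$survival, paths[2L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- data.frame(sample = colnames(cohort$expression),
                      true_label = cohort$true_labels,
                      hazard = cohort$true_params$hazard)
  utils::write.table(truth, paths[3L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
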