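#' Configuration for an end-to-end signature run
#'
#' Bundles the inputs and tuning parameters of the full discovery +
#' transfer workflow so a run is reproducible from its configuration
#' alone. Inputs may be file paths (TSV, read with [read_expression()] /
#' [read_survival()]) or in-memory objects.
#'
#' @param expression training expression matrix or TSV path.
#' @param survival training survival table or TSV path.
#' @param valid_expression,valid_survival optional validation cohort
#'   (survival optional even when expression is given).
#' @param probe_map optional probe-to-gene table (or TSV path with
#'   columns `probe`, `gene`) applied to both cohorts before anything
#'   else.
#' @param q_threshold BH selection threshold for the gene screen.
#' @param min_cluster minimum minor-cluster size in the screen.
#' @param families multivariate candidate families for the signature.
#' @param ties Cox tie handling.
#' @param borderline posterior band flagged as borderline.
#' @param combat_mode `"joint"` (pool both cohorts for standardization,
#'   default), `"reference"` (training cohort as reference batch) or
#'   `"none"`.
#' @param covariates optional covariate column names (must exist in the
#'   training survival table) for the adjusted Cox model.
#' @param seed integer seed recorded in the manifest (the pipeline's
#'   deterministic initialization does not consume randomness, but the
#'   seed is part of the run's identity).
#' @param out_dir output directory for [run_pipeline()].
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expression, survival,
                            valid_expression = NULL, valid_survival = NULL,
                            probe_map = NULL,
                            q_threshold = 0.05, min_cluster = 3L,
                            families = NULL, ties = "efron",
                            borderline = c(0.4, 0.6),
                            combat_mode = c("joint", "reference", "none"),
                            covariates = NULL,
                            seed = 1L, out_dir = tempfile("clustsig_run_")) {
  structure(list(expression = expression, survival = survival,
                 valid_expression = valid_expression,
                 valid_survival = valid_survival, probe_map = probe_map,
                 q_threshold = q_threshold, min_cluster = as.integer(min_cluster),
                 families = families, ties = ties, borderline = borderline,
                 combat_mode = match.arg(combat_mode),
                 covariates = covariates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

load_input <- function(x, reader) if (is.character(x) && length(x) == 1L) reader(x) else x

#' Run the full discovery-and-transfer pipeline
#'
#' Executes, in order: probe collapse, per-gene screen, multivariate
#' signature fit, optional covariate-adjusted Cox model, optional batch
#' adjustment of the validation cohort, frozen-model prediction and
#' validation survival analysis. Every artifact is written to the run
#' directory as TSV/JSON next to a `manifest.json` carrying the
#' configuration digest, package version and MD5 of each numeric
#' output, so identical configuration reproduces identical hashes.
#' Stage failures abort with the stage name; artifacts of completed
#' stages are left in place for debugging.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of class `"clustsig_run"` with `screen`,
#'   `signature`, `train_assignment`, `adjusted` (Cox or NULL),
#'   `valid_assignment`, `valid_cox`, `km`, `manifest`, `out_dir`,
#'   `status` (`"ok"` or `"no genes selected"`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf("[%s] %s\n", "clustsig", sprintf(...)),
                            file = log_path, append = TRUE)
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logf("stage %s: done", name)
    res
  }
  out <- list(out_dir = config$out_dir, status = "ok")

  expr <- stage("load_training", {
    e <- load_input(config$expression, read_expression)
    s <- load_input(config$survival, read_survival)
    pm <- load_input(config$probe_map,
                     function(p) utils::read.delim(p, stringsAsFactors = FALSE))
    if (!is.null(pm)) e <- collapse_probes(e, pm)
    list(expr = e, surv = s)
  })

  screen <- stage("screen", {
    sc <- screen_genes(expr$expr, expr$surv,
                       q_threshold = config$q_threshold,
                       min_cluster = config$min_cluster, ties = config$ties)
    write_screen(sc, file.path(config$out_dir, "screen_report.tsv"))
    writeLines(selected_genes(sc),
               file.path(config$out_dir, "selected_genes.txt"))
    sc
  })
  out$screen <- screen
  genes <- selected_genes(screen)
  logf("screen: %d genes selected", length(genes))

  if (length(genes) < 2L) {
    out$status <- "no genes selected"
    logf("stopping: fewer than 2 genes selected, no signature fitted")
    out$manifest <- write_manifest(config, out)
    return(invisible(structure(out, class = "clustsig_run")))
  }

  sig <- stage("fit_signature", {
    s <- fit_signature(expr$expr, expr$surv, genes = genes,
                       families = config$families, ties = config$ties)
    write_signature(s, file.path(config$out_dir, "signature_model.json"))
    utils::write.table(s$train$assignment,
                       file.path(config$out_dir, "train_assignment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_cox(s$train$cox, file.path(config$out_dir, "train_cox.tsv"))
    km <- km_estimate(s$train$surv, s$train$assignment$adverse)
    utils::write.table(km, file.path(config$out_dir, "train_km.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    s
  })
  out$signature <- sig
  out$train_assignment <- sig$train$assignment
  logf("signature: genes %s, adverse fraction %.4f",
       paste(genes, collapse = ","), sig$train$adverse_fraction)

  if (!is.null(config$covariates)) {
    out$adjusted <- stage("adjusted_cox", {
      covs <- sig$train$surv[, config$covariates, drop = FALSE]
      a <- adjusted_cox(sig$train$surv, sig$train$assignment$adverse,
                        covariates = covs, ties = config$ties)
      write_cox(a, file.path(config$out_dir, "adjusted_cox.tsv"))
      a
    })
  }

  if (!is.null(config$valid_expression)) {
    vexpr <- stage("load_validation", {
      e <- load_input(config$valid_expression, read_expression)
      pm <- load_input(config$probe_map,
                       function(p) utils::read.delim(p, stringsAsFactors = FALSE))
      if (!is.null(pm)) e <- collapse_probes(e, pm)
      common <- intersect(rownames(expr$expr), rownames(e))
      missing_sig <- setdiff(genes, common)
      if (length(missing_sig))
        stop("signature gene(s) unresolvable in validation cohort: ",
             paste(missing_sig, collapse = ", "))
      e[common, , drop = FALSE]
    })
    vadj <- stage("batch_adjust", {
      if (config$combat_mode == "none") vexpr
      else {
        common <- intersect(rownames(expr$expr), rownames(vexpr))
        joint <- cbind(expr$expr[common, , drop = FALSE],
                       vexpr[common, , drop = FALSE])
        b <- rep(c("train", "valid"),
                 c(ncol(expr$expr), ncol(vexpr)))
        ca <- combat_adjust(joint, b,
                            ref_batch = if (config$combat_mode == "reference")
                              "train" else NULL)
        if (config$combat_mode == "reference")
          logf("batch_adjust: training cohort used as reference batch")
        ca$adjusted[, b == "valid", drop = FALSE]
      }
    })
    out$valid_assignment <- stage("apply_signature", {
      a <- apply_signature(sig, vadj, borderline = config$borderline)
      utils::write.table(a, file.path(config$out_dir, "valid_assignment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      a
    })
    logf("transfer: validation adverse fraction %.4f (%d borderline)",
         mean(out$valid_assignment$adverse), sum(out$valid_assignment$borderline))
    if (!is.null(config$valid_survival)) {
      out$valid_cox <- stage("validate", {
        vs <- load_input(config$valid_survival, read_survival)
        al <- align_samples(vadj, vs)
        lab <- out$valid_assignment$adverse[
          match(colnames(al$expr), out$valid_assignment$sample)]
        cx <- fit_cox(al$surv, cbind(cluster = lab), ties = config$ties)
        write_cox(cx, file.path(config$out_dir, "valid_cox.tsv"))
        km <- km_estimate(al$surv, lab)
        utils::write.table(km, file.path(config$out_dir, "valid_km.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        cx
      })
    }
  }
  out$manifest <- write_manifest(config, out)
  invisible(structure(out, class = "clustsig_run"))
}

write_cox <- function(cox, path) {
  tab <- data.frame(term = names(cox$beta), beta = cox$beta, se = cox$se,
                    hr = cox$hr, ci_low = cox$ci_low, ci_high = cox$ci_high,
                    p = cox$p, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(config, out) {
  files <- setdiff(list.files(config$out_dir), c("manifest.json", "run.log"))
  hashes <- as.list(tools::md5sum(file.path(config$out_dir, files)))
  names(hashes) <- files
  cfg <- config[c("q_threshold", "min_cluster", "ties", "borderline",
                  "combat_mode", "seed")]
  manifest <- list(package = "clustsig",
                   version = as.character(utils::packageVersion("clustsig")),
                   status = out$status,
                   config = cfg,
                   outputs = hashes)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.clustsig_run <- function(x, ...) {
  cat("Pipeline run:", x$status, "\n")
  cat("  output directory:", x$out_dir, "\n")
  if (!is.null(x$screen))
    cat("  genes selected:", sum(x$screen$selected), "\n")
  if (!is.null(x$signature))
    cat(sprintf("  training adverse fraction: %.2f%%, HR %.2f\n",
                100 * x$signature$train$adverse_fraction,
                x$signature$train$cox$hr))
  if (!is.null(x$valid_assignment))
    cat(sprintf("  validation adverse fraction: %.2f%%%s\n",
                100 * mean(x$valid_assignment$adverse),
                if (!is.null(x$valid_cox))
                  sprintf(", HR %.2f", x$valid_cox$hr) else ""))
  invisible(x)
}
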