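#' Read a gene x sample expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene (or probe)
#' identifiers and whose header row holds sample identifiers — the
#' common export format for normalized, log2-scale microarray or RNA-seq
#' matrices. GCT files are accepted by skipping their two header lines.
#'
#' @param path file path.
#' @param na_policy `"error"` (default) aborts on any missing value;
#'   `"drop_gene"` removes genes containing missing values and reports
#'   how many were dropped.
#' @param format `"tsv"` or `"gct"`.
#' @return a numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @export
read_expression <- function(path, na_policy = c("error", "drop_gene"),
                            format = c("tsv", "gct")) {
  na_policy <- match.arg(na_policy)
  format <- match.arg(format)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          skip = if (format == "gct") 2L else 0L)
  if (ncol(df) < 2L) stop("expression file needs an id column plus samples")
  ids <- as.character(df[[1L]])
  if (format == "gct" && tolower(names(df)[2L]) == "description")
    df <- df[, -2L, drop = FALSE]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    lines <- which(ids %in% dup) + 1L
    stop("duplicated gene id(s) ", paste(dup, collapse = ", "),
         " at line(s) ", paste(lines, collapse = ", "))
  }
  samp <- names(df)[-1L]
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, TRUE))
  if (length(bad)) {
    # locate non-numeric cells for the error message
    col <- bad[1L]
    cell <- which(is.na(suppressWarnings(as.numeric(vals[[col]]))) &
                    !is.na(vals[[col]]))[1L]
    stop("non-numeric value '", vals[[col]][cell], "' in column '",
         samp[col], "' at line ", cell + 1L)
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyNA(m)) {
    if (na_policy == "error")
      stop("missing values in expression matrix (", sum(is.na(m)),
           " cells); use na_policy = 'drop_gene' to remove affected genes")
    drop <- rowSums(is.na(m)) > 0
    message("dropping ", sum(drop), " gene(s) with missing values")
    m <- m[!drop, , drop = FALSE]
  }
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: first column `gene`, one column per
#' sample. Values are written at full double precision so that a
#' read-back is value-identical.
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table from TSV
#'
#' Columns: `sample`, `time`, `event`, then any covariates.
#'
#' @param path file path.
#' @param time_unit free-text label recorded as an attribute (the two
#'   cohorts of a transfer study may define overall survival from
#'   different origins; the unit/origin is metadata the caller owns).
#' @return a validated `data.frame`.
#' @export
read_survival <- function(path, time_unit = "years") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival file needs columns: ", paste(need, collapse = ", "))
  df <- validate_survival(df)
  attr(df, "time_unit") <- time_unit
  df
}

#' Collapse probe-level rows to gene level by median
#'
#' For genes targeted by multiple probes the per-sample median across
#' those probes is taken; single-probe genes pass through unchanged.
#' Probes absent from the map are dropped with a message.
#'
#' @param expr probe x sample matrix (rownames = probe ids).
#' @param probe_map `data.frame` with columns `probe` and `gene`.
#' @return gene x sample matrix.
#' @export
collapse_probes <- function(expr, probe_map) {
  stopifnot(is.matrix(expr))
  probe_map <- as.data.frame(probe_map)
  if (!all(c("probe", "gene") %in% names(probe_map)))
    stop("probe_map needs 'probe' and 'gene' columns")
  keep <- rownames(expr) %in% probe_map$probe
  if (!any(keep)) stop("no probes in common between matrix and map")
  if (any(!keep))
    message("dropping ", sum(!keep), " unmapped probe(s)")
  expr <- expr[keep, , drop = FALSE]
  gene <- probe_map$gene[match(rownames(expr), probe_map$probe)]
  multi <- unique(gene[duplicated(gene)])
  if (!length(multi)) {
    rownames(expr) <- gene
    return(expr)
  }
  single <- !(gene %in% multi)
  out_single <- expr[single, , drop = FALSE]
  rownames(out_single) <- gene[single]
  out_multi <- t(vapply(multi, function(g) {
    apply(expr[gene == g, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(expr))))
  rownames(out_multi) <- multi
  out <- rbind(out_single, out_multi)
  out[order(rownames(out)), , drop = FALSE]
}

#' Align an expression matrix with a survival table
#'
#' Inner join on sample ids, warning about samples present on only one
#' side (silent intersection is forbidden by design: the dropped ids are
#' the numbers a reviewer asks about).
#'
#' @param expr gene x sample matrix.
#' @param surv survival table with a `sample` column.
#' @return list with the aligned `expr` and `surv` in matched order.
#' @export
align_samples <- function(expr, surv) {
  surv <- validate_survival(surv)
  if (!"sample" %in% names(surv)) stop("survival table needs a 'sample' column")
  common <- intersect(colnames(expr), surv$sample)
  if (!length(common)) stop("no samples in common")
  lost_e <- setdiff(colnames(expr), common)
  lost_s <- setdiff(surv$sample, common)
  if (length(lost_e) || length(lost_s))
    warning("dropping unmatched samples: ",
            length(lost_e), " expression-only, ",
            length(lost_s), " survival-only (",
            paste(utils::head(c(lost_e, lost_s), 10L), collapse = ", "),
            if (length(lost_e) + length(lost_s) > 10L) ", ..." else "", ")")
  list(expr = expr[, common, drop = FALSE],
       surv = surv[match(common, surv$sample), , drop = FALSE])
}
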