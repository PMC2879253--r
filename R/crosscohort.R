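# Multi-cohort validation: gene/probe matching across platforms,
# per-cohort evaluation, pooled ("Combined") performance, and the combined
# exact p-value.

#' Match signature genes to expression rows across platforms
#'
#' When a signature is applied to a cohort measured on a different platform,
#' gene symbols must be mapped to that platform's probe ids.  Where several
#' probes map to one symbol, the probe with the highest mean expression is
#' selected.  Unmatched genes either fail (default) or are dropped.
#'
#' @param genes signature gene symbols.
#' @param expr cohort expression matrix (rows = probes or symbols).
#' @param annotation optional data.frame with columns \code{probe_id} and
#'   \code{gene_symbol}; when \code{NULL} row names are taken to be symbols
#'   (identity mapping).
#' @param on_missing "fail" (error naming the genes) or "drop".
#' @return expression matrix with one row per matched gene, rows renamed to
#'   the gene symbols; attribute \code{"unmatched"} lists dropped genes.
#' @export
match_genes <- function(genes, expr, annotation = NULL,
                        on_missing = c("fail", "drop")) {
  on_missing <- match.arg(on_missing)
  if (is.null(annotation)) {
    found <- genes[genes %in% rownames(expr)]
    rows <- match(found, rownames(expr))
  } else {
    stopifnot(all(c("probe_id", "gene_symbol") %in% names(annotation)))
    rows <- integer(0)
    found <- character(0)
    for (g in genes) {
      probes <- annotation$probe_id[annotation$gene_symbol == g]
      probes <- probes[probes %in% rownames(expr)]
      if (!length(probes)) next
      mu <- rowMeans(expr[probes, , drop = FALSE])
      rows <- c(rows, match(names(which.max(mu)), rownames(expr)))
      found <- c(found, g)
    }
  }
  unmatched <- setdiff(genes, found)
  if (length(unmatched) && on_missing == "fail")
    stop("signature gene(s) not matched on this platform: ",
         paste(unmatched, collapse = ", "))
  out <- expr[rows, , drop = FALSE]
  rownames(out) <- found
  attr(out, "unmatched") <- unmatched
  out
}

#' Evaluate a signature in one cohort
#'
#' Applies a gene signature to a cohort and scores the predictions against
#' the true outcomes.  With \code{refit_mode = "per-cohort"} (default) the
#' logistic coefficients are refit within the cohort on the fixed gene set,
#' which is the appropriate mode when the validation cohort was measured
#' with a different technique (qRT-PCR) or chip; \code{"frozen"} applies
#' the training coefficients to the cohort's z-scored features.
#'
#' @param genes signature gene ids (used in both modes).
#' @param cohort a `tall_cohort`.
#' @param refit_mode "per-cohort" or "frozen".
#' @param model a trained `signature_model`; required for "frozen",
#'   optional for "per-cohort" (only its cutoff is reused).
#' @param annotation optional probe annotation for [match_genes()].
#' @return list with \code{confusion}, \code{report}, \code{predictions}
#'   and \code{model} (the model actually applied).
#' @export
validate_cohort <- function(genes, cohort,
                            refit_mode = c("per-cohort", "frozen"),
                            model = NULL, annotation = NULL) {
  refit_mode <- match.arg(refit_mode)
  if (!is.null(annotation) || !all(genes %in% rownames(cohort$expression))) {
    matched <- match_genes(genes, cohort$expression, annotation)
    cohort$expression <- rbind(
      cohort$expression[setdiff(rownames(cohort$expression),
                                rownames(matched)), , drop = FALSE],
      matched)
  }
  if (refit_mode == "per-cohort") {
    cutoff <- if (is.null(model)) 0.5 else model$cutoff
    m <- fit_signature_model(cohort, genes, cutoff = cutoff)
  } else {
    if (is.null(model)) stop("frozen mode requires a trained model")
    m <- model
  }
  pred <- predict(m, cohort, rescale = (refit_mode == "frozen"))
  ev <- evaluate_predictions(pred$label, cohort$clinical$label)
  c(ev, list(predictions = pred, model = m))
}

#' Pool confusion tables and compute combined performance
#'
#' Sums the per-cohort confusion tables elementwise and computes the
#' performance panel from the pooled counts; this equals the count-weighted
#' aggregation of the per-cohort numerators and denominators.
#'
#' @param tables list of [confusion_table()]s.
#' @return list with \code{confusion} (pooled) and \code{report}.
#' @export
pooled_performance <- function(tables) {
  if (!length(tables)) stop("no confusion tables supplied")
  ct <- confusion_table(tp = sum(vapply(tables, `[[`, numeric(1), "tp")),
                        fn = sum(vapply(tables, `[[`, numeric(1), "fn")),
                        fp = sum(vapply(tables, `[[`, numeric(1), "fp")),
                        tn = sum(vapply(tables, `[[`, numeric(1), "tn")))
  list(confusion = ct, report = performance_report(ct))
}

#' Combined p-value across cohorts
#'
#' The default global assessment pools the per-cohort confusion tables
#' elementwise and applies the two-sided Fisher exact test to the pooled
#' 2x2 table.  Fisher's method (chi-square combination of the per-cohort
#' exact p-values) is available as an alternative.  Cohorts may be excluded
#' by name (e.g. to drop the training cohort).
#'
#' @param tables named (or unnamed) list of [confusion_table()]s, length
#'   >= 2.
#' @param exclude names or indices of cohorts to exclude.
#' @param method "pooled_fisher" (default) or "fishers_method".
#' @return combined p-value.
#' @export
combined_p <- function(tables, exclude = NULL,
                       method = c("pooled_fisher", "fishers_method")) {
  method <- match.arg(method)
  if (length(tables) < 2) stop("need at least two cohorts to combine")
  if (!is.null(exclude)) {
    keep <- if (is.character(exclude)) !(names(tables) %in% exclude)
            else !(seq_along(tables) %in% exclude)
    tables <- tables[keep]
  }
  if (!length(tables)) stop("all cohorts excluded")
  if (method == "pooled_fisher") {
    pooled_performance(tables)$report$fisher_p
  } else {
    ps <- vapply(tables, fisher_exact_two_sided, numeric(1))
    stat <- -2 * sum(log(ps))
    pchisq(stat, df = 2 * length(ps), lower.tail = FALSE)
  }
}

#' Validate a signature across multiple cohorts
#'
#' Runs [validate_cohort()] on every cohort, pools the confusion tables,
#' and computes the combined exact p with and without the cohorts named in
#' \code{training}.
#'
#' @param genes signature gene ids.
#' @param cohorts named list of `tall_cohort`s.
#' @param refit_mode,model,annotation passed to [validate_cohort()].
#' @param training name(s) of training cohort(s) for the
#'   excluding-training combined p.
#' @return A \code{validation_run}: list with per-cohort results
#'   (\code{cohorts}), \code{pooled}, \code{combined_p_all},
#'   \code{combined_p_excl_training} and \code{refit_mode}.
#' @export
validate_signature <- function(genes, cohorts,
                               refit_mode = c("per-cohort", "frozen"),
                               model = NULL, annotation = NULL,
                               training = NULL) {
  refit_mode <- match.arg(refit_mode)
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  per <- lapply(cohorts, function(co)
    validate_cohort(genes, co, refit_mode = refit_mode, model = model,
                    annotation = annotation))
  tables <- lapply(per, `[[`, "confusion")
  pooled <- pooled_performance(tables)
  p_all <- if (length(tables) >= 2) combined_p(tables) else
    fisher_exact_two_sided(tables[[1]])
  p_ex <- if (!is.null(training) && length(tables) - length(training) >= 1) {
    kept <- tables[!(names(tables) %in% training)]
    if (length(kept) >= 2) combined_p(kept)
    else fisher_exact_two_sided(kept[[1]])
  } else NA_real_
  structure(list(cohorts = per, pooled = pooled,
                 combined_p_all = p_all,
                 combined_p_excl_training = p_ex,
                 refit_mode = refit_mode),
            class = "validation_run")
}

#' @export
print.validation_run <- function(x, ...) {
  cat("multi-cohort validation (", x$refit_mode, " refit)\n", sep = "")
  cat(sprintf("%-12s %4s %4s %4s %4s %4s  %s\n",
              "Cohort", "Acc", "PPV", "NPV", "Sens", "Spec", "P-value"))
  for (nm in names(x$cohorts)) {
    r <- x$cohorts[[nm]]$report
    m <- rounded_metrics(r)
    cat(sprintf("%-12s %4.0f %4.0f %4.0f %4.0f %4.0f  %s\n", nm,
                m["acc"], m["ppv"], m["npv"], m["sens"], m["spec"],
                format_p(r$fisher_p)))
  }
  m <- rounded_metrics(x$pooled$report)
  cat(sprintf("%-12s %4.0f %4.0f %4.0f %4.0f %4.0f  %s", "Combined",
              m["acc"], m["ppv"], m["npv"], m["sens"], m["spec"],
              format_p(x$combined_p_all)))
  if (!is.na(x$combined_p_excl_training))
    cat(" (", format_p(x$combined_p_excl_training), " excl. training)",
        sep = "")
  cat("\n")
  invisible(x)
}
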