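#' Discover a k-gene relapse classifier from a cohort
#'
#' One-call discovery pipeline: ranks all genes by Random-Forest permutation
#' importance, shortlists the top candidates with the platform/detectability
#' filters, exhaustively scores all k-gene combinations by the PC1-vs-outcome
#' r-squared, and refits the top-T combinations with logistic regression,
#' selecting the one with the best training accuracy (ties broken by r2,
#' then by gene ids).
#'
#' @param cohort a `tall_cohort` (both classes present).
#' @param k signature size (default 5).
#' @param top_n ranking depth fed to the shortlist (default 500).
#' @param shortlist_size optional hard cap on the shortlist length (keeps
#'   the best-ranked genes); \code{NULL} keeps all genes that pass the
#'   filters.
#' @param b_chip_threshold,min_mean_expression shortlist filters, see
#'   [apply_shortlist()].
#' @param strategy,max_evals,beam_width search controls, see
#'   [search_combinations()].
#' @param top_t number of top combinations refit by logistic regression.
#' @param n_trees,seed Random-Forest controls, see [rank_genes()].
#' @param cutoff probability cutoff of the final model.
#' @return An object of class \code{gene_classifier}: the selected
#'   `signature_model` plus the ranking, shortlist, combination ranking and
#'   training performance.  Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{plot}.
#' @examples
#' \donttest{
#' co <- simulate_cohort(sim_config(n_genes = 60,
#'   planted_genes = c(g1 = 2, g2 = 2, g3 = 2), seed = 11))
#' cls <- fit_gene_classifier(co, k = 3, top_n = 60, shortlist_size = 12,
#'                            n_trees = 300)
#' cls
#' }
#' @export
fit_gene_classifier <- function(cohort, k = 5L, top_n = 500L,
                                shortlist_size = NULL,
                                b_chip_threshold = 222000L,
                                min_mean_expression = 0,
                                strategy = c("exhaustive", "beam"),
                                max_evals = 1e7, beam_width = 50L,
                                top_t = 100L, n_trees = 1000L,
                                seed = 1L, cutoff = 0.5) {
  strategy <- match.arg(strategy)
  ranking <- rank_genes(cohort, n_trees = n_trees, seed = seed)
  shortlist <- apply_shortlist(ranking, cohort$expression, top_n = top_n,
                               b_chip_threshold = b_chip_threshold,
                               min_mean_expression = min_mean_expression)
  if (!is.null(shortlist_size)) shortlist <- head(shortlist, shortlist_size)
  if (length(shortlist) < k)
    stop("shortlist has fewer than k genes; relax the filters")
  combos <- search_combinations(cohort, shortlist, k = k,
                                strategy = strategy, max_evals = max_evals,
                                beam_width = beam_width, top_t = top_t)
  gene_cols <- seq_len(k)
  best <- NULL
  best_key <- c(-Inf, -Inf)
  truth <- cohort$clinical$label
  for (i in seq_len(nrow(combos))) {
    genes <- as.character(combos[i, gene_cols])
    m <- fit_signature_model(cohort, genes, cutoff = cutoff)
    acc <- evaluate_predictions(predict(m, cohort)$label,
                                truth)$report$accuracy
    key <- c(acc, combos$r2[i])
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2])) {
      best <- list(model = m, genes = genes, r2 = combos$r2[i],
                   accuracy = acc)
      best_key <- key
    }
  }
  pred <- predict(best$model, cohort)
  perf <- evaluate_predictions(pred$label, truth)
  structure(list(
    model = best$model,
    genes = best$genes,
    r2 = best$r2,
    ranking = ranking,
    shortlist = shortlist,
    combos = combos,
    training_performance = perf,
    cohort_n = length(truth),
    call = match.call()
  ), class = "gene_classifier")
}

#' @export
print.gene_classifier <- function(x, ...) {
  cat(length(x$genes), "-gene relapse classifier (", x$cohort_n,
      " training samples)\n", sep = "")
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  cat(sprintf("  PC1 r2 = %.4f\n", x$r2))
  cat("  training performance: ")
  print(x$training_performance$report)
  invisible(x)
}

#' @export
summary.gene_classifier <- function(object, ...) {
  cat("Gene classifier discovery summary\n")
  cat("  shortlist size:", length(object$shortlist), "\n")
  cat("  combinations evaluated:",
      format(attr(object$combos, "n_evaluated"), big.mark = ","), "\n")
  print(object)
  cat("  model coefficients:\n")
  print(round(coef(object), 4))
  invisible(object)
}

#' @export
coef.gene_classifier <- function(object, ...) coef(object$model)

#' @export
predict.gene_classifier <- function(object, cohort, ...) {
  predict(object$model, cohort, ...)
}

#' Kaplan-Meier curves of the predicted outcome groups
#'
#' Plots relapse-free survival curves for the patients the classifier
#' labels R versus CCR, annotated with the log-rank p-value.
#'
#' @param x a `gene_classifier`.
#' @param cohort the cohort to stratify (needs clinical time/event data).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the log-rank test result.
#' @export
plot.gene_classifier <- function(x, cohort, ...) {
  pred <- predict(x, cohort)
  cl <- cohort$clinical
  lr <- logrank_test(cl$time_years, cl$event, pred$label)
  cols <- c(CCR = "#2166ac", R = "#b2182c")
  plot(NA, xlim = c(0, max(cl$time_years)), ylim = c(0, 1),
       xlab = "Years from diagnosis", ylab = "Relapse-free survival",
       main = sprintf("Predicted groups (log-rank p = %.2g)", lr$p), ...)
  for (g in unique(pred$label)) {
    idx <- pred$label == g
    if (!any(idx)) next
    km <- km_estimate(cl$time_years[idx], cl$event[idx])
    lines(stats::stepfun(km$time, c(1, km$survival)), do.points = FALSE,
          col = cols[[g]], lwd = 2)
  }
  legend("bottomleft", legend = names(cols), col = cols, lwd = 2, bty = "n")
  invisible(lr)
}
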