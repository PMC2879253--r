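# Logistic signature models, the confusion-table performance panel, and the
# two-sided Fisher exact test (point-probability method).

# round half away from zero to integer percent (printed-table convention:
# 62.5 -> 63, unlike banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# ridge-penalized logistic fit by iteratively reweighted least squares;
# intercept unpenalized.  Used as the perfect-separation fallback.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100L,
                           tol = 1e-10) {
  Xd <- cbind(1, X)
  pen <- diag(c(0, rep(lambda, ncol(X))))
  beta <- numeric(ncol(Xd))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, Xd * w) + 2 * pen
    g <- crossprod(Xd, y - mu) - 2 * pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Fit a logistic signature model on a gene set
#'
#' Maximum-likelihood logistic regression of the relapse indicator on
#' per-gene z-scored log2 expression.  If the fit separates perfectly (glm
#' reports fitted probabilities numerically 0 or 1), the model is refit with
#' a weak L2 penalty (lambda = 1e-4 on the standardized features, intercept
#' unpenalized) and flagged.
#'
#' @param cohort a `tall_cohort` with both classes present.
#' @param genes gene ids to use as predictors.
#' @param cutoff probability cutoff for the R label, in (0, 1); default 0.5.
#' @param lambda ridge penalty used only on separation fallback.
#' @return An object of class \code{signature_model}: genes, coefficients
#'   (per gene, on the z-scored log2 scale), intercept, cutoff, the per-gene
#'   centering/scaling used, a \code{separation} flag, and the training
#'   platform tag.
#' @examples
#' co <- simulate_cohort(sim_config(n_genes = 50, seed = 3))
#' m <- fit_signature_model(co, names(sim_config()$planted_genes))
#' m
#' @export
fit_signature_model <- function(cohort, genes, cutoff = 0.5,
                                lambda = 1e-4) {
  stopifnot(cutoff > 0, cutoff < 1)
  y <- outcome_indicator(cohort)
  if (length(unique(y)) < 2)
    stop("both outcome classes are required to fit a model")
  z <- zscore_log2(cohort$expression, genes)
  genes <- rownames(z)
  X <- t(z)
  dat <- data.frame(y = y, X, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  # glm does not always warn on separation; fitted probabilities driven to
  # the boundary are the reliable symptom
  mu <- fitted(fit)
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) separated <- TRUE
  if (separated || any(!is.finite(coef(fit)))) {
    separated <- TRUE
    beta <- ridge_logistic(X, y, lambda = lambda)
  } else {
    beta <- coef(fit)
  }
  lx <- log2(cohort$expression[genes, , drop = FALSE])
  structure(list(
    genes = genes,
    coefficients = setNames(as.numeric(beta[-1]), genes),
    intercept = unname(beta[1]),
    cutoff = cutoff,
    center = rowMeans(lx),
    scale = apply(lx, 1, sd),
    separation = separated,
    training_platform = cohort$platform,
    n_train = length(y)
  ), class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("logistic signature model (", length(x$genes), " genes, trained on ",
      x$n_train, " samples, platform '", x$training_platform, "')\n",
      sep = "")
  cat("  cutoff:", x$cutoff,
      if (x$separation) " [perfect separation: ridge fallback]", "\n")
  print(round(c("(Intercept)" = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' @export
coef.signature_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict relapse probabilities and labels for a cohort
#'
#' Computes per-sample relapse probabilities from the logistic model and
#' converts them to labels at the model cutoff.  A probability exactly at
#' the cutoff is classified as R (conservative toward detecting relapse).
#' By default features are standardized with the cohort's own per-gene
#' log2 means and sds (appropriate when scales differ across platforms);
#' set \code{rescale = FALSE} to reuse the training centering/scaling.
#'
#' @param object a `signature_model`.
#' @param cohort a `tall_cohort` containing every model gene.
#' @param rescale standardize with the new cohort's statistics (default) or
#'   the training statistics.
#' @param ... unused.
#' @return data.frame with columns \code{sample}, \code{probability},
#'   \code{label}.
#' @export
predict.signature_model <- function(object, cohort, rescale = TRUE, ...) {
  missing <- setdiff(object$genes, rownames(cohort$expression))
  if (length(missing))
    stop("cohort is missing model gene(s): ",
         paste(missing, collapse = ", "))
  lx <- log2(cohort$expression[object$genes, , drop = FALSE])
  if (rescale) {
    ctr <- rowMeans(lx)
    scl <- apply(lx, 1, sd)
  } else {
    ctr <- object$center
    scl <- object$scale
  }
  scl[scl == 0] <- 1
  z <- (lx - ctr) / scl
  eta <- object$intercept + drop(crossprod(z, object$coefficients))
  prob <- 1 / (1 + exp(-eta))
  data.frame(sample = cohort$clinical$sample,
             probability = prob,
             label = ifelse(prob >= object$cutoff, "R", "CCR"),
             stringsAsFactors = FALSE)
}

#' Confusion table for relapse prediction
#'
#' The positive class is relapse: tp counts patients predicted R who
#' relapsed, tn patients predicted CCR who stayed in remission.
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return object of class \code{confusion_table}.
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(setNames(as.integer(counts), names(counts))),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("R", "CCR"),
                              observed = c("R", "CCR")))
  print(m)
  invisible(x)
}

as_matrix_ct <- function(ct) matrix(c(ct$tp, ct$fp, ct$fn, ct$tn), 2, 2)

#' Two-sided Fisher exact test on a confusion table
#'
#' Exact two-sided p-value by the point-probability method: with margins
#' fixed, the hypergeometric probabilities of all tables whose point
#' probability does not exceed that of the observed table (up to a relative
#' tolerance of 1e-7 guarding floating-point ties) are summed.  A zero
#' margin means no association is testable and returns p = 1.
#'
#' @param ct a [confusion_table()] (or a list with tp/fn/fp/tn).
#' @return the exact two-sided p-value.
#' @export
fisher_exact_two_sided <- function(ct) {
  tp <- ct$tp; fn <- ct$fn; fp <- ct$fp; tn <- ct$tn
  m <- tp + fn      # true relapsers
  n <- fp + tn      # true CCR
  k <- tp + fp      # predicted R
  if (m == 0 || n == 0 || k == 0 || (fn + tn) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tp, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Performance panel from predicted and true labels
#'
#' Builds the confusion table (positive class = R) and the standard panel:
#' accuracy, PPV, NPV, sensitivity and specificity as percentages, plus the
#' two-sided Fisher exact p for model performance.  Percentages are exact;
#' the print method rounds them half-up to integer percent as in published
#' validation tables (see [rounded_metrics()]).
#'
#' @param predicted,truth character vectors of "R"/"CCR" labels, equal
#'   length.
#' @return list with components \code{confusion} (a `confusion_table`) and
#'   \code{report} (a `performance_report`).
#' @export
evaluate_predictions <- function(predicted, truth) {
  if (!length(predicted) || length(predicted) != length(truth))
    stop("predicted and truth must be non-empty and of equal length")
  if (!all(predicted %in% c("R", "CCR")) || !all(truth %in% c("R", "CCR")))
    stop("labels must be 'R' or 'CCR'")
  ct <- confusion_table(tp = sum(predicted == "R" & truth == "R"),
                        fn = sum(predicted == "CCR" & truth == "R"),
                        fp = sum(predicted == "R" & truth == "CCR"),
                        tn = sum(predicted == "CCR" & truth == "CCR"))
  list(confusion = ct, report = performance_report(ct))
}

#' Performance report from a confusion table
#'
#' @param ct a [confusion_table()].
#' @return object of class \code{performance_report}: accuracy, ppv, npv,
#'   sensitivity, specificity (exact percentages; NA where the denominator
#'   is empty), fisher_p and n.
#' @export
performance_report <- function(ct) {
  n <- ct$tp + ct$fn + ct$fp + ct$tn
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(list(
    accuracy = pct(ct$tp + ct$tn, n),
    ppv = pct(ct$tp, ct$tp + ct$fp),
    npv = pct(ct$tn, ct$tn + ct$fn),
    sensitivity = pct(ct$tp, ct$tp + ct$fn),
    specificity = pct(ct$tn, ct$tn + ct$fp),
    fisher_p = fisher_exact_two_sided(ct),
    n = n
  ), class = "performance_report")
}

#' Integer-percent metrics of a performance report
#'
#' Rounds the five panel metrics half-up to integer percent, the convention
#' of published validation tables.
#'
#' @param report a `performance_report`.
#' @return named numeric vector (acc, ppv, npv, sens, spec).
#' @export
rounded_metrics <- function(report) {
  round_half_up(c(acc = report$accuracy, ppv = report$ppv,
                  npv = report$npv, sens = report$sensitivity,
                  spec = report$specificity))
}

format_p <- function(p) {
  if (is.na(p)) "NA"
  else if (p < 1e-4) format(signif(p, 2), scientific = TRUE)
  else as.character(signif(p, 2))
}

#' @export
print.performance_report <- function(x, ...) {
  m <- rounded_metrics(x)
  cat(sprintf("n=%d  Acc %s  PPV %s  NPV %s  Sens %s  Spec %s  P %s\n",
              x$n, m["acc"], m["ppv"], m["npv"], m["sens"], m["spec"],
              format_p(x$fisher_p)))
  invisible(x)
}

#' Reconstruct a confusion table from printed sensitivity/specificity
#'
#' Given the class sizes and the integer-percent sensitivity and specificity
#' of a published row, finds the integer counts tp and tn that round
#' (half-up) to the printed values.  Errors if no solution exists or if it
#' is ambiguous, listing the candidates.
#'
#' @param n_relapse,n_ccr class sizes.
#' @param sensitivity,specificity printed integer percentages.
#' @return the unique [confusion_table()].
#' @export
confusion_from_metrics <- function(n_relapse, n_ccr, sensitivity,
                                   specificity) {
  tp <- which(round_half_up(100 * (0:n_relapse) / n_relapse) == sensitivity) - 1L
  tn <- which(round_half_up(100 * (0:n_ccr) / n_ccr) == specificity) - 1L
  if (length(tp) != 1)
    stop("ambiguous or impossible tp reconstruction; candidates: ",
         paste(tp, collapse = ", "))
  if (length(tn) != 1)
    stop("ambiguous or impossible tn reconstruction; candidates: ",
         paste(tn, collapse = ", "))
  confusion_table(tp = tp, fn = n_relapse - tp,
                  fp = n_ccr - tn, tn = tn)
}

#' Serialize / restore a signature model as JSON
#' @param model a `signature_model`.
#' @param path file path.
#' @return invisibly `path`; `read_signature_model` returns the model.
#' @export
write_signature_model <- function(model, path) {
  x <- unclass(model)
  # named vectors must become JSON objects, not bare arrays
  for (f in c("coefficients", "center", "scale")) x[[f]] <- as.list(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$coefficients <- unlist(m$coefficients)
  m$center <- unlist(m$center)
  m$scale <- unlist(m$scale)
  class(m) <- "signature_model"
  m
}
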