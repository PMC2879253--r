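# Survival validation: Kaplan-Meier curves, log-rank comparison of
# predicted groups, univariate Cox regression on the relapse probability,
# and single-gene tertile stratification.  Backed by the survival package
# (product-limit estimator, score test, Efron ties).

#' Kaplan-Meier product-limit estimate
#'
#' @param time event/censoring times (> 0), years.
#' @param event 0/1 event indicators (1 = relapse).
#' @return A \code{km_curve}: data.frame with columns \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{survival}
#'   (one row per distinct time), carrying the underlying
#'   \code{survival::survfit} object as attribute \code{"fit"}.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("no records")
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  attr(out, "fit") <- fit
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test between survival groups
#'
#' Standard (unweighted) log-rank chi-square with \code{k - 1} degrees of
#' freedom for k groups.  If no events occurred in any group the test is
#' vacuous and p = 1 is returned.
#'
#' @param time,event aligned survival data as in [km_estimate()].
#' @param group per-record group labels (>= 2 non-empty groups).
#' @return list with \code{chisq}, \code{df} and \code{p}.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("need at least two non-empty groups")
  if (sum(event) == 0)
    return(list(chisq = 0, df = nlevels(droplevels(group)) - 1L, p = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit of the hazard on a single continuous covariate
#' (typically the modeled relapse probability), Efron tie handling, Wald
#' 95\% confidence interval and p-value.  Monotone-likelihood fits (the
#' covariate perfectly orders the events) are flagged rather than failed.
#'
#' @param x covariate values aligned with the records.
#' @param time,event survival data as in [km_estimate()].
#' @return A \code{cox_result}: list with \code{hazard_ratio},
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{log_hr}, \code{se} and
#'   a \code{monotone} flag.
#' @export
cox_univariate <- function(x, time, event) {
  stopifnot(length(x) == length(time), length(time) == length(event))
  if (sd(x) == 0) stop("covariate has no variation")
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  zcrit <- qnorm(0.975)
  structure(list(
    hazard_ratio = exp(beta),
    ci_low = exp(beta - zcrit * se),
    ci_high = exp(beta + zcrit * se),
    p = 2 * pnorm(-abs(beta / se)),
    log_hr = beta, se = se,
    monotone = monotone
  ), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  p_str <- if (x$p < 1e-4) "<0.0001" else sprintf("%.4g", x$p)
  cat(sprintf("HR %.3g (95%% CI %.3g, %.3g), p %s%s\n",
              x$hazard_ratio, x$ci_low, x$ci_high, p_str,
              if (x$monotone) " [monotone likelihood]" else ""))
  invisible(x)
}

#' Split values into expression tertiles
#'
#' Assigns each value to the lower, middle or upper third by the empirical
#' 33.3 / 66.7 percentiles.  A value tied with a boundary goes to the lower
#' tertile.
#'
#' @param values numeric vector with at least 3 distinct values.
#' @return factor with ordered levels \code{low}, \code{mid}, \code{high}.
#' @export
tertile_groups <- function(values) {
  if (length(unique(values)) < 3)
    stop("need at least 3 distinct values to form tertiles")
  q <- quantile(values, c(1, 2) / 3, names = FALSE)
  factor(ifelse(values <= q[1], "low",
                ifelse(values <= q[2], "mid", "high")),
         levels = c("low", "mid", "high"))
}

#' Write a Kaplan-Meier curve as TSV
#' @param curve a `km_curve`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_km_curve <- function(curve, path) {
  write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
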