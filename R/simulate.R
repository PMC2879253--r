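#' Simulation configuration for synthetic T-ALL cohorts
#'
#' Describes a two-class (relapse vs CCR) cohort with planted signature genes
#' at specified linear fold changes, log-normal relapse times and uniform
#' censoring times.  Defaults reproduce the structure of a typical training
#' cohort in pediatric T-ALL outcome studies: n = 50 with a 44\% relapse
#' fraction (22 relapse / 28 CCR), relapse times with median 1.3 years in
#' 0.2--3.8, follow-up (censoring) times with median 7.3 years in 3.3--9.2,
#' and the five-gene relapse signature (ABTB2, IL7R, LGALS8, PLAC8, FAM13A1)
#' planted at its reported array fold changes.
#'
#' Expression is generated per gene as Gaussian log2 intensities (baseline
#' mean drawn from \code{N(base_log2_mean, base_log2_sd)}, within-class noise
#' \code{noise_sd}) and exponentiated to the linear scale, matching RMA
#' conventions.  A planted gene with fold change f has its relapse-class log2
#' mean shifted by log2(f), so the expected ratio of linear class means is
#' exactly f (equal class variances).
#'
#' @param n_patients cohort size; the relapse class gets
#'   \code{round(n_patients * relapse_fraction)} patients (deterministic
#'   split, so the canonical 22/28 split is exact at the defaults).
#' @param relapse_fraction fraction of patients who relapse, in (0, 1).
#' @param n_genes number of genes in the simulated universe.
#' @param planted_genes named numeric vector: names are gene ids, values are
#'   linear R/CCR fold changes (> 0).  Names not of the form
#'   \code{gene_000i} must still be members of the generated universe; the
#'   first \code{length(planted_genes)} universe slots are renamed to the
#'   planted ids.
#' @param base_log2_mean,base_log2_sd mean and sd of per-gene baseline log2
#'   intensities.
#' @param noise_sd within-class log2 sd (applies to every gene).
#' @param platform_shift sd of a per-gene log2 additive bias (multiplicative
#'   on the linear scale) emulating a platform difference; 0 disables it.
#' @param qpcr_target_r default target correlation for
#'   \code{\link{emulate_requantification}}, in (0, 1].
#' @param relapse_time_median_years,relapse_time_range median and
#'   (min, max) truncation range of log-normal relapse times, years.
#' @param followup_median_years,followup_range median and (min, max) range
#'   of censoring (follow-up) times for CCR patients, years.
#' @param seed integer RNG seed; fixed seed gives byte-identical cohorts.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 50L,
                       relapse_fraction = 0.44,
                       n_genes = 1000L,
                       planted_genes = c(ABTB2 = 1.34, IL7R = 0.54,
                                         LGALS8 = 0.85, PLAC8 = 0.54,
                                         FAM13A1 = 0.83),
                       base_log2_mean = 8,
                       base_log2_sd = 1.5,
                       noise_sd = 1,
                       platform_shift = 0,
                       qpcr_target_r = 0.92,
                       relapse_time_median_years = 1.3,
                       relapse_time_range = c(0.2, 3.8),
                       followup_median_years = 7.3,
                       followup_range = c(3.3, 9.2),
                       seed = 1L) {
  stopifnot(n_patients >= 2, n_genes >= 1)
  if (!(relapse_fraction > 0 && relapse_fraction < 1))
    stop("relapse_fraction must lie strictly in (0, 1)")
  if (length(planted_genes)) {
    if (is.null(names(planted_genes)) || any(!nzchar(names(planted_genes))))
      stop("planted_genes must be a named vector of fold changes")
    if (any(planted_genes <= 0))
      stop("all planted fold changes must be > 0")
    if (length(planted_genes) > n_genes)
      stop("more planted genes than genes in the universe")
  }
  if (!(qpcr_target_r > 0 && qpcr_target_r <= 1))
    stop("qpcr_target_r must lie in (0, 1]")
  stopifnot(length(relapse_time_range) == 2,
            relapse_time_range[1] > 0,
            relapse_time_range[1] < relapse_time_range[2],
            length(followup_range) == 2,
            followup_range[1] > 0,
            followup_range[1] < followup_range[2],
            noise_sd >= 0, base_log2_sd >= 0, platform_shift >= 0)
  n_relapse <- round(n_patients * relapse_fraction)
  if (n_relapse < 2 || n_patients - n_relapse < 2)
    stop("degenerate cohort: fewer than 2 patients in a class; ",
         "increase n_patients or adjust relapse_fraction")
  structure(list(
    n_patients = as.integer(n_patients),
    relapse_fraction = relapse_fraction,
    n_relapse = as.integer(n_relapse),
    n_genes = as.integer(n_genes),
    planted_genes = planted_genes,
    base_log2_mean = base_log2_mean,
    base_log2_sd = base_log2_sd,
    noise_sd = noise_sd,
    platform_shift = platform_shift,
    qpcr_target_r = qpcr_target_r,
    relapse_time_median_years = relapse_time_median_years,
    relapse_time_range = relapse_time_range,
    followup_median_years = followup_median_years,
    followup_range = followup_range,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# truncated log-normal draw with a given median (truncation bounds in years)
rtrunc_lnorm <- function(n, median, range, sdlog = NULL) {
  meanlog <- log(median)
  if (is.null(sdlog)) # spread so ~99% of the untruncated mass is in range
    sdlog <- (log(range[2]) - log(range[1])) / (2 * qnorm(0.995))
  lo <- plnorm(range[1], meanlog, sdlog)
  hi <- plnorm(range[2], meanlog, sdlog)
  qlnorm(runif(n, lo, hi), meanlog, sdlog)
}

#' Simulate a two-class expression + survival cohort
#'
#' Generates a `tall_cohort`: a genes-by-samples matrix of positive linear
#' intensities, an aligned clinical table (outcome label, time-to-event,
#' event flag, age, WBC, sex), a platform tag and the list of planted genes.
#' Relapse patients receive log-normal relapse times (event = 1); CCR
#' patients receive uniform censoring times within the follow-up range
#' (event = 0).  Clinical covariates are drawn to plausible pediatric T-ALL
#' distributions but carry no outcome signal.
#'
#' @param config a [sim_config()] object.
#' @param platform free-text platform tag stored on the cohort.
#' @return An object of class \code{tall_cohort}: a list with components
#'   \code{expression} (matrix, genes x samples), \code{clinical}
#'   (data.frame with columns sample, label, time_years, event, age, wbc,
#'   sex), \code{platform} and \code{truth} (planted gene ids).
#' @examples
#' co <- simulate_cohort(sim_config(seed = 7))
#' co
#' @export
simulate_cohort <- function(config, platform = "synthetic-array") {
  stopifnot(inherits(config, "sim_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_patients
  n_r <- config$n_relapse
  n_c <- n - n_r
  p <- config$n_genes
  genes <- sprintf("gene_%04d", seq_len(p))
  planted <- config$planted_genes
  if (length(planted)) {
    extra <- setdiff(names(planted), genes)
    if (length(extra) > length(genes))
      stop("planted gene not in universe: ", paste(extra, collapse = ", "))
    # planted ids occupy the leading universe slots
    genes[seq_along(planted)] <- names(planted)
  }
  samples <- sprintf("S%03d", seq_len(n))
  label <- c(rep("R", n_r), rep("CCR", n_c))

  base_mu <- rnorm(p, config$base_log2_mean, config$base_log2_sd)
  names(base_mu) <- genes
  shift <- setNames(numeric(p), genes)
  if (length(planted)) shift[names(planted)] <- log2(planted)
  mu <- outer(base_mu, numeric(n), `+`)              # genes x samples
  mu[, label == "R"] <- mu[, label == "R"] + shift   # recycled by column
  log2e <- mu + matrix(rnorm(p * n, 0, config$noise_sd), p, n)
  if (config$platform_shift > 0)
    log2e <- log2e + rnorm(p, 0, config$platform_shift)
  expr <- 2^log2e
  dimnames(expr) <- list(genes, samples)

  time <- numeric(n)
  time[label == "R"] <- rtrunc_lnorm(n_r, config$relapse_time_median_years,
                                     config$relapse_time_range)
  time[label == "CCR"] <- runif(n_c, config$followup_range[1],
                                config$followup_range[2])
  clinical <- data.frame(
    sample = samples,
    label = label,
    time_years = time,
    event = as.integer(label == "R"),
    age = pmin(pmax(rlnorm(n, log(10), 0.55), 1), 18),
    wbc = pmin(pmax(rlnorm(n, log(150), 0.9), 1), 900),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.75, 0.25)),
    stringsAsFactors = FALSE
  )
  structure(list(expression = expr, clinical = clinical,
                 platform = platform,
                 truth = names(planted)),
            class = "tall_cohort")
}

#' @export
print.tall_cohort <- function(x, ...) {
  tab <- table(x$clinical$label)
  cat("T-ALL cohort:", ncol(x$expression), "samples x",
      nrow(x$expression), "genes [", x$platform, "]\n")
  cat("  outcome: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  if (length(x$truth))
    cat("  planted genes:", paste(x$truth, collapse = ", "), "\n")
  invisible(x)
}

#' Extract outcome labels as a relapse indicator
#'
#' @param cohort a `tall_cohort`.
#' @return integer vector, 1 = relapse (R), 0 = CCR.
#' @export
outcome_indicator <- function(cohort) {
  as.integer(cohort$clinical$label == "R")
}

#' Emulate re-measurement of expression on a second platform (e.g. qRT-PCR)
#'
#' Returns a same-shape matrix of positive intensities whose per-gene log2
#' Pearson correlation with the input has expectation \code{target_r}.  On
#' the log2 scale each gene is regenerated as
#' \code{target_r * z + sqrt(1 - target_r^2) * noise} around its own mean and
#' sd, so rank structure is preserved on average and \code{target_r = 1}
#' returns the input up to a per-gene affine transform.  Genes with zero
#' variance cannot carry a correlation; they are copied through and flagged
#' in the \code{"degenerate_genes"} attribute of the result.
#'
#' @param expr matrix of positive linear intensities, genes x samples.
#' @param target_r target per-gene correlation, in (0, 1].
#' @param seed integer RNG seed.
#' @return matrix like \code{expr}, with attribute \code{degenerate_genes}.
#' @export
emulate_requantification <- function(expr, target_r, seed = 1L) {
  if (any(expr <= 0)) stop("expression intensities must be positive")
  if (!(target_r > 0 && target_r <= 1))
    stop("target_r must lie in (0, 1]")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lx <- log2(expr)
  m <- rowMeans(lx)
  s <- apply(lx, 1, sd)
  degen <- s == 0
  z <- (lx - m) / ifelse(s == 0, 1, s)
  noise <- matrix(rnorm(length(lx)), nrow(lx), ncol(lx))
  zy <- target_r * z + sqrt(1 - target_r^2) * noise
  ly <- m + ifelse(s == 0, 1, s) * zy
  ly[degen, ] <- lx[degen, ]
  out <- 2^ly
  dimnames(out) <- dimnames(expr)
  attr(out, "degenerate_genes") <- rownames(expr)[degen]
  out
}

#' Simulate a cohort in which low expression of one gene raises the hazard
#'
#' Emulates the adverse-outcome pattern seen for low IL-7R expression: a
#' continuous marker gene is drawn per patient and patients in its lowest
#' tertile relapse at \code{hazard_ratio} times the baseline hazard.  Event
#' times are exponential, censored by a uniform follow-up window.
#'
#' @param n number of patients.
#' @param hazard_ratio hazard multiplier for the lowest-tertile group
#'   (default 2, i.e. hazard doubling).
#' @param baseline_hazard events per year for the reference group.
#' @param followup_years (min, max) of the uniform censoring window.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{marker} (log2 expression),
#'   \code{time_years}, \code{event}.
#' @seealso [tertile_groups()]
#' @export
simulate_marker_hazard_cohort <- function(n = 150L, hazard_ratio = 2,
                                          baseline_hazard = 0.15,
                                          followup_years = c(1, 10),
                                          seed = 1L) {
  stopifnot(n >= 9, hazard_ratio > 0, baseline_hazard > 0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  marker <- rnorm(n, 8, 1)
  low <- marker <= quantile(marker, 1/3)
  haz <- baseline_hazard * ifelse(low, hazard_ratio, 1)
  t_event <- rexp(n, haz)
  t_cens <- runif(n, followup_years[1], followup_years[2])
  data.frame(marker = marker,
             time_years = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Write a cohort to plain-text files
#'
#' Expression goes to a tab-delimited genes x samples matrix (first column
#' \code{gene}, header = sample ids); the clinical table to CSV with columns
#' sample, label, time_years, event, age, wbc, sex.
#'
#' @param cohort a `tall_cohort`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ef <- file.path(dir, paste0(prefix, "_expression.tsv"))
  cf <- file.path(dir, paste0(prefix, "_clinical.csv"))
  df <- data.frame(gene = rownames(cohort$expression),
                   cohort$expression, check.names = FALSE)
  write.table(df, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(cohort$clinical, cf, row.names = FALSE)
  invisible(c(expression = ef, clinical = cf))
}

#' Read a cohort back from the files written by [write_cohort()]
#'
#' @param expression_file tab-delimited genes x samples matrix.
#' @param clinical_file CSV clinical table.
#' @param platform platform tag to attach.
#' @return a `tall_cohort`.
#' @export
read_cohort <- function(expression_file, clinical_file,
                        platform = "unknown") {
  df <- read.delim(expression_file, check.names = FALSE)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df[[1]]
  clinical <- read.csv(clinical_file, stringsAsFactors = FALSE)
  if (ncol(expr) != nrow(clinical))
    stop("expression columns and clinical rows do not align")
  structure(list(expression = expr, clinical = clinical,
                 platform = platform, truth = character()),
            class = "tall_cohort")
}
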