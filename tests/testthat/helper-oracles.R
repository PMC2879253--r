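# Independent oracles used across test files.  These deliberately take the
# slow, textbook route so they share no code with the package internals.

# product-limit estimator computed step by step from first principles
km_oracle <- function(time, event) {
  ord <- order(time, -event)  # events before censorings at tied times
  time <- time[ord]; event <- event[ord]
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    t <- times[i]
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = times, survival = surv)
}

# two-sided Fisher exact p by brute-force enumeration of all tables with
# the observed margins, using factorials directly
fisher_oracle <- function(tp, fn, fp, tn) {
  m <- tp + fn; n <- fp + tn; k <- tp + fp
  if (m == 0 || n == 0 || k == 0 || fn + tn == 0) return(1)
  table_prob <- function(a) {
    b <- k - a; c <- m - a; d <- n - b
    if (b < 0 || c < 0 || d < 0) return(NA_real_)
    exp(lchoose(m, a) + lchoose(n, b) - lchoose(m + n, k))
  }
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, table_prob, numeric(1))
  p_obs <- table_prob(tp)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# step-by-step weighted KS running sum (explicit loop, no cumsum)
es_oracle <- function(scores, gene_set, weight = 1) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  N <- length(s); nh <- sum(hit)
  denom_hit <- sum(abs(s[hit])^weight)
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (hit[i]) cur <- cur + abs(s[i])^weight / denom_hit
    else cur <- cur - 1 / (N - nh)
    running[i] <- cur
  }
  peak <- which.max(abs(running))
  list(es = running[peak], running_sum = running, peak_index = peak)
}

# small planted-signature cohort used by several files
planted_cohort <- function(seed, n_genes = 200, fold = 2,
                           n_planted = 5, n_patients = 50,
                           noise_sd = 1) {
  planted <- setNames(rep(fold, n_planted),
                      sprintf("planted_%02d", seq_len(n_planted)))
  simulate_cohort(sim_config(n_patients = n_patients,
                             relapse_fraction = 0.44,
                             n_genes = n_genes,
                             planted_genes = planted,
                             noise_sd = noise_sd,
                             seed = seed))
}
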