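test_that("gene matching picks the highest-mean probe and reports failures", {
  expr <- rbind("p1_a" = rep(100, 4), "p1_b" = rep(80, 4),
                "p2" = rep(50, 4))
  colnames(expr) <- paste0("s", 1:4)
  ann <- data.frame(probe_id = c("p1_a", "p1_b", "p2"),
                    gene_symbol = c("IL7R", "IL7R", "PLAC8"))
  m <- match_genes(c("IL7R", "PLAC8"), expr, ann)
  expect_identical(rownames(m), c("IL7R", "PLAC8"))
  expect_equal(unname(m["IL7R", 1]), 100)  # max-mean probe chosen
  # identity mapping when rows are already symbols
  expr2 <- rbind(IL7R = 1:4, PLAC8 = 5:8)
  m2 <- match_genes(c("IL7R", "PLAC8"), expr2)
  expect_equal(m2, expr2, ignore_attr = TRUE)
  # absent symbol: error naming it, or dropped on request
  expect_error(match_genes(c("IL7R", "ABTB2"), expr2), "ABTB2")
  m3 <- match_genes(c("IL7R", "ABTB2"), expr2, on_missing = "drop")
  expect_identical(attr(m3, "unmatched"), "ABTB2")
})

test_that("pooled counts equal elementwise sums and metrics come from pooled counts", {
  t1 <- confusion_table(17, 5, 4, 24)
  t2 <- confusion_table(2, 7, 0, 25)
  pooled <- pooled_performance(list(t1, t2))
  expect_equal(unlist(pooled$confusion[c("tp", "fn", "fp", "tn")]),
               c(tp = 19, fn = 12, fp = 4, tn = 49))
  # pooled metric = count-weighted aggregation of numerators/denominators
  expect_equal(pooled$report$sensitivity, 100 * 19 / 31, tolerance = 1e-12)
  expect_equal(pooled$report$accuracy, 100 * 68 / 84, tolerance = 1e-12)
  # single cohort: identical to its own report
  solo <- pooled_performance(list(t1))
  expect_equal(solo$report$accuracy,
               performance_report(t1)$accuracy, tolerance = 1e-15)
})

test_that("pooling the reconstructed cohort tables reproduces every Combined row", {
  perf <- reference_performance()
  for (mod in unique(perf$model)) {
    rows <- perf[perf$model == mod & perf$cohort != "Combined", ]
    comb <- perf[perf$model == mod & perf$cohort == "Combined", ]
    tables <- lapply(seq_len(nrow(rows)), function(i)
      confusion_from_metrics(rows$n_relapse[i], rows$n_ccr[i],
                             rows$sensitivity[i], rows$specificity[i]))
    pooled <- pooled_performance(tables)
    m <- rounded_metrics(pooled$report)
    expect_equal(unname(m),
                 unlist(comb[c("accuracy", "ppv", "npv", "sensitivity",
                               "specificity")], use.names = FALSE),
                 info = mod)
  }
})

test_that("the combined exact p matches the published magnitudes and conventions", {
  perf <- reference_performance()
  rows <- perf[perf$model == "5-GC" & perf$cohort != "Combined", ]
  tables <- lapply(seq_len(nrow(rows)), function(i)
    confusion_from_metrics(rows$n_relapse[i], rows$n_ccr[i],
                           rows$sensitivity[i], rows$specificity[i]))
  names(tables) <- rows$cohort
  expect_equal(signif(combined_p(tables), 2), 1.5e-9)
  expect_equal(signif(combined_p(tables, exclude = "Training"), 2), 1.2e-4)
  # permutation invariance to cohort order
  expect_equal(combined_p(tables), combined_p(rev(tables)), tolerance = 1e-15)
  # two no-association tables combine to p = 1
  null_t <- confusion_table(5, 5, 5, 5)
  expect_equal(combined_p(list(null_t, null_t)), 1)
  # Fisher's-method alternative runs and is a valid probability
  pm <- combined_p(tables, method = "fishers_method")
  expect_true(pm > 0 && pm < 1)
  expect_error(combined_p(tables[1]), "two cohorts")
})

test_that("per-cohort refit transfers accuracy to independent cohorts", {
  planted <- setNames(rep(2, 5), sprintf("planted_%02d", 1:5))
  accs <- vapply(1:5, function(s) {
    train <- simulate_cohort(sim_config(n_genes = 60, planted_genes = planted,
                                        seed = 600 + s))
    test <- simulate_cohort(sim_config(n_genes = 60, planted_genes = planted,
                                       platform_shift = 0.5,
                                       seed = 700 + s),
                            platform = "shifted-array")
    m <- fit_signature_model(train, names(planted))
    tr_acc <- evaluate_predictions(predict(m, train)$label,
                                   train$clinical$label)$report$accuracy
    va <- validate_cohort(names(planted), test, refit_mode = "per-cohort",
                          model = m)
    va$report$accuracy - tr_acc
  }, numeric(1))
  expect_gte(mean(abs(accs) <= 15), 0.8)
})

test_that("shuffled labels pull external accuracy to the prevalence ceiling", {
  planted <- setNames(rep(2, 5), sprintf("planted_%02d", 1:5))
  test <- simulate_cohort(sim_config(n_genes = 60, planted_genes = planted,
                                     n_patients = 200, seed = 801))
  set.seed(9)
  test$clinical$label <- sample(test$clinical$label)
  test$clinical$event <- as.integer(test$clinical$label == "R")
  va <- validate_cohort(names(planted), test)
  expect_lt(va$report$accuracy, 75)  # prevalence ceiling is 56%
})

test_that("frozen coefficients without restandardization degrade on shifted platforms", {
  planted <- setNames(rep(2.5, 5), sprintf("planted_%02d", 1:5))
  deg <- vapply(1:5, function(s) {
    train <- simulate_cohort(sim_config(n_genes = 40, planted_genes = planted,
                                        noise_sd = 0.8, seed = 900 + s))
    test <- simulate_cohort(sim_config(n_genes = 40, planted_genes = planted,
                                       noise_sd = 0.8, platform_shift = 2,
                                       seed = 950 + s))
    m <- fit_signature_model(train, names(planted))
    raw <- predict(m, test, rescale = FALSE)   # training centering on shifted data
    std <- predict(m, test, rescale = TRUE)
    acc <- function(p) evaluate_predictions(p$label,
                                            test$clinical$label)$report$accuracy
    acc(std) - acc(raw)
  }, numeric(1))
  expect_gt(mean(deg), 0)  # restandardizing recovers accuracy on average
})

test_that("multi-cohort validation pools counts and reports both combined p-values", {
  planted <- setNames(rep(2, 5), sprintf("planted_%02d", 1:5))
  cohorts <- list(
    Training = simulate_cohort(sim_config(n_genes = 40,
                                          planted_genes = planted, seed = 71)),
    External = simulate_cohort(sim_config(n_genes = 40, n_patients = 40,
                                          relapse_fraction = 0.35,
                                          planted_genes = planted, seed = 72)))
  vr <- validate_signature(names(planted), cohorts, training = "Training")
  sums <- Reduce(`+`, lapply(vr$cohorts, function(x) unlist(x$confusion)))
  expect_equal(unlist(vr$pooled$confusion), sums)
  expect_true(vr$combined_p_all > 0 && vr$combined_p_all <= 1)
  expect_true(vr$combined_p_excl_training > 0)
  expect_output(print(vr), "Combined")
})
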