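test_that("the performance panel reproduces published validation rows", {
  # training-cohort row: 22 relapse / 28 CCR
  r <- performance_report(confusion_table(tp = 17, fn = 5, fp = 4, tn = 24))
  expect_equal(unname(rounded_metrics(r)), c(82, 81, 83, 77, 86))
  expect_equal(signif(r$fisher_p, 2), 9.4e-6)
  # validation-cohort row: 9 relapse / 25 CCR
  r2 <- performance_report(confusion_table(tp = 2, fn = 7, fp = 0, tn = 25))
  expect_equal(unname(rounded_metrics(r2)), c(79, 100, 78, 22, 100))
  expect_equal(signif(r2$fisher_p, 2), 0.064)
  # perfect prediction
  r3 <- performance_report(confusion_table(10, 0, 0, 10))
  expect_equal(unname(rounded_metrics(r3)), rep(100, 5))
})

test_that("two-sided Fisher exact matches both stats::fisher.test and enumeration", {
  expect_equal(fisher_exact_two_sided(confusion_table(5, 5, 5, 5)), 1)
  expect_equal(fisher_exact_two_sided(confusion_table(0, 0, 3, 7)), 1) # zero margin
  set.seed(31)
  for (i in 1:200) {
    ct <- confusion_table(sample(0:30, 1), sample(0:30, 1),
                          sample(0:30, 1), sample(0:30, 1))
    p <- fisher_exact_two_sided(ct)
    expect_equal(p, fisher_oracle(ct$tp, ct$fn, ct$fp, ct$tn),
                 tolerance = 1e-12)
    if (ct$tp + ct$fn > 0 && ct$fp + ct$tn > 0 && ct$tp + ct$fp > 0 &&
        ct$fn + ct$tn > 0) {
      ft <- fisher.test(matrix(c(ct$tp, ct$fp, ct$fn, ct$tn), 2))$p.value
      expect_equal(p, ft, tolerance = 1e-9)
    }
  }
})

test_that("confusion tables reconstruct uniquely from printed metrics", {
  ct <- confusion_from_metrics(14, 30, 36, 93)
  expect_equal(unlist(ct[c("tp", "fn", "fp", "tn")]),
               c(tp = 5, fn = 9, fp = 2, tn = 28))
  ct2 <- confusion_from_metrics(17, 24, 29, 96)
  expect_equal(unlist(ct2[c("tp", "fn", "fp", "tn")]),
               c(tp = 5, fn = 12, fp = 1, tn = 23))
  ct3 <- confusion_from_metrics(10, 10, 100, 100)
  expect_equal(c(ct3$tp, ct3$tn), c(10, 10))
  # two integer counts round to 50% of 200 -> ambiguous
  expect_error(confusion_from_metrics(200, 10, 50, 100), "ambiguous")
})

test_that("reconstruction and evaluation round-trip the printed metrics", {
  perf <- reference_performance()
  rows <- perf[perf$cohort != "Combined", ]
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, ]
    ct <- confusion_from_metrics(row$n_relapse, row$n_ccr,
                                 row$sensitivity, row$specificity)
    m <- rounded_metrics(performance_report(ct))
    expect_equal(unname(m), unlist(row[c("accuracy", "ppv", "npv",
                                         "sensitivity", "specificity")],
                                   use.names = FALSE))
  }
})

test_that("model fitting flags perfect separation and falls back to ridge", {
  co <- planted_cohort(seed = 5, n_genes = 20)
  co$expression["planted_01", ] <-
    2^(8 + 2 * outcome_indicator(co) + rnorm(50, 0, 1e-3))
  m <- fit_signature_model(co, "planted_01")
  expect_true(m$separation)
  pred <- predict(m, co)
  acc <- evaluate_predictions(pred$label, co$clinical$label)$report$accuracy
  expect_equal(acc, 100)
  expect_true(all(is.finite(coef(m))))
})

test_that("probabilities at the cutoff classify as relapse", {
  co <- planted_cohort(seed = 5, n_genes = 20)
  m <- fit_signature_model(co, "planted_01")
  m$coefficients[] <- 0
  m$intercept <- 0       # intercept-only: probability exactly 0.5
  pred <- predict(m, co)
  expect_true(all(pred$probability == 0.5))
  expect_true(all(pred$label == "R"))
})

test_that("prediction on the training cohort reproduces the training table", {
  co <- planted_cohort(seed = 13, n_genes = 50)
  m <- fit_signature_model(co, co$truth)
  p1 <- predict(m, co)
  p2 <- predict(m, co, rescale = FALSE)
  expect_equal(p1$probability, p2$probability, tolerance = 1e-9)
  ev1 <- evaluate_predictions(p1$label, co$clinical$label)
  ev2 <- evaluate_predictions(p2$label, co$clinical$label)
  expect_identical(unclass(ev1$confusion), unclass(ev2$confusion))
})

test_that("predicted probability is monotone in each gene", {
  co <- planted_cohort(seed = 14, n_genes = 20)
  m <- fit_signature_model(co, co$truth[1:3])
  g <- co$truth[1]
  co_hi <- co
  co_hi$expression[g, ] <- co_hi$expression[g, ] * 4
  # same standardization as training so the shift moves every sample up
  p0 <- predict(m, co, rescale = FALSE)$probability
  p1 <- predict(m, co_hi, rescale = FALSE)$probability
  if (m$coefficients[g] > 0) expect_true(all(p1 >= p0))
  else expect_true(all(p1 <= p0))
})

test_that("missing model genes raise an explicit error naming them", {
  co <- planted_cohort(seed = 5, n_genes = 20)
  m <- fit_signature_model(co, co$truth[1:2])
  co$expression <- co$expression[setdiff(rownames(co$expression),
                                         "planted_01"), ]
  expect_error(predict(m, co), "planted_01")
})

test_that("null cohorts fit near the prevalence ceiling", {
  accs <- vapply(1:15, function(s) {
    co <- planted_cohort(seed = 400 + s, n_genes = 20, fold = 1)
    m <- fit_signature_model(co, co$truth)
    evaluate_predictions(predict(m, co)$label,
                         co$clinical$label)$report$accuracy
  }, numeric(1))
  # training accuracy on noise hovers at/above the majority-class rate (56%)
  expect_lt(abs(mean(accs) - 56) , 15)
})

test_that("signature models survive a JSON round trip", {
  co <- planted_cohort(seed = 16, n_genes = 20)
  m <- fit_signature_model(co, co$truth[1:3])
  f <- tempfile(fileext = ".json")
  write_signature_model(m, f)
  back <- read_signature_model(f)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(predict(back, co)$probability, predict(m, co)$probability,
               tolerance = 1e-12)
  unlink(f)
})
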