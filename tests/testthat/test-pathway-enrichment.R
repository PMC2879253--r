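ranked_scores <- function(n, seed = 1) {
  set.seed(seed)
  setNames(sort(rnorm(n, 0, 1), decreasing = TRUE),
           sprintf("gene_%04d", seq_len(n)))
}

test_that("enrichment score matches a step-by-step manual oracle", {
  scores <- setNames(c(5, 4, 3.5, 3, 2, 1.5, 1, 0.5, 0.2, 0.1),
                     paste0("g", 1:10))
  set3 <- c("g2", "g5", "g9")
  for (w in c(0, 1)) {
    got <- enrichment_score(scores, set3, weight = w)
    want <- es_oracle(scores, set3, weight = w)
    expect_equal(got$es, want$es, tolerance = 1e-12)
    expect_equal(got$running_sum, unname(want$running_sum),
                 tolerance = 1e-12)
    expect_equal(got$peak_index, want$peak_index)
  }
})

test_that("enrichment score limiting cases behave as required", {
  scores <- ranked_scores(200)
  # set = small top slice, w = 0: es approaches +1
  es_top <- enrichment_score(scores, names(scores)[1:5], weight = 0)$es
  expect_gt(es_top, 0.95)
  # set = entire list: es 0 by construction
  expect_equal(enrichment_score(scores, names(scores))$es, 0)
  # zero overlap errors
  expect_error(enrichment_score(scores, c("absent1", "absent2")), "overlap")
  expect_error(enrichment_score(setNames(c(1, 2), c("a", "a")), "a"),
               "duplicate")
})

test_that("running sum is conserved (ends at zero) and w=0 is rank-invariant", {
  scores <- ranked_scores(100, seed = 2)
  gs <- sample(names(scores), 12)
  for (w in c(0, 1)) {
    rs <- enrichment_score(scores, gs, weight = w)$running_sum
    expect_equal(rs[length(rs)], 0, tolerance = 1e-12)
  }
  # monotone transformation of the scores leaves the w=0 statistic unchanged
  es_a <- enrichment_score(scores, gs, weight = 0)$es
  es_b <- enrichment_score(exp(scores), gs, weight = 0)$es
  expect_equal(es_a, es_b, tolerance = 1e-12)
})

test_that("leading edge is the overlap at or before the peak, disjoint from the rest", {
  scores <- setNames(c(5, 4, 3, 2, 1, 0.5, 0.4, 0.3, 0.2, 0.1),
                     paste0("g", 1:10))
  gs <- c("g1", "g3", "g4", "g9")
  es <- enrichment_score(scores, gs, weight = 1)
  le <- leading_edge(es, scores, gs)
  # manual extraction: peak of the hand oracle
  manual <- es_oracle(scores, gs, weight = 1)
  sorted_genes <- names(sort(scores, decreasing = TRUE))
  hits <- sorted_genes[sorted_genes %in% gs]
  manual_le <- sorted_genes[seq_len(manual$peak_index)]
  manual_le <- manual_le[manual_le %in% gs]
  expect_identical(le, manual_le)
  # union with post-peak members recovers the full overlap, disjointly
  rest <- setdiff(hits, le)
  expect_setequal(c(le, rest), hits)
  expect_length(intersect(le, rest), 0)
  # es peak at the last hit => the leading edge is the whole overlap
  gs_top <- c("g1", "g2", "g3")
  es_top <- enrichment_score(scores, gs_top, weight = 1)
  expect_setequal(leading_edge(es_top, scores, gs_top), gs_top)
})

test_that("permutation p is deterministic, bounded below 1/n_perm, and calibrated", {
  scores <- ranked_scores(150, seed = 3)
  gs <- names(scores)[1:10]  # extreme set: beats every permutation
  a <- permutation_null(scores, gs, n_perm = 200, seed = 5)
  b <- permutation_null(scores, gs, n_perm = 200, seed = 5)
  expect_identical(a, b)
  expect_lt(a$nominal_p, 1 / 200)
  expect_error(permutation_null(scores, gs, n_perm = 50), "100")

  # nominal p approximately uniform under the null (random sets)
  set.seed(11)
  ps <- vapply(1:150, function(i) {
    permutation_null(scores, sample(names(scores), 10), n_perm = 120,
                     seed = 1000 + i)$nominal_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("NES-based FDR gives identical q to identical sets and respects the bound", {
  scores <- ranked_scores(150, seed = 4)
  gs <- names(scores)[1:8]
  r1 <- permutation_null(scores, gs, n_perm = 150, seed = 1)
  res <- fdr_across_sets(list(r1, r1))
  expect_equal(res[1], res[2])
  expect_lte(res[1], r1$nominal_p * 2 + 1e-9) # strongly enriched: small q
})

test_that("gene sets load from GMT and run_gsea flags enriched sets", {
  gmt <- system.file("extdata", "example_sets.gmt", package = "tallgc")
  sets <- read_gene_sets(gmt)
  expect_named(sets, c("SET_TOP", "SET_MIXED", "SET_BOTTOM"))
  expect_true(all(lengths(sets) >= 5))
  scores <- ranked_scores(1000, seed = 6)
  res <- run_gsea(scores, sets, n_perm = 150, seed = 2)
  expect_s3_class(res, "gsea_result")
  expect_equal(nrow(res), 3)
  expect_gt(res$es[res$set == "SET_TOP"], 0)
  expect_lt(res$es[res$set == "SET_BOTTOM"], 0)
  le <- attr(res, "leading_edges")
  expect_true(all(le$SET_TOP %in% sets$SET_TOP))
})

test_that("pathway classifiers fit on leading-edge genes predict planted outcomes", {
  # 14 co-regulated genes at fold 1.5, n = 50: cell-adhesion-sized pathway
  planted <- setNames(rep(1.5, 14), sprintf("path_%02d", 1:14))
  co <- simulate_cohort(sim_config(n_genes = 100, planted_genes = planted,
                                   noise_sd = 1, seed = 31))
  m <- pathway_classifier(co, names(planted))
  acc <- evaluate_predictions(predict(m, co)$label,
                              co$clinical$label)$report$accuracy
  expect_gte(acc, 75)
  # a single leading-edge gene reduces to a single-gene logistic model
  m1 <- pathway_classifier(co, names(planted)[1])
  expect_length(m1$genes, 1)
  expect_error(pathway_classifier(co, c("nope1", "nope2")), "no leading-edge")
})
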