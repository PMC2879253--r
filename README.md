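# tallgc

Discovery and multi-cohort validation of small gene-expression classifiers
that predict **relapse (R)** versus **continuous complete remission (CCR)**
in pediatric T-cell acute lymphoblastic leukemia (T-ALL) from diagnostic
bone-marrow expression profiles.

Relapsed T-ALL carries a dismal prognosis, and classical risk factors (age,
WBC at diagnosis) stratify T-ALL poorly. A compact diagnostic gene
classifier — small enough to translate to routine qRT-PCR testing — can flag
patients who would benefit from augmented therapy. This package implements
the full statistical pipeline for building and validating such classifiers,
together with a synthetic-cohort generator so every stage is testable
without patient data.

## The method

Given a cohort (genes × samples linear intensities, e.g. RMA summaries,
plus an outcome label per patient):

1. **Gene ranking.** All genes are ranked by Random-Forest permutation
   importance (mean decrease in accuracy) for separating R from CCR on
   log2 expression.
2. **Shortlisting.** The top *n* genes (default 500) are filtered to drop
   legacy B-chip probe sets (6-digit probe ids ≥ 222000) and genes below a
   mean-expression floor that proxies qRT-PCR detectability.
3. **Combination search.** Every k-gene combination (default k = 5) is
   scored by

   *r²* = cor(PC1, y)² ,

   the squared Pearson correlation between the first principal component of
   the combination's z-scored log2 expression and the 0/1 outcome label.
   The exhaustive search works on the k×k correlation submatrix (a compiled
   fast path evaluates all C(57,5) ≈ 4.19 M tuples in under a minute on one
   CPU); a greedy beam search is available for larger pools.
4. **Signature model.** The top combinations are refit by logistic
   regression P(relapse | z-scored log2 expression); patients with fitted
   probability ≥ 0.5 are labeled R. Performance is reported as accuracy,
   PPV, NPV, sensitivity, specificity and a two-sided Fisher exact test
   (point-probability method) on the confusion table.
5. **Survival validation.** Predicted groups are compared by Kaplan-Meier
   curves and the log-rank test; the fitted relapse probability enters a
   univariate Cox proportional-hazards model as a continuous covariate.
   Single-gene markers can be stratified into expression tertiles.
6. **Pathway classifiers.** A minimal GSEA (weighted Kolmogorov-Smirnov
   enrichment score, gene-set permutation null, NES-based FDR) identifies
   enriched pathways in the ranked gene list; the *leading edge* — set
   members at or before the running-sum peak — feeds a logistic pathway
   classifier.
7. **Cross-cohort validation.** A signature is applied to independent
   cohorts (refit per cohort on the fixed gene set by default, since
   platforms and assays differ), per-cohort confusion tables are pooled
   elementwise, and a combined exact p-value is computed on the pooled
   table, optionally excluding the training cohort.

## Worked example

```r
library(tallgc)

# a synthetic training cohort: 50 patients (22 R / 28 CCR), 200 genes,
# the five-gene reference signature planted at its reported fold changes
co <- simulate_cohort(sim_config(n_genes = 200, seed = 42))
co
#> T-ALL cohort: 50 samples x 200 genes [ synthetic-array ]
#>   outcome: CCR=28, R=22
#>   planted genes: ABTB2, IL7R, LGALS8, PLAC8, FAM13A1

cls <- fit_gene_classifier(co, k = 5, top_n = 200, shortlist_size = 20,
                           n_trees = 500, seed = 1)
cls
#> 5-gene relapse classifier (50 training samples)
#>   genes: FAM13A1, gene_0033, gene_0041, gene_0101, PLAC8
#>   PC1 r2 = 0.6226
#>   training performance: n=50  Acc 94  PPV 95  NPV 93  Sens 91  Spec 96  P 9.6e-11
```

Two planted genes (PLAC8, FAM13A1) survive into the selected signature at
these fold changes and noise level; the r² of 0.62 says PC1 of the selected
five genes explains 62 % of the outcome variance in training, and the
training panel overstates transfer performance, which is why external
validation matters.

The published validation panel can be reconstructed exactly from the class
sizes and printed sensitivity/specificity, then pooled:

```r
perf <- reference_performance()
rows <- perf[perf$model == "5-GC" & perf$cohort != "Combined", ]
tabs <- lapply(seq_len(nrow(rows)), function(i)
  confusion_from_metrics(rows$n_relapse[i], rows$n_ccr[i],
                         rows$sensitivity[i], rows$specificity[i]))
names(tabs) <- rows$cohort
pooled_performance(tabs)$report
#> n=169  Acc 76  PPV 81  NPV 75  Sens 47  Spec 93  P 1.5e-09
signif(combined_p(tabs, exclude = "Training"), 2)
#> [1] 0.00012
```

The pooled panel reads: across 169 patients in four cohorts the classifier
calls 76 % of outcomes correctly; 81 % of predicted relapsers truly
relapse (PPV), it catches 47 % of all relapses (sensitivity) while
mislabeling only 7 % of CCR patients (specificity 93), and the association
between prediction and outcome is far beyond chance (combined exact
p = 1.5 × 10⁻⁹; 1.2 × 10⁻⁴ with the training cohort excluded).

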