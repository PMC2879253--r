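# Minimal ranked-list gene set enrichment analysis: weighted
# Kolmogorov-Smirnov enrichment score, gene-set permutation null, NES-based
# FDR across sets, and leading-edge extraction.  Pathway classifiers are
# logistic signature models fit on the leading edge.

#' Read gene sets from a GMT file
#'
#' @param path GMT file (one set per line: name, description, members).
#' @return named list of character vectors (gene ids per set).
#' @export
read_gene_sets <- function(path) {
  fgsea::gmtPathways(path)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list from top to bottom; a gene in the set increments
#' the running sum by its |score|^weight (normalized by the total over set
#' members), a gene outside decrements by 1/(N - set size).  The enrichment
#' score is the running-sum value of largest magnitude (signed); the
#' leading edge is defined by the position of that extremum.
#'
#' @param scores named numeric vector of ranking scores (e.g. Random-Forest
#'   importances or signed statistics); sorted internally in decreasing
#'   order.  Names must be unique.
#' @param gene_set character vector of member gene ids (overlap with the
#'   list must be non-empty).
#' @param weight weighting exponent (0 = classic KS, 1 = weighted; default 1).
#' @return list with \code{es}, \code{running_sum} (over the sorted list),
#'   \code{peak_index}, and \code{order} (the sorting permutation).
#' @export
enrichment_score <- function(scores, gene_set, weight = 1) {
  if (anyDuplicated(names(scores)))
    stop("ranked list contains duplicate genes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene set does not overlap the ranked list")
  N <- length(s)
  if (nh == N) {
    # the whole list is in the set: nothing to enrich against
    return(list(es = 0, running_sum = rep(0, N), peak_index = N,
                order = ord))
  }
  w <- abs(s)^weight
  whit_total <- sum(w[hit])
  inc <- numeric(N)
  # all-zero hit weights (possible for weight > 0): fall back to equal steps
  inc[hit] <- if (whit_total > 0) w[hit] / whit_total else 1 / nh
  inc[!hit] <- -1 / (N - nh)
  rs <- cumsum(inc)
  peak <- which.max(abs(rs))
  list(es = rs[peak], running_sum = rs, peak_index = peak, order = ord)
}

#' Gene-set permutation null for an enrichment score
#'
#' Re-draws random gene sets of the same size from the ranked list
#' \code{n_perm} times.  The nominal p is the fraction of same-sign null
#' scores at least as extreme as the observed one, with the add-one
#' convention \code{(1 + hits) / (1 + n_same_sign)}, so an observed score
#' beyond every permutation reports a value below 1/n_perm.  NES is the
#' observed score divided by the mean magnitude of same-sign null scores.
#'
#' @param scores,gene_set,weight as in [enrichment_score()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer RNG seed (fixed seed gives identical p).
#' @return list with \code{es}, \code{nominal_p}, \code{nes},
#'   \code{null_es}, \code{null_nes} and a \code{degenerate} flag (set when
#'   the same-sign null is empty or all zero).
#' @export
permutation_null <- function(scores, gene_set, n_perm = 1000L, seed = 1L,
                             weight = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  obs <- enrichment_score(scores, gene_set, weight)
  size <- sum(names(scores) %in% gene_set)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  universe <- names(scores)
  null_es <- vapply(seq_len(n_perm), function(i) {
    enrichment_score(scores, sample(universe, size), weight)$es
  }, numeric(1))
  same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  degenerate <- length(same) == 0 || all(same == 0)
  if (degenerate) {
    p <- 1 / (1 + n_perm)
    nes <- NA_real_
    null_nes <- rep(NA_real_, n_perm)
  } else {
    hits <- sum(abs(same) >= abs(obs$es))
    p <- (1 + hits) / (1 + length(same))
    # more extreme than every permutation: report below 1/n_perm
    if (hits == 0) p <- min(p, 1 / (n_perm + 1))
    m <- mean(abs(same))
    nes <- obs$es / m
    # normalize each null score by the same-sign null mean magnitude
    m_pos <- mean(abs(null_es[null_es >= 0]))
    m_neg <- mean(abs(null_es[null_es < 0]))
    null_nes <- ifelse(null_es >= 0,
                       null_es / ifelse(is.nan(m_pos) || m_pos == 0, 1, m_pos),
                       null_es / ifelse(is.nan(m_neg) || m_neg == 0, 1, m_neg))
  }
  list(es = obs$es, nominal_p = p, nes = nes, null_es = null_es,
       null_nes = null_nes, degenerate = degenerate)
}

#' NES-based FDR q-values across gene sets
#'
#' GSEA-style false discovery rate: for each set, the tail fraction of the
#' pooled null NES distribution at the set's NES is divided by the tail
#' fraction of observed NES values (same sign), capped at 1 and monotonized
#' from the most extreme NES downwards.
#'
#' @param results list of [permutation_null()] outputs (one per set).
#' @return numeric vector of q-values aligned with \code{results}.
#' @export
fdr_across_sets <- function(results) {
  if (!length(results)) stop("no enrichment results")
  nes <- vapply(results, `[[`, numeric(1), "nes")
  null_nes <- unlist(lapply(results, `[[`, "null_nes"))
  null_nes <- null_nes[is.finite(null_nes)]
  q <- vapply(seq_along(results), function(i) {
    x <- nes[i]
    if (!is.finite(x)) return(NA_real_)
    if (x >= 0) {
      null_tail <- mean(null_nes[null_nes >= 0] >= x)
      obs_tail <- mean(nes[is.finite(nes) & nes >= 0] >= x)
    } else {
      null_tail <- mean(null_nes[null_nes < 0] <= x)
      obs_tail <- mean(nes[is.finite(nes) & nes < 0] <= x)
    }
    if (is.nan(null_tail)) null_tail <- 0
    min(1, null_tail / max(obs_tail, .Machine$double.eps))
  }, numeric(1))
  # monotonize: a more extreme NES never has a larger q (running minimum
  # taken from the least extreme set towards the most extreme, as in
  # step-up multiple-testing adjustments)
  for (sgn in c(1, -1)) {
    idx <- which(is.finite(nes) & (if (sgn > 0) nes >= 0 else nes < 0))
    if (length(idx) > 1) {
      ord <- idx[order(abs(nes[idx]))]
      q[ord] <- cummin(q[ord])
    }
  }
  q
}

#' Leading-edge genes of an enrichment result
#'
#' Set members ranked at or before the running-sum peak for a positive
#' enrichment score; at or after the trough for a negative one.
#'
#' @param es_result output of [enrichment_score()] (or the matching fields
#'   of [permutation_null()] plus \code{peak_index}/\code{order}).
#' @param scores the ranked scores the result was computed from.
#' @param gene_set the gene set.
#' @return character vector of leading-edge gene ids, in rank order.
#' @export
leading_edge <- function(es_result, scores, gene_set) {
  ord <- es_result$order
  genes_sorted <- names(scores)[ord]
  hit <- genes_sorted %in% gene_set
  peak <- es_result$peak_index
  if (es_result$es >= 0) {
    genes_sorted[hit & seq_along(genes_sorted) <= peak]
  } else {
    genes_sorted[hit & seq_along(genes_sorted) >= peak]
  }
}

#' Run GSEA over a collection of gene sets
#'
#' Computes the enrichment score, gene-set permutation p, NES, NES-based
#' FDR q and leading edge for every set, and flags the sets passing the
#' discovery thresholds (defaults FDR < 0.25 and nominal p < 0.001).
#'
#' @param scores named ranking scores (see [enrichment_score()]).
#' @param gene_sets named list of gene sets (e.g. from [read_gene_sets()]).
#'   Sets with no overlap are skipped with a warning.
#' @param n_perm,seed,weight see [permutation_null()].
#' @param fdr_threshold,p_threshold discovery thresholds.
#' @return A \code{gsea_result}: data.frame with one row per analyzed set
#'   (set, size, es, nes, nominal_p, fdr_q, leading_edge_size, selected)
#'   and the leading-edge gene lists in attribute \code{"leading_edges"}.
#' @export
run_gsea <- function(scores, gene_sets, n_perm = 1000L, seed = 1L,
                     weight = 1, fdr_threshold = 0.25,
                     p_threshold = 0.001) {
  overlap <- vapply(gene_sets, function(g) sum(names(scores) %in% g),
                    numeric(1))
  if (any(overlap == 0)) {
    warning("skipping set(s) with no overlap: ",
            paste(names(gene_sets)[overlap == 0], collapse = ", "))
    gene_sets <- gene_sets[overlap > 0]
  }
  if (!length(gene_sets)) stop("no gene set overlaps the ranked list")
  results <- lapply(seq_along(gene_sets), function(i) {
    permutation_null(scores, gene_sets[[i]], n_perm = n_perm,
                     seed = seed + i - 1L, weight = weight)
  })
  q <- fdr_across_sets(results)
  edges <- lapply(seq_along(gene_sets), function(i) {
    es <- enrichment_score(scores, gene_sets[[i]], weight)
    leading_edge(es, scores, gene_sets[[i]])
  })
  names(edges) <- names(gene_sets)
  out <- data.frame(
    set = names(gene_sets),
    size = vapply(gene_sets, function(g) sum(names(scores) %in% g),
                  numeric(1)),
    es = vapply(results, `[[`, numeric(1), "es"),
    nes = vapply(results, `[[`, numeric(1), "nes"),
    nominal_p = vapply(results, `[[`, numeric(1), "nominal_p"),
    fdr_q = q,
    leading_edge_size = lengths(edges),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$selected <- !is.na(out$fdr_q) & out$fdr_q < fdr_threshold &
    out$nominal_p < p_threshold
  attr(out, "leading_edges") <- edges
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Fit a pathway outcome classifier from leading-edge genes
#'
#' Logistic signature model ([fit_signature_model()]) on the leading-edge
#' genes of an enriched pathway that are present in the cohort.
#'
#' @param cohort a `tall_cohort`.
#' @param leading_edge_genes character vector of leading-edge gene ids.
#' @param ... passed to [fit_signature_model()].
#' @return a `signature_model`.
#' @export
pathway_classifier <- function(cohort, leading_edge_genes, ...) {
  present <- intersect(leading_edge_genes, rownames(cohort$expression))
  if (!length(present))
    stop("no leading-edge gene present in the cohort")
  fit_signature_model(cohort, present, ...)
}

#' Write GSEA results as TSV
#' @param result a `gsea_result`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_gsea <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
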