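#' Rank genes by Random-Forest permutation importance
#'
#' Grows an ensemble of randomized decision trees on log2 expression with the
#' relapse/CCR label as response and scores each gene by permutation
#' (mean-decrease-in-accuracy) importance.  Zero-variance genes cannot enter
#' a split; they receive score 0 and are ranked last.  Ties are broken by
#' gene id (lexicographic) so reruns under the same seed are identical.
#'
#' @param cohort a `tall_cohort` (both classes must be present, >= 2 samples
#'   each).
#' @param n_trees number of trees (default 1000).
#' @param seed integer RNG seed.
#' @param mtry features tried per split; default \code{sqrt(p)}.
#' @return A \code{gene_ranking}: a data.frame with columns \code{gene},
#'   \code{score} (importance, >= 0 after flooring at 0) and \code{rank}
#'   (1-based, a permutation of 1..n genes).
#' @export
rank_genes <- function(cohort, n_trees = 1000L, seed = 1L, mtry = NULL) {
  y <- factor(cohort$clinical$label, levels = c("CCR", "R"))
  if (nlevels(droplevels(y)) < 2)
    stop("both outcome classes must be present to rank genes")
  if (min(table(y)) < 2)
    stop("need at least 2 samples per class")
  if (anyNA(cohort$expression)) stop("expression contains missing values")
  lx <- t(log2(cohort$expression))          # samples x genes
  v <- apply(lx, 2, var)
  keep <- v > 0
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(sum(keep))))
  rf <- randomForest::randomForest(
    x = lx[, keep, drop = FALSE], y = y,
    ntree = n_trees, mtry = mtry, importance = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
  score <- setNames(numeric(ncol(lx)), colnames(lx))
  score[names(imp)] <- pmax(imp, 0)
  # score desc; zero-variance genes last; gene id as deterministic tie-break
  ord <- order(-score, !keep, names(score))
  out <- data.frame(gene = names(score)[ord],
                    score = unname(score[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Shortlist the top-ranked genes with platform and detectability filters
#'
#' Takes the top \code{top_n} genes of a ranking and removes (i) probe sets
#' originating from the older B-chip platform, identified by an integer
#' probe-id prefix at or above \code{b_chip_threshold} (Affymetrix ids above
#' ~222000 belong to HG-U133B / Plus-2-only content) or by an explicit
#' annotation table, and (ii) genes whose mean linear expression falls below
#' \code{min_mean_expression}, a transparent proxy for qRT-PCR
#' detectability.  Order (by rank) is preserved; the operation is
#' idempotent.
#'
#' @param ranking a `gene_ranking` from [rank_genes()].
#' @param expr the expression matrix the ranking refers to (linear scale).
#' @param top_n how many top-ranked genes to start from (default 500).
#' @param b_chip_threshold integer probe-id prefix cutoff; ids whose leading
#'   integer is >= this value are dropped.  \code{NULL} disables the filter.
#' @param min_mean_expression linear intensity floor; genes with lower mean
#'   are dropped.  0 disables the filter.
#' @param annotation optional data.frame with columns \code{probe_id} and
#'   \code{chip}; probes annotated with chip \code{"B"} are dropped instead
#'   of using the numeric prefix rule.
#' @return character vector of gene ids in rank order (possibly empty, with
#'   a warning).
#' @export
apply_shortlist <- function(ranking, expr, top_n = 500L,
                            b_chip_threshold = 222000L,
                            min_mean_expression = 0,
                            annotation = NULL) {
  stopifnot(inherits(ranking, "gene_ranking"), top_n >= 1)
  if (!all(rownames(expr) %in% ranking$gene))
    stop("ranking does not cover all genes in the expression matrix")
  sel <- head(ranking$gene, top_n)
  if (!is.null(annotation)) {
    bad <- annotation$probe_id[annotation$chip == "B"]
    sel <- sel[!(sel %in% bad)]
  } else if (!is.null(b_chip_threshold)) {
    # B-chip probes carry 6-digit ids at/above the threshold; 7-digit ids
    # are later Plus-2 content and are retained
    prefix <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", sel)))
    drop <- !is.na(prefix) & prefix >= b_chip_threshold & prefix < 1e6
    sel <- sel[!drop]
  }
  if (min_mean_expression > 0) {
    mu <- rowMeans(expr[sel[sel %in% rownames(expr)], , drop = FALSE])
    sel <- sel[sel %in% names(mu)[mu >= min_mean_expression]]
  }
  if (!length(sel)) warning("shortlist is empty after filtering")
  sel
}

#' Linear-scale fold change between outcome classes
#'
#' Ratio of the relapse-class mean to the CCR-class mean of linear
#' intensities for one gene (R mean / CCR mean).
#'
#' @param expr linear expression matrix, genes x samples.
#' @param labels per-sample labels, "R" / "CCR".
#' @param gene gene id (row of \code{expr}).
#' @return positive ratio.
#' @export
fold_change <- function(expr, labels, gene) {
  if (!gene %in% rownames(expr)) stop("gene not found: ", gene)
  if (!all(c("R", "CCR") %in% labels))
    stop("both classes must be present")
  x <- expr[gene, ]
  m_ccr <- mean(x[labels == "CCR"])
  if (m_ccr == 0) stop("undefined ratio: CCR class mean is zero")
  mean(x[labels == "R"]) / m_ccr
}

#' Write / read a gene ranking as TSV
#' @param ranking a `gene_ranking`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_ranking <- function(ranking, path) {
  write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("gene_ranking", "data.frame")
  out
}
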