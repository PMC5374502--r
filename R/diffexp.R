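#' @include AllClasses.R
NULL

#' Count prefilter for differential expression
#'
#' A gene is analyzed only if it has at least `min_count` counts in at
#' least `min_cells` cells, pooled across both groups.
#'
#' @param sc an [ScCounts] object.
#' @param groupA,groupB disjoint, non-empty character vectors of cell ids.
#' @param min_count per-cell count threshold (default 10, inclusive).
#' @param min_cells required number of qualifying cells (default 3).
#' @return Character vector of gene ids passing the filter.
#' @export
dePrefilter <- function(sc, groupA, groupB, min_count = 10L, min_cells = 3L) {
  stopifnot(methods::is(sc, "ScCounts"))
  if (!length(groupA) || !length(groupB))
    stopc("scmge_empty_group", "both groups must be non-empty")
  if (length(intersect(groupA, groupB)))
    stopc("scmge_overlapping_groups", "groups must be disjoint")
  x <- counts(sc)[, c(groupA, groupB), drop = FALSE]
  rownames(x)[rowSums(x >= min_count) >= min_cells]
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) p-value
#'
#' Midrank tie handling; the exact null distribution is used when the
#' combined sample size is at most `exact_max_n` and there are no ties,
#' otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param a,b numeric expression values of the two groups (non-empty).
#' @param exact_max_n combined-size bound for the exact distribution
#'   (default 20).
#' @return Two-sided p-value in (0, 1].
#' @export
mannWhitney <- function(a, b, exact_max_n = 20L) {
  if (!length(a) || !length(b))
    stopc("scmge_empty_group", "both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  ex <- (length(a) + length(b)) <= exact_max_n && !ties
  p <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = "two.sided", exact = ex, correct = TRUE))$p.value
  min(max(p, .Machine$double.xmin), 1)
}

#' Floored-median log2 fold-change
#'
#' Per cell, `log2(nRPKM)` is computed and values below `floor`
#' (including `-Inf` from zeros) are replaced with the floor; the
#' fold-change is the difference of the group medians of these floored
#' log values (group A minus group B).  `scale = "raw_median"` exposes
#' the alternative reading in which medians are taken on raw nRPKM and
#' only then logged and floored.
#'
#' @param x named numeric vector of per-cell nRPKM values (>= 0).
#' @param groupA,groupB cell ids (names of `x`).
#' @param floor log2 floor (default -8).
#' @param scale `"floored_log"` (default) or `"raw_median"`.
#' @return The log2 fold-change (A minus B).
#' @export
medianLFC <- function(x, groupA, groupB, floor = -8,
                      scale = c("floored_log", "raw_median")) {
  scale <- match.arg(scale)
  if (any(x < 0)) stopc("scmge_negative_input", "nRPKM values must be >= 0")
  if (scale == "floored_log") {
    lg <- pmax(log2(x), floor)
    stats::median(lg[groupA]) - stats::median(lg[groupB])
  } else {
    pmax(log2(stats::median(x[groupA])), floor) -
      pmax(log2(stats::median(x[groupB])), floor)
  }
}

#' Multiple-testing adjustment
#'
#' `"holm"` is the step-down Holm procedure (the default of the
#' standard adjustment function this mirrors); `"bh"` is the
#' Benjamini-Hochberg step-up FDR.  Both are clipped to 1, monotone,
#' and preserve input order.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @param method `"holm"` or `"bh"`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjustPvalues <- function(p, method = c("holm", "bh")) {
  method <- match.arg(method)
  if (any(p <= 0 | p > 1))
    stopc("scmge_bad_pvalues", "p-values must lie in (0, 1]")
  stats::p.adjust(p, method = c(holm = "holm", bh = "BH")[[method]])
}

#' Run the differential-expression procedure
#'
#' Composition of the stages: count prefilter, per-gene Mann-Whitney
#' test on nRPKM, floored-median log2 fold-change, multiple-testing
#' adjustment over tested genes only, then backfill of untested genes
#' with `p = 1`, `lfc = 0`, `tested = FALSE`.
#'
#' @param sc an [ScCounts] object (prefilter operates on raw counts).
#' @param nrpkm_expr the matching [ScExpr] of nRPKM values (the test
#'   and fold-change operate on these).
#' @param groupA,groupB disjoint cell-id vectors.
#' @param adjust `"holm"` (default) or `"bh"`.
#' @param floor log2 floor for the fold-change (default -8).
#' @param lfc_scale see [medianLFC()].
#' @return A [DEResult]; adjustment method, floor and group sizes are in
#'   its `metadata()`.
#' @export
runDE <- function(sc, nrpkm_expr, groupA, groupB,
                  adjust = c("holm", "bh"), floor = -8,
                  lfc_scale = c("floored_log", "raw_median")) {
  adjust <- match.arg(adjust)
  lfc_scale <- match.arg(lfc_scale)
  stopifnot(methods::is(sc, "ScCounts"), methods::is(nrpkm_expr, "ScExpr"))
  tested <- dePrefilter(sc, groupA, groupB)
  x <- exprValues(nrpkm_expr)
  ids <- rownames(x)
  p <- rep(1, length(ids))
  lfc <- rep(0, length(ids))
  names(p) <- names(lfc) <- ids
  for (g in tested) {
    p[g] <- mannWhitney(x[g, groupA], x[g, groupB])
    lfc[g] <- medianLFC(x[g, ], groupA, groupB, floor = floor,
                        scale = lfc_scale)
  }
  padj <- rep(1, length(ids))
  names(padj) <- ids
  if (length(tested)) padj[tested] <- adjustPvalues(p[tested], method = adjust)
  DEResult(
    data.frame(gene_id = ids, tested = ids %in% tested,
               p_value = unname(p), p_adjusted = unname(padj),
               lfc = unname(lfc),
               n_A = length(groupA), n_B = length(groupB),
               row.names = ids),
    metadata = list(adjust = adjust, floor = floor, lfc_scale = lfc_scale,
                    groupA = groupA, groupB = groupB))
}

#' Top differentially expressed genes
#'
#' Tested genes ranked by ascending adjusted p, ties by descending
#' absolute fold-change, remaining ties by gene id.
#'
#' @param de a [DEResult].
#' @param n how many genes (default 100); if it exceeds the number of
#'   tested genes, all are returned with a warning.
#' @return `data.frame` with columns `gene_id`, `p_adjusted`, `lfc` and
#'   `direction` (sign of the fold-change).
#' @export
topDEGenes <- function(de, n = 100L) {
  stopifnot(methods::is(de, "DEResult"))
  tt <- as.data.frame(de[de$tested, , drop = FALSE])
  if (n > nrow(tt)) {
    warnc("n = %d exceeds the %d tested genes; returning all", n, nrow(tt))
    n <- nrow(tt)
  }
  ord <- order(tt$p_adjusted, -abs(tt$lfc), tt$gene_id, method = "radix")
  tt <- tt[ord, ][seq_len(n), , drop = FALSE]
  data.frame(gene_id = tt$gene_id, p_adjusted = tt$p_adjusted, lfc = tt$lfc,
             direction = ifelse(tt$lfc > 0, "up",
                                ifelse(tt$lfc < 0, "down", "none")),
             row.names = NULL)
}
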