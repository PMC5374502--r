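#' @include AllClasses.R
NULL

#' Heatmap value preparation
#'
#' The display convention used for expression heatmaps: `log2(nRPKM)`
#' with values below the floor (default -6, including `-Inf` from
#' zeros) replaced by the floor, then Z-scored per gene with the
#' population standard deviation.
#'
#' @param nrpkm_expr an [ScExpr] of nRPKM values.
#' @param floor log2 floor (default -6).
#' @return An [ScExpr] with transform `"zscore"` and `floorApplied`
#'   recording the floor.
#' @export
heatmapValues <- function(nrpkm_expr, floor = -6) {
  stopifnot(methods::is(nrpkm_expr, "ScExpr"))
  lg <- pmax(log2(exprValues(nrpkm_expr)), floor)
  z <- zscoreGenes(lg)
  methods::new("ScExpr", methods::as(z, "SummarizedExperiment"),
               transform = "zscore", floorApplied = floor)
}

#' Cross-system fold-change concordance
#'
#' Joins two differential-expression results on their shared genes and
#' flags genes significant in both systems (raw p below `p_cut`, or
#' adjusted p with `use_adjusted`) with fold-changes of the same sign.
#' Quadrant counts are attached as attributes.
#'
#' @param de1,de2 [DEResult] objects from the two systems.
#' @param p_cut significance cut (default 0.05, strict `<`).
#' @param use_adjusted compare adjusted instead of raw p-values.
#' @return `data.frame(gene_id, lfc_system1, lfc_system2, p1, p2,
#'   concordant_significant)` with attributes `n_dropped` (genes not
#'   shared) and `quadrants`.
#' @export
concordance <- function(de1, de2, p_cut = 0.05, use_adjusted = FALSE) {
  stopifnot(methods::is(de1, "DEResult"), methods::is(de2, "DEResult"))
  shared <- intersect(de1$gene_id, de2$gene_id)
  if (!length(shared))
    stopc("scmge_empty_group", "the two results share no genes")
  nDropped <- length(de1$gene_id) + length(de2$gene_id) - 2L * length(shared)
  a <- as.data.frame(de1[match(shared, de1$gene_id), ])
  b <- as.data.frame(de2[match(shared, de2$gene_id), ])
  p1 <- if (use_adjusted) a$p_adjusted else a$p_value
  p2 <- if (use_adjusted) b$p_adjusted else b$p_value
  out <- data.frame(
    gene_id = shared, lfc_system1 = a$lfc, lfc_system2 = b$lfc,
    p1 = p1, p2 = p2,
    concordant_significant = p1 < p_cut & p2 < p_cut &
      sign(a$lfc) == sign(b$lfc) & sign(a$lfc) != 0,
    row.names = NULL)
  attr(out, "n_dropped") <- nDropped
  attr(out, "quadrants") <- table(
    quadrant = paste0(ifelse(out$lfc_system1 >= 0, "right", "left"), "_",
                      ifelse(out$lfc_system2 >= 0, "up", "down")))
  out
}

#' Volcano table
#'
#' Per-gene fold-change and `-log10(p)` sorted by ascending p, with a
#' significance flag at a strict raw-p cut (backfilled untested genes
#' have `p = 1`, hence `-log10(p) = 0`).
#'
#' @param de a [DEResult].
#' @param p_cut significance cut (default 0.05, strict `<`).
#' @param use_adjusted flag on adjusted instead of raw p-values.
#' @return `data.frame(gene_id, lfc, neg_log10_p, significant)`.
#' @export
volcanoTable <- function(de, p_cut = 0.05, use_adjusted = FALSE) {
  stopifnot(methods::is(de, "DEResult"))
  p <- if (use_adjusted) de$p_adjusted else de$p_value
  out <- data.frame(gene_id = de$gene_id, lfc = de$lfc,
                    neg_log10_p = -log10(p), significant = p < p_cut,
                    row.names = NULL)
  out[order(p, out$gene_id, method = "radix"), , drop = FALSE]
}
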