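#' @include AllClasses.R
NULL

#' Per-cell QC thresholds
#'
#' The three quality gates applied to cells before any downstream
#' analysis: total uniquely mapped reads, mitochondrial read fraction
#' and fraction of annotated genes detected.  The defaults encode the
#' gates >= 2,000,000 reads (inclusive), < 5% mitochondrial (strict)
#' and >= 10% of genes detected (inclusive).
#'
#' @param min_total_reads minimum per-cell mapped reads (inclusive).
#' @param max_mito_fraction mitochondrial fraction bound (strict `<`).
#' @param min_gene_detect_fraction minimum detected-gene fraction
#'   (inclusive).
#' @return A classed list of the three thresholds.
#' @export
qcThresholds <- function(min_total_reads = 2e6,
                         max_mito_fraction = 0.05,
                         min_gene_detect_fraction = 0.10) {
  if (min_total_reads < 0)
    stopc("scmge_bad_config", "min_total_reads must be >= 0")
  if (max_mito_fraction < 0 || max_mito_fraction > 1 ||
      min_gene_detect_fraction < 0 || min_gene_detect_fraction > 1)
    stopc("scmge_bad_config", "QC fractions must lie in [0, 1]")
  structure(list(min_total_reads = min_total_reads,
                 max_mito_fraction = max_mito_fraction,
                 min_gene_detect_fraction = min_gene_detect_fraction),
            class = "QCThresholds")
}

#' Compute per-cell QC metrics
#'
#' For each cell: total mapped reads (from the cell table), the
#' mitochondrial read fraction (counts in mitochondria-flagged genes
#' over all counts in the matrix; 0 for an all-zero cell), the number of
#' genes detected (count > 0) and the detected-gene fraction.
#'
#' @param sc an [ScCounts] object.
#' @return A [S4Vectors::DataFrame] with one row per cell and columns
#'   `cell_id`, `total_mapped_reads`, `mito_read_fraction`,
#'   `genes_detected`, `gene_detect_fraction`.
#' @export
computeQCMetrics <- function(sc) {
  stopifnot(methods::is(sc, "ScCounts"))
  x <- counts(sc)
  mito <- geneData(sc)$is_mitochondrial
  tot <- colSums(x)
  mitoFrac <- ifelse(tot == 0, 0, colSums(x[mito, , drop = FALSE]) / tot)
  det <- colSums(x > 0)
  S4Vectors::DataFrame(
    cell_id = colnames(x),
    total_mapped_reads = cellData(sc)$total_mapped_reads,
    mito_read_fraction = unname(mitoFrac),
    genes_detected = unname(det),
    gene_detect_fraction = unname(det) / nrow(x),
    row.names = colnames(x))
}

#' Apply the QC gates
#'
#' A cell is kept iff `total_mapped_reads >= min_total_reads` AND
#' `mito_read_fraction < max_mito_fraction` (strict) AND
#' `gene_detect_fraction >= min_gene_detect_fraction`.  Cell order is
#' preserved; an empty result is permitted with a warning.
#'
#' @param metrics output of [computeQCMetrics()].
#' @param thresholds a [qcThresholds()] object.
#' @return Character vector of kept cell ids.
#' @export
filterCells <- function(metrics, thresholds = qcThresholds()) {
  keep <- metrics$total_mapped_reads >= thresholds$min_total_reads &
    metrics$mito_read_fraction < thresholds$max_mito_fraction &
    metrics$gene_detect_fraction >= thresholds$min_gene_detect_fraction
  out <- metrics$cell_id[keep]
  if (!length(out)) warnc("no cells pass the QC gates")
  out
}

#' nRPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `nRPKM(g, c) = count(g, c) * 1e9 / (length_bp(g) * total(c))`.  The
#' per-cell denominator `total(c)` is, by default, the total counts
#' assigned to annotated genes (the column sum of the matrix);
#' `denominator = "total_mapped_reads"` uses the cell table's mapped
#' read totals instead.  An all-zero cell yields an all-zero column.
#'
#' @param sc an [ScCounts] object with gene lengths.
#' @param denominator `"assigned"` (column sums, default) or
#'   `"total_mapped_reads"`.
#' @return An [ScExpr] with transform `"nRPKM"`; the denominator choice
#'   is recorded in the object's metadata.
#' @export
nrpkm <- function(sc, denominator = c("assigned", "total_mapped_reads")) {
  stopifnot(methods::is(sc, "ScCounts"))
  denominator <- match.arg(denominator)
  len <- geneData(sc)$length_bp
  if (any(len <= 0))
    stopc("scmge_bad_annotation", "gene lengths must be positive")
  x <- counts(sc)
  tot <- if (denominator == "assigned") colSums(x) else
    cellData(sc)$total_mapped_reads
  denom <- ifelse(tot == 0, 1, tot)  # all-zero column stays all-zero
  v <- sweep(x / len, 2L, denom / 1e9, `/`)
  out <- ScExpr(v, genes = geneData(sc), cells = cellData(sc),
                transform = "nRPKM")
  S4Vectors::metadata(out)$denominator <- denominator
  out
}

#' Molecule-count normalization (norm_mRNA_mol)
#'
#' Scales molecule counts per cell by `s(c) = total(c) / mean(total)`,
#' so the scaling factors average to 1 across cells:
#' `norm(g, c) = count(g, c) / s(c)`.
#'
#' @param sc an [ScCounts] object with `unit == "molecules"`.
#' @return An [ScExpr] with transform `"norm_mRNA_mol"`.
#' @export
normMrnaMol <- function(sc) {
  stopifnot(methods::is(sc, "ScCounts"))
  if (countUnit(sc) != "molecules")
    stopc("scmge_bad_unit", "norm_mRNA_mol requires molecule-unit counts")
  x <- counts(sc)
  tot <- colSums(x)
  mtot <- mean(tot)
  if (mtot == 0)
    stopc("scmge_degenerate", "all cells have zero total molecules")
  s <- tot / mtot
  v <- sweep(x, 2L, ifelse(s == 0, 1, s), `/`)
  ScExpr(v, genes = geneData(sc), cells = cellData(sc),
         transform = "norm_mRNA_mol")
}

#' log2(x + offset) stabilization
#'
#' @param expr an [ScExpr] with non-negative values (e.g. nRPKM).
#' @param offset pseudo-count added before the log (default 1, so
#'   0 maps to 0).
#' @return An [ScExpr] with transform `"log2p1"`.
#' @export
logStabilize <- function(expr, offset = 1) {
  stopifnot(methods::is(expr, "ScExpr"))
  x <- exprValues(expr)
  if (any(x < 0))
    stopc("scmge_negative_input", "log stabilization requires values >= 0")
  ScExpr(log2(x + offset), genes = geneData(expr), cells = cellData(expr),
         transform = "log2p1")
}
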