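#' @include AllClasses.R
NULL

#' Fill missing Ct values
#'
#' Replaces every missing (never-amplified) entry with the matrix's
#' `missing_fill` Ct (default 40); no other entry is altered.
#'
#' @param ct a [CtMatrix].
#' @return A dense [CtMatrix].
#' @export
imputeMissing <- function(ct) {
  stopifnot(methods::is(ct, "CtMatrix"))
  m <- ctValues(ct)
  m[is.na(m)] <- missingFill(ct)
  CtMatrix(m, reference_gene = referenceGene(ct),
           missing_fill = missingFill(ct))
}

#' Delta-Ct normalization
#'
#' Per cell, subtracts the reference gene's Ct (Actb by default):
#' `dCt(g, c) = Ct(g, c) - Ct(ref, c)`.  The reference gene's own row
#' is identically zero, and any assay-wide per-cell Ct offset cancels.
#'
#' @param ct an imputed (dense) [CtMatrix].
#' @return An [ScExpr] with transform `"delta_ct"`.
#' @export
deltaCt <- function(ct) {
  stopifnot(methods::is(ct, "CtMatrix"))
  m <- ctValues(ct)
  if (anyNA(m))
    stopc("scmge_missing_values", "impute missing Ct values first")
  ref <- referenceGene(ct)
  if (!ref %in% rownames(m))
    stopc("scmge_missing_reference", "reference gene '%s' not present", ref)
  d <- sweep(m, 2L, m[ref, ], `-`)
  ScExpr(d, transform = "delta_ct")
}

#' Per-gene Z-score normalization
#'
#' Each gene row is centered and scaled by its population (divide-by-n)
#' standard deviation; zero-variance rows become all zeros with a
#' warning.
#'
#' @param x an [ScExpr] or numeric matrix.
#' @return An [ScExpr] with transform `"zscore"`.
#' @export
zscoreGenes <- function(x) {
  m <- if (methods::is(x, "ScExpr")) exprValues(x) else as.matrix(x)
  s <- .rowSdPop(m)
  if (any(s == 0)) warnc("%d zero-variance rows set to 0", sum(s == 0))
  z <- (m - rowMeans(m)) / ifelse(s == 0, 1, s)
  ScExpr(z, transform = "zscore")
}
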