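#' @include AllClasses.R
NULL

#' Variance-stabilize a count matrix
#'
#' Counts are first scaled by per-cell size factors (DESeq-style median
#' of ratios over genes with all-nonzero counts, falling back to
#' column-sum ratios when no such gene exists).  `method = "log2p1"`
#' then applies `log2(x + 1)`; `method = "nb_vst"` applies the
#' closed-form negative-binomial stabilizer
#' `y = (2 / sqrt(alpha)) * asinh(sqrt(alpha * x))` with a single
#' dispersion `alpha` fitted by the method of moments
#' (`alpha = sum(var_g - mean_g) / sum(mean_g^2)` over expressed
#' genes).  A non-positive dispersion estimate falls back to `log2p1`
#' with a warning.  In the small-dispersion limit the stabilizer
#' approaches `2 * sqrt(x)`.
#'
#' @param sc an [ScCounts] object.
#' @param method `"log2p1"` or `"nb_vst"`.
#' @return An [ScExpr] with transform `"vst"`; size factors and the
#'   fitted dispersion are recorded in its metadata.
#' @export
varianceStabilize <- function(sc, method = c("log2p1", "nb_vst")) {
  stopifnot(methods::is(sc, "ScCounts"))
  method <- match.arg(method)
  x <- counts(sc)
  allPos <- rowSums(x == 0) == 0L
  if (any(allPos)) {
    logGeo <- rowMeans(log(x[allPos, , drop = FALSE]))
    sf <- apply(x[allPos, , drop = FALSE], 2L,
                function(col) exp(stats::median(log(col) - logGeo)))
  } else {
    cs <- colSums(x)
    sf <- cs / mean(cs)
  }
  sf[sf == 0] <- 1
  scaled <- sweep(x, 2L, sf, `/`)
  alpha <- NA_real_
  if (method == "nb_vst") {
    m <- rowMeans(scaled)
    v <- .rowVars(scaled)
    expressed <- m > 0
    alpha <- sum(v[expressed] - m[expressed]) / sum(m[expressed]^2)
    if (!is.finite(alpha) || alpha <= 0) {
      warnc("non-positive dispersion estimate (%.3g); falling back to log2p1",
            alpha)
      method <- "log2p1"
    }
  }
  y <- if (method == "nb_vst") (2 / sqrt(alpha)) * asinh(sqrt(alpha * scaled))
       else log2(scaled + 1)
  out <- ScExpr(y, genes = geneData(sc), cells = cellData(sc),
                transform = "vst")
  S4Vectors::metadata(out) <- list(method = method, size_factors = sf,
                                   dispersion = alpha)
  out
}

#' Select the most variable genes
#'
#' The `n` genes with the largest across-cell variance of (stabilized)
#' expression; ties at the cutoff are broken by lexicographic gene id,
#' so the selection is deterministic.
#'
#' @param expr an [ScExpr] (typically variance-stabilized).
#' @param n number of genes to keep (default 500).
#' @return Character vector of gene ids, most variable first.
#' @export
selectVariableGenes <- function(expr, n = 500L) {
  stopifnot(methods::is(expr, "ScExpr"))
  x <- exprValues(expr)
  if (n > nrow(x))
    stopc("scmge_bad_config", "n = %d exceeds the %d available genes", n, nrow(x))
  v <- .rowVars(x)
  ord <- order(-v, rownames(x), method = "radix")
  rownames(x)[ord][seq_len(n)]
}

#' Principal component analysis by exact SVD
#'
#' Genes are centered (not scaled; the input is already
#' variance-stabilized, and unit-variance scaling would undo the
#' stabilizer — set `scale_genes = TRUE` to scale anyway), the matrix is
#' restricted to `genes`, and an exact SVD taken.  Scores are
#' `U %*% D`, loadings the orthonormal right singular vectors; the sign
#' of each component is fixed so its largest-magnitude loading entry is
#' non-negative.
#'
#' @param expr an [ScExpr].
#' @param genes gene ids to use (e.g. from [selectVariableGenes()]);
#'   `NULL` uses all genes.
#' @param k number of components (<= min(n_cells, n_genes)).
#' @param scale_genes also scale genes to unit variance (default FALSE).
#' @return A [PCModel].
#' @export
runPCA <- function(expr, genes = NULL, k = 10L, scale_genes = FALSE) {
  stopifnot(methods::is(expr, "ScExpr"))
  x <- exprValues(expr)
  if (is.null(genes)) genes <- rownames(x)
  if (!all(genes %in% rownames(x)))
    stopc("scmge_bad_config", "unknown gene ids in `genes`")
  x <- x[genes, , drop = FALSE]
  if (k > min(ncol(x), nrow(x)))
    stopc("scmge_bad_config", "k = %d exceeds min(n_cells, n_genes) = %d",
          k, min(ncol(x), nrow(x)))
  ctr <- rowMeans(x)
  xc <- x - ctr
  if (scale_genes) {
    sdv <- sqrt(.rowVars(x))
    sdv[sdv == 0] <- 1
    xc <- xc / sdv
  }
  sv <- svd(t(xc))  # cells x genes
  d2 <- sv$d^2
  tot <- sum(d2)
  ve <- if (tot > 0) d2[seq_len(k)] / tot else rep(0, k)
  if (tot == 0) warnc("degenerate input: all components have zero variance")
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(genes, paste0("PC", seq_len(k)))
  methods::new("PCModel", variableGenes = genes, scores = scores,
               loadings = loadings, varianceExplained = ve, center = ctr)
}

#' Expression prefilter for PC-gene association
#'
#' Keeps genes with nRPKM >= `expr_threshold` in at least `prevalence`
#' of the cells (both bounds inclusive).
#'
#' @param nrpkm_expr an [ScExpr] with transform `"nRPKM"`.
#' @param expr_threshold expression level (default 0.5 nRPKM).
#' @param prevalence required cell fraction (default 0.25).
#' @return Character vector of kept gene ids.
#' @export
pcGenePrefilter <- function(nrpkm_expr, expr_threshold = 0.5,
                            prevalence = 0.25) {
  stopifnot(methods::is(nrpkm_expr, "ScExpr"))
  x <- exprValues(nrpkm_expr)
  keep <- rowMeans(x >= expr_threshold) >= prevalence
  rownames(x)[keep]
}

# method-of-moments fit of a scaled-F prior to residual variances on the
# log scale; df is the (scalar) residual degrees of freedom
.fitVarPrior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 3L)
    return(list(df_prior = 0, var_prior = stats::median(s2[ok])))
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(df_prior = d0, var_prior = s02)
}

#' Associate genes with a principal component
#'
#' Per gene, ordinary least squares of log expression on the scores of
#' one principal component (intercept + slope).  With
#' `moderate = TRUE` (default) residual variances are shrunk toward a
#' common prior by an empirical-Bayes squeeze,
#' `s2_post = (d0 * s0^2 + d * s2) / (d0 + d)`, with the prior
#' `(d0, s0^2)` fitted by the method of moments on the log residual
#' variances; the moderated t-statistic then has `d0 + d` degrees of
#' freedom.  Genes constant across cells get `p = 1`.
#'
#' @param logexpr an [ScExpr] of log-scale expression (prefiltered with
#'   [pcGenePrefilter()] upstream).
#' @param pc a [PCModel] over the same cells.
#' @param component which component (1-based).
#' @param alpha selection threshold on the two-sided p-value
#'   (default 1e-4; applied per component, no cross-component
#'   correction).
#' @param moderate use the empirical-Bayes variance squeeze.
#' @return A [S4Vectors::DataFrame] with columns `gene_id`,
#'   `component`, `slope`, `t_statistic`, `p_value`, `selected`.
#' @export
pcAssociation <- function(logexpr, pc, component, alpha = 1e-4,
                          moderate = TRUE) {
  stopifnot(methods::is(logexpr, "ScExpr"), methods::is(pc, "PCModel"))
  y <- exprValues(logexpr)
  sc <- pcScores(pc)
  if (!all(colnames(y) %in% rownames(sc)))
    stopc("scmge_dim_mismatch", "PC model lacks scores for some cells")
  if (component < 1L || component > ncol(sc))
    stopc("scmge_bad_config", "component must lie in 1..%d", ncol(sc))
  x <- sc[colnames(y), component]
  n <- length(x)
  if (n < 3L) stopc("scmge_degenerate", "need >= 3 cells")
  xc <- x - mean(x)
  Sxx <- sum(xc^2)
  if (Sxx == 0) stopc("scmge_degenerate", "component scores have zero variance")
  yc <- y - rowMeans(y)
  slope <- as.vector(yc %*% xc) / Sxx
  rss <- pmax(rowSums(yc^2) - slope^2 * Sxx, 0)
  df <- n - 2L
  s2 <- rss / df
  constGene <- .rowVars(y) <= 0
  if (moderate) {
    prior <- .fitVarPrior(s2[!constGene], df)
    d0 <- prior$df_prior
    s2post <- if (is.infinite(d0)) rep(prior$var_prior, length(s2)) else
      (d0 * prior$var_prior + df * s2) / (d0 + df)
    tstat <- slope / sqrt(s2post / Sxx)
    dfTot <- d0 + df
  } else {
    tstat <- slope / sqrt(s2 / Sxx)
    dfTot <- df
  }
  p <- 2 * stats::pt(-abs(tstat), df = dfTot)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  slope[constGene] <- 0
  tstat[constGene] <- 0
  p[constGene] <- 1
  S4Vectors::DataFrame(
    gene_id = rownames(y), component = as.integer(component),
    slope = slope, t_statistic = tstat, p_value = p,
    selected = p <= alpha, row.names = rownames(y))
}

#' Genes associated with any of the leading components
#'
#' Convenience wrapper running [pcAssociation()] for each requested
#' component and returning the union of selected genes (significant for
#' at least one component at `alpha`).
#'
#' @inheritParams pcAssociation
#' @param components components to scan (default the first four).
#' @return Character vector of selected gene ids (input gene order).
#' @export
pcSelectedGenes <- function(logexpr, pc, components = 1:4, alpha = 1e-4,
                            moderate = TRUE) {
  sel <- Reduce(`|`, lapply(components, function(j)
    pcAssociation(logexpr, pc, j, alpha = alpha, moderate = moderate)$selected))
  rownames(exprValues(logexpr))[sel]
}

#' Agglomerative hierarchical clustering
#'
#' Clusters cells (columns) or genes (rows) with a configurable
#' distance (default 1 - Pearson correlation) and linkage (default
#' average).  Items are pre-sorted by id so the dendrogram is
#' deterministic under input reordering; an item constant across the
#' other axis has undefined correlation and is placed at the maximal
#' distance 1 with a warning.
#'
#' @param x an [ScExpr] or numeric matrix.
#' @param axis `"cells"` or `"genes"`.
#' @param k optional number of flat clusters to cut to.
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage any [stats::hclust] method (default `"average"`).
#' @return A [ClusterResult].
#' @export
hcluster <- function(x, axis = c("cells", "genes"), k = NULL,
                     distance = c("correlation", "euclidean"),
                     linkage = "average") {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  m <- if (methods::is(x, "ScExpr")) exprValues(x) else as.matrix(x)
  if (axis == "genes") m <- t(m)
  items <- colnames(m)
  if (is.null(items)) items <- sprintf("item%04d", seq_len(ncol(m)))
  colnames(m) <- items
  if (ncol(m) < 2L)
    stopc("scmge_degenerate", "need >= 2 items to cluster")
  m <- m[, order(items, method = "radix"), drop = FALSE]
  items <- colnames(m)
  if (distance == "correlation") {
    cc <- suppressWarnings(stats::cor(m))
    if (anyNA(cc)) {
      warnc("constant items: correlation undefined, using maximal distance 1")
      cc[is.na(cc)] <- 0
    }
    d <- stats::as.dist(1 - cc)
  } else {
    d <- stats::dist(t(m))
  }
  hc <- stats::hclust(d, method = linkage)
  labels <- if (is.null(k)) integer(0) else stats::cutree(hc, k = k)
  methods::new("ClusterResult", tree = hc, leafOrder = items[hc$order],
               labels = labels, axis = axis)
}
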