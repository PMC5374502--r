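#' @include AllClasses.R
NULL

#' Prevalence rule for marker derivation
#'
#' A gene is a marker for a cell type if it is expressed at or above
#' `expr_threshold` in at least `expr_prevalence` of that type's cells,
#' and is "detected" (strictly above `detect_threshold`) in fewer than
#' `detect_prevalence` of the cells of every other type (inclusive
#' disqualification: detection in exactly `detect_prevalence` of
#' another type disqualifies).  The reference-transfer variant uses
#' prevalence 0.75 on normalized molecule counts; the within-dataset
#' variant uses 0.50 on nRPKM.
#'
#' @param expr_threshold expression level for the positive clause
#'   (default 1.0, inclusive).
#' @param expr_prevalence required fraction of own-type cells
#'   (default 0.75; use 0.50 for the within-dataset variant).
#' @param detect_threshold detection level for the negative clause
#'   (default 0, strict `>`).
#' @param detect_prevalence disqualifying detection fraction in other
#'   types (default 0.25).
#' @param scope `"each_other_type"` (the negative clause must hold
#'   against every other type separately, default) or
#'   `"pooled_other_types"` (against all other cells pooled).
#' @return A classed list.
#' @export
markerRule <- function(expr_threshold = 1.0, expr_prevalence = 0.75,
                       detect_threshold = 0, detect_prevalence = 0.25,
                       scope = c("each_other_type", "pooled_other_types")) {
  scope <- match.arg(scope)
  if (expr_prevalence <= 0 || expr_prevalence > 1 ||
      detect_prevalence <= 0 || detect_prevalence > 1)
    stopc("scmge_bad_config", "prevalences must lie in (0, 1]")
  if (expr_threshold <= detect_threshold)
    stopc("scmge_bad_config", "expr_threshold must exceed detect_threshold")
  structure(list(expr_threshold = expr_threshold,
                 expr_prevalence = expr_prevalence,
                 detect_threshold = detect_threshold,
                 detect_prevalence = detect_prevalence,
                 scope = scope), class = "MarkerRule")
}

#' Derive cell-type-specific markers
#'
#' Applies the prevalence rule of [markerRule()] to a labelled
#' normalized expression matrix (norm_mRNA_mol for a labelled
#' reference, nRPKM within-dataset).  With a single labelled type the
#' exclusion clause is vacuously true (warning).
#'
#' @param norm an [ScExpr] of normalized expression.
#' @param labels named character vector: cell id -> type label; every
#'   labelled type must have at least one cell in `norm`.
#' @param rule a [markerRule()].
#' @param provenance free-text dataset tag stored in the result.
#' @return A [MarkerSet].
#' @export
deriveMarkers <- function(norm, labels, rule = markerRule(),
                          provenance = "dataset") {
  stopifnot(methods::is(norm, "ScExpr"))
  x <- exprValues(norm)
  labels <- labels[names(labels) %in% colnames(x)]
  types <- sort(unique(unname(labels)))
  if (!length(types)) stopc("scmge_empty_group", "no labelled cells")
  if (length(types) == 1L)
    warnc("single labelled type: exclusion clause is vacuous")
  fracAbove <- function(thr, strict) vapply(types, function(ty) {
    sub <- x[, names(labels)[labels == ty], drop = FALSE]
    rowMeans(if (strict) sub > thr else sub >= thr)
  }, numeric(nrow(x)))
  exprFrac <- matrix(fracAbove(rule$expr_threshold, FALSE), nrow = nrow(x),
                     dimnames = list(rownames(x), types))
  detFrac <- matrix(fracAbove(rule$detect_threshold, TRUE), nrow = nrow(x),
                    dimnames = list(rownames(x), types))
  markers <- lapply(types, function(ty) {
    own <- exprFrac[, ty] >= rule$expr_prevalence
    others <- setdiff(types, ty)
    excl <- if (!length(others)) rep(TRUE, nrow(x))
    else if (rule$scope == "each_other_type")
      rowSums(detFrac[, others, drop = FALSE] >= rule$detect_prevalence) == 0L
    else {
      pooled <- rowMeans(x[, names(labels)[labels %in% others],
                           drop = FALSE] > rule$detect_threshold)
      pooled < rule$detect_prevalence
    }
    rownames(x)[own & excl]
  })
  methods::new("MarkerSet", markers = stats::setNames(markers, types),
               rule = unclass(rule), provenance = provenance)
}

#' Rule-based cell-type classification
#'
#' Counts, per cell and type, the markers expressed above
#' `call_threshold`; a cell is assigned the unique type reaching
#' `min_markers` hits, marked `excluded_conflict` when two or more
#' types reach it, and `unassigned` otherwise.  Explicit exclusion
#' rules mirror ad-hoc curation: a pair rule
#' `(typeX, typeY, "exclude")` turns a cell with >= `min_markers` hits
#' for both into `excluded_conflict` even if one is below the
#' assignment bar, and `(typeX, "*", "implausible")` relabels any cell
#' assigned `typeX` as `excluded_implausible`.
#'
#' @param expr an [ScExpr] (any normalized transform).
#' @param markers a [MarkerSet]; marker genes absent from `expr` are
#'   dropped with a warning.
#' @param min_markers hits needed for assignment (default 4).
#' @param exclusions optional `data.frame(type_a, type_b, action)` with
#'   `action` in `"exclude"` / `"implausible"`.
#' @param call_threshold expression level counting as a hit
#'   (default 0, strict `>`).
#' @return A [CellTypeCall].
#' @export
classifyCells <- function(expr, markers, min_markers = 4L,
                          exclusions = NULL, call_threshold = 0) {
  stopifnot(methods::is(expr, "ScExpr"), methods::is(markers, "MarkerSet"))
  ml <- markerList(markers)
  if (!length(ml)) stopc("scmge_empty_group", "empty MarkerSet")
  x <- exprValues(expr)
  missing <- setdiff(unlist(ml), rownames(x))
  if (length(missing)) {
    warnc("%d marker genes absent from the expression matrix; dropped",
          length(missing))
    ml <- lapply(ml, intersect, rownames(x))
  }
  types <- names(ml)
  hits <- sapply(types, function(ty) {
    g <- ml[[ty]]
    if (!length(g)) return(rep(0L, ncol(x)))
    colSums(x[g, , drop = FALSE] > call_threshold)
  })
  hits <- matrix(as.integer(hits), nrow = ncol(x),
                 dimnames = list(colnames(x), types))
  reach <- hits >= min_markers
  nReach <- rowSums(reach)
  assigned <- rep("unassigned", ncol(x))
  one <- nReach == 1L
  assigned[one] <- types[apply(reach[one, , drop = FALSE], 1L, which)]
  assigned[nReach >= 2L] <- "excluded_conflict"
  if (!is.null(exclusions) && nrow(exclusions)) {
    for (i in seq_len(nrow(exclusions))) {
      a <- exclusions$type_a[i]; b <- exclusions$type_b[i]
      act <- exclusions$action[i]
      if (identical(b, "*")) {
        hit <- assigned == a
        assigned[hit] <- if (act == "implausible") "excluded_implausible"
                         else "excluded_conflict"
      } else if (all(c(a, b) %in% types)) {
        hit <- reach[, a] & reach[, b]
        assigned[hit] <- if (act == "implausible") "excluded_implausible"
                         else "excluded_conflict"
      }
    }
  }
  methods::new("CellTypeCall", hits = hits,
               assigned = stats::setNames(assigned, colnames(x)),
               minMarkers = as.integer(min_markers))
}

#' Supervised two-signature classification
#'
#' Scores each cell by its mean z-scored expression over an "up" and a
#' "down" gene signature (e.g. the top DE genes of two reference
#' populations) and assigns the higher-scoring class; cells whose score
#' difference does not exceed `margin` are `ambiguous`.
#'
#' @param expr an [ScExpr] z-scored per gene (see [zscoreGenes()]).
#' @param sig_up,sig_down non-empty gene-id signatures; absent genes
#'   are dropped with a warning.
#' @param margin required score separation (default 0: hard argmax,
#'   exact ties ambiguous).
#' @param class_labels labels for the two classes.
#' @return Named character vector: cell id -> class label or
#'   `"ambiguous"`.
#' @export
signatureClassify <- function(expr, sig_up, sig_down, margin = 0,
                              class_labels = c("classA", "classB")) {
  stopifnot(methods::is(expr, "ScExpr"))
  x <- exprValues(expr)
  dropN <- sum(!c(sig_up, sig_down) %in% rownames(x))
  if (dropN) warnc("%d signature genes absent from the matrix; dropped", dropN)
  sig_up <- intersect(sig_up, rownames(x))
  sig_down <- intersect(sig_down, rownames(x))
  if (!length(sig_up) || !length(sig_down))
    stopc("scmge_empty_group", "a signature is empty after dropping")
  sA <- colMeans(x[sig_up, , drop = FALSE])
  sB <- colMeans(x[sig_down, , drop = FALSE])
  out <- rep("ambiguous", ncol(x))
  out[sA - sB > margin] <- class_labels[1L]
  out[sB - sA > margin] <- class_labels[2L]
  stats::setNames(out, colnames(x))
}

#' Test for an increased class proportion versus a baseline condition
#'
#' For each non-baseline condition, a one-sided test that the class
#' proportion exceeds the baseline's: Fisher's exact test (upper
#' hypergeometric tail) or the pooled two-proportion z-test.
#'
#' @param calls `data.frame(condition, successes, total)`, one row per
#'   condition (successes = cells of the class of interest).
#' @param baseline the baseline condition name.
#' @param test `"fisher"` (default) or `"two_proportion_z"`.
#' @return `data.frame(condition, p_value)` for non-baseline conditions.
#' @export
proportionTrend <- function(calls, baseline,
                            test = c("fisher", "two_proportion_z")) {
  test <- match.arg(test)
  if (!baseline %in% calls$condition)
    stopc("scmge_bad_config", "baseline '%s' not among conditions", baseline)
  if (any(calls$total <= 0))
    stopc("scmge_degenerate", "every condition needs a positive total")
  b <- calls[calls$condition == baseline, ]
  others <- calls[calls$condition != baseline, , drop = FALSE]
  p <- vapply(seq_len(nrow(others)), function(i) {
    k1 <- others$successes[i]; n1 <- others$total[i]
    k0 <- b$successes; n0 <- b$total
    if (test == "fisher") {
      stats::fisher.test(matrix(c(k1, n1 - k1, k0, n0 - k0), nrow = 2L),
                         alternative = "greater")$p.value
    } else {
      ph <- (k1 + k0) / (n1 + n0)
      se <- sqrt(ph * (1 - ph) * (1 / n1 + 1 / n0))
      if (se == 0) return(1)
      stats::pnorm((k1 / n1 - k0 / n0) / se, lower.tail = FALSE)
    }
  }, numeric(1L))
  data.frame(condition = others$condition, p_value = p, row.names = NULL)
}
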