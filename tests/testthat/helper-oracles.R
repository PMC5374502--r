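# Independent brute-force oracles used to pin expected values.

# two-sided Mann-Whitney p by full enumeration of group assignments
mwEnumOracle <- function(a, b) {
  x <- c(a, b)
  nA <- length(a)
  uObs <- sum(outer(a, b, `>`)) + 0.5 * sum(outer(a, b, `==`))
  idx <- utils::combn(length(x), nA)
  us <- apply(idx, 2L, function(i)
    sum(outer(x[i], x[-i], `>`)) + 0.5 * sum(outer(x[i], x[-i], `==`)))
  pLe <- mean(us <= uObs)
  pGe <- mean(us >= uObs)
  min(1, 2 * min(pLe, pGe))
}

# Holm step-down, written independently of p.adjust
holmOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  cur <- 0
  for (i in seq_len(m)) {
    cur <- max(cur, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, cur)
  }
  adj
}

# Benjamini-Hochberg step-up, written independently of p.adjust
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  cur <- Inf
  for (i in seq_len(m)) {
    r <- m - i + 1
    cur <- min(cur, m / r * p[o[i]])
    adj[o[i]] <- min(1, cur)
  }
  adj
}

# naive agglomeration returning merge heights in merge order
linkageOracle <- function(D, method = c("single", "average")) {
  method <- match.arg(method)
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    bestD <- Inf
    for (i in seq_len(length(clusters) - 1L)) for (j in seq(i + 1L, length(clusters))) {
      cross <- D[clusters[[i]], clusters[[j]], drop = FALSE]
      dd <- if (method == "single") min(cross) else mean(cross)
      if (dd < bestD) { bestD <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestD)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# quick ScCounts around a plain matrix
makeCounts <- function(m, mito = rep(FALSE, nrow(m)),
                       lengths = rep(1000L, nrow(m)),
                       reads = rep(2e6, ncol(m)),
                       condition = rep("c1", ncol(m)),
                       unit = "reads") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  ScCounts(m,
           data.frame(gene_id = rownames(m), symbol = rownames(m),
                      length_bp = lengths, is_mitochondrial = mito),
           data.frame(cell_id = colnames(m), condition = condition,
                      total_mapped_reads = reads),
           unit = unit)
}

makeExpr <- function(m, transform = "nRPKM") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  ScExpr(m, transform = transform)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
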