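test_that("the NB stabilizer approaches 2*sqrt(x) for small dispersion", {
  set.seed(6)
  mns <- runif(60, 10, 200)
  cnt <- t(sapply(mns, function(m) rnbinom(100, mu = m, size = 1 / 1e-4)))
  sc <- makeCounts(cnt)
  v <- varianceStabilize(sc, "nb_vst")
  expect_equal(S4Vectors::metadata(v)$method, "nb_vst")
  sf <- S4Vectors::metadata(v)$size_factors
  scaled <- sweep(counts(sc), 2, sf, `/`)
  big <- scaled >= 10
  expect_true(all(abs(exprValues(v)[big] / (2 * sqrt(scaled[big])) - 1) < 0.01))
})

test_that("stabilization flattens the variance-mean trend", {
  set.seed(6)
  mns <- exp(seq(log(2), log(200), length.out = 50))
  cnt <- t(sapply(mns, function(m) rnbinom(200, mu = m, size = 1 / 0.3)))
  sc <- makeCounts(cnt)
  v <- exprValues(varianceStabilize(sc, "nb_vst"))
  vr <- apply(v, 1, var)
  vu <- apply(cnt, 1, var)
  expect_lt(max(vr) / min(vr), 3)
  expect_gt(max(vu) / min(vu), 10)
  # a constant gene stays constant up to size-factor scaling
  cnt2 <- rbind(cnt, rep(5L, 200))
  rownames(cnt2) <- NULL
  v2 <- exprValues(varianceStabilize(makeCounts(cnt2), "log2p1"))
  expect_lt(var(v2[nrow(v2), ]), var(v2[1, ]))
})

test_that("variable-gene selection is deterministic with the stated tie rule", {
  m <- matrix(1, nrow = 3, ncol = 4,
              dimnames = list(c("gB", "gA", "gC"), NULL))
  m["gC", ] <- c(1, 1, 4, 4)  # variance 3, others 0
  e <- makeExpr(m, transform = "vst")
  expect_equal(selectVariableGenes(e, 1), "gC")
  # gA and gB tied at zero variance: lexicographically smaller id kept
  expect_equal(selectVariableGenes(e, 2), c("gC", "gA"))
  expect_error(selectVariableGenes(e, 10), class = "scmge_bad_config")
})

test_that("PCA separates planted blocks and is invariant to duplication", {
  m <- matrix(0, nrow = 10, ncol = 8)
  m[1:5, 1:4] <- 5 + matrix(rnorm(20, sd = 0.1), 5)
  m[6:10, 5:8] <- 5 + matrix(rnorm(20, sd = 0.1), 5)
  e <- makeExpr(m, transform = "vst")
  pc <- runPCA(e, k = 3)
  s1 <- pcScores(pc)[, 1]
  expect_true(max(s1[1:4]) < min(s1[5:8]) || min(s1[1:4]) > max(s1[5:8]))

  dup <- makeExpr(cbind(m, m), transform = "vst")
  pcd <- runPCA(dup, k = 3)
  expect_equal(abs(pcLoadings(pcd)), abs(pcLoadings(pc)), tolerance = 1e-8)

  # gene reordering leaves scores unchanged (sign fixed by convention)
  perm <- c(7, 2, 9, 1, 10, 3, 6, 4, 8, 5)
  pcp <- runPCA(makeExpr(m[perm, ], transform = "vst"), k = 3)
  expect_equal(pcScores(pcp), pcScores(pc), tolerance = 1e-8)
})

test_that("a full-rank PCA accounts for all variance", {
  set.seed(7)
  e <- makeExpr(matrix(rnorm(12 * 6), nrow = 12), transform = "vst")
  pc <- runPCA(e, k = 6)
  expect_equal(sum(varianceExplained(pc)), 1, tolerance = 1e-8)
  expect_true(all(diff(varianceExplained(pc)) <= 1e-12))
  expect_error(runPCA(e, k = 7), class = "scmge_bad_config")
})

test_that("the nRPKM prefilter applies inclusive boundaries", {
  m <- matrix(0, nrow = 3, ncol = 100,
              dimnames = list(c("gA", "gB", "gC"), NULL))
  m["gA", 1:25] <- 0.5        # exactly 0.5 in exactly 25% -> kept
  m["gB", ] <- 0.49           # everywhere below threshold -> dropped
  e <- makeExpr(m, transform = "nRPKM")
  expect_equal(pcGenePrefilter(e), "gA")
})

test_that("unmoderated PC association matches an independent OLS fit", {
  set.seed(8)
  n <- 10
  x <- rnorm(n)
  y <- matrix(rnorm(6 * n), nrow = 6)
  y[1, ] <- x  # perfect fit
  y[2, ] <- 3  # constant
  e <- makeExpr(y, transform = "log2p1")
  pcm <- runPCA(e, k = 2)  # placeholder scores replaced below
  pcm@scores[, 1] <- x
  res <- pcAssociation(e, pcm, 1, moderate = FALSE)
  for (i in 3:6) {
    fit <- summary(lm(y[i, ] ~ x))$coefficients
    expect_equal(unname(res$t_statistic[i]), fit[[2, 3]], tolerance = 1e-10)
    expect_equal(unname(res$p_value[i]), fit[[2, 4]], tolerance = 1e-10)
  }
  expect_lt(res$p_value[[1]], 1e-10)
  expect_true(res$selected[1])
  expect_equal(unname(res$p_value[2]), 1)
  expect_false(res$selected[2])
})

test_that("the moderated test tracks the reference empirical-Bayes fit", {
  set.seed(5)
  n <- 30; g <- 120
  x <- rnorm(n)
  y <- matrix(rnorm(g * n), g)
  y[1:10, ] <- y[1:10, ] + outer(rep(2, 10), x)
  e <- makeExpr(y, transform = "log2p1")
  pcm <- runPCA(e, k = 2)
  pcm@scores[, 1] <- x
  mine <- pcAssociation(e, pcm, 1, moderate = TRUE)
  fit <- limma::eBayes(limma::lmFit(y, cbind(1, x)))
  expect_equal(mine$t_statistic, unname(fit$t[, 2]), tolerance = 0.05)
  expect_equal(mine$p_value, unname(fit$p.value[, 2]), tolerance = 0.01)
  expect_true(all(mine$selected == (mine$p_value <= 1e-4)))
})

test_that("association p-values are uniform under a permuted-score null", {
  set.seed(11)
  y <- matrix(rnorm(200 * 50), 200)
  e <- makeExpr(y, transform = "log2p1")
  pcm <- runPCA(e, k = 2)
  pcm@scores[, 1] <- sample(pcm@scores[, 1])
  p <- pcAssociation(e, pcm, 1)$p_value
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("degenerate association inputs raise errors", {
  e <- makeExpr(matrix(rnorm(40), 4), transform = "log2p1")
  pcm <- runPCA(e, k = 2)
  pcm@scores[, 2] <- 0
  expect_error(pcAssociation(e, pcm, 2), class = "scmge_degenerate")
  expect_error(pcAssociation(e, pcm, 9), class = "scmge_bad_config")
})

test_that("hierarchical clustering recovers duplicate pairs and matches a brute-force linkage oracle", {
  m <- matrix(rnorm(40), nrow = 10)
  m <- cbind(m[, 1], m[, 1], m[, 3], m[, 3])
  colnames(m) <- c("a1", "a2", "b1", "b2")
  cl <- hcluster(m, axis = "cells", k = 2)
  lab <- clusterLabels(cl)
  expect_equal(lab[["a1"]], lab[["a2"]])
  expect_equal(lab[["b1"]], lab[["b2"]])
  expect_true(lab[["a1"]] != lab[["b1"]])

  # 5 points on a line: heights must match the naive agglomerator,
  # and single vs average linkage must genuinely differ
  pts <- c(1, 2, 4, 8, 16)
  D <- as.matrix(dist(pts))
  hs <- hcluster(matrix(pts, nrow = 1), axis = "cells",
                 distance = "euclidean", linkage = "single")
  ha <- hcluster(matrix(pts, nrow = 1), axis = "cells",
                 distance = "euclidean", linkage = "average")
  expect_equal(clusterTree(hs)$height, linkageOracle(D, "single"),
               tolerance = 1e-12)
  expect_equal(clusterTree(ha)$height, linkageOracle(D, "average"),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(clusterTree(hs)$height,
                                clusterTree(ha)$height)))
})

test_that("constant items get maximal correlation distance with a warning", {
  m <- matrix(rnorm(30), nrow = 10)
  m[, 2] <- 7  # constant cell
  colnames(m) <- c("a", "b", "c")
  expect_warning(cl <- hcluster(m, axis = "cells", k = 2), "constant")
  expect_equal(length(clusterLabels(cl)), 3L)
})
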