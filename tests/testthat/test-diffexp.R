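test_that("the count prefilter applies its boundaries literally", {
  m <- matrix(0L, nrow = 3, ncol = 6,
              dimnames = list(c("gA", "gB", "gC"), sprintf("c%d", 1:6)))
  m["gA", 1:3] <- 10L             # exactly 10 in exactly 3 cells -> kept
  m["gB", 1:3] <- c(9L, 100L, 100L)  # only 2 cells reach 10 -> dropped
  sc <- makeCounts(m)
  A <- c("c1", "c2", "c3"); B <- c("c4", "c5", "c6")
  expect_equal(dePrefilter(sc, A, B), "gA")
  expect_error(dePrefilter(sc, A, c("c3", "c4")),
               class = "scmge_overlapping_groups")
  expect_error(dePrefilter(sc, character(0), B), class = "scmge_empty_group")
})

test_that("Mann-Whitney p-values match enumeration and handle symmetry", {
  expect_equal(mannWhitney(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(mannWhitney(c(1, 2, 3), c(4, 5, 6)),
               mwEnumOracle(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(mannWhitney(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(mannWhitney(numeric(0), 1), class = "scmge_empty_group")
})

test_that("exact and approximate Mann-Whitney agree closely at moderate n", {
  set.seed(3)
  for (i in 1:200) {
    a <- runif(8); b <- runif(8)
    expect_lt(abs(mannWhitney(a, b, exact_max_n = 16) -
                  mannWhitney(a, b, exact_max_n = 0)), 0.02)
  }
})

test_that("the rank test is invariant to strictly monotone transforms", {
  set.seed(4)
  for (i in 1:20) {
    a <- rexp(7); b <- rexp(9)
    expect_equal(mannWhitney(a, b), mannWhitney(exp(a), exp(b)))
    expect_equal(mannWhitney(a, b), mannWhitney(log(a), log(b)))
  }
})

test_that("the floored-median fold-change reproduces forced values", {
  x <- c(a1 = 4, a2 = 4, a3 = 4, b1 = 1, b2 = 1, b3 = 1)
  A <- c("a1", "a2", "a3"); B <- c("b1", "b2", "b3")
  expect_equal(medianLFC(x, A, B), 2)         # log2 4 - log2 1
  x0 <- c(a1 = 4, a2 = 4, a3 = 4, b1 = 0, b2 = 0, b3 = 0)
  expect_equal(medianLFC(x0, A, B), 10)       # 2 - (-8), floor rule
  expect_equal(medianLFC(x, A, A), 0)
  # antisymmetry on random inputs
  set.seed(5)
  for (i in 1:20) {
    v <- setNames(rexp(10) * rbinom(10, 1, 0.7), sprintf("c%d", 1:10))
    A2 <- sprintf("c%d", 1:5); B2 <- sprintf("c%d", 6:10)
    expect_equal(medianLFC(v, A2, B2), -medianLFC(v, B2, A2))
  }
  # the raw-median reading floors after taking medians
  expect_equal(medianLFC(x0, A, B, scale = "raw_median"), 2 - (-8))
  xh <- c(a1 = 4, a2 = 4, a3 = 4, b1 = 0, b2 = 2, b3 = 2)
  expect_equal(medianLFC(xh, A, B, scale = "raw_median"), 2 - 1)
})

test_that("Holm and BH adjustments match hand-derived values and the oracle", {
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03), "holm"),
               c(0.03, 0.04, 0.04))
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03), "bh"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjustPvalues(0.2, "holm"), 0.2)
  expect_error(adjustPvalues(c(0.5, 0)), class = "scmge_bad_pvalues")
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    h <- adjustPvalues(p, "holm"); b <- adjustPvalues(p, "bh")
    expect_equal(h, holmOracle(p), tolerance = 1e-12)
    expect_equal(b, bhOracle(p), tolerance = 1e-12)
    expect_true(all(h >= p - 1e-15 & h <= 1))
    expect_true(all(b >= p - 1e-15 & b <= 1))
    expect_true(all(h >= b - 1e-15))  # FWER control dominates FDR
  }
})

test_that("runDE composes the stages and backfills untested genes", {
  m <- matrix(0L, nrow = 3, ncol = 8,
              dimnames = list(c("gA", "gB", "gC"), sprintf("c%d", 1:8)))
  m["gA", ] <- c(50L, 60L, 55L, 58L, 12L, 10L, 11L, 13L)
  m["gB", ] <- c(2L, 1L, 0L, 2L, 1L, 0L, 2L, 1L)  # never reaches 10
  m["gC", ] <- c(20L, 22L, 21L, 19L, 20L, 22L, 21L, 19L)
  sc <- makeCounts(m)
  nr <- nrpkm(sc)
  A <- sprintf("c%d", 1:4); B <- sprintf("c%d", 5:8)
  de <- runDE(sc, nr, A, B)
  expect_false(de["gB", ]$tested)
  expect_equal(de["gB", ]$p_value, 1)
  expect_equal(de["gB", ]$lfc, 0)
  expect_true(all(de$tested == (de$gene_id %in% c("gA", "gC"))))
  # adjustment ran over tested genes only
  expect_equal(unname(de$p_adjusted[de$tested]),
               holmOracle(unname(de$p_value[de$tested])))
  expect_gt(de["gA", ]$lfc, 0)
  # determinism
  expect_identical(as.data.frame(de), as.data.frame(runDE(sc, nr, A, B)))
})

test_that("top-gene extraction follows the documented ordering", {
  df <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    tested = c(TRUE, TRUE, TRUE, FALSE),
    p_value = c(0.01, 0.01, 0.2, 1),
    p_adjusted = c(0.03, 0.03, 0.4, 1),
    lfc = c(1, -5, 2, 0), n_A = 3L, n_B = 3L)
  de <- scmge:::DEResult(df)
  top <- topDEGenes(de, 2)
  expect_equal(top$gene_id, c("g2", "g1"))  # tie on p_adj: larger |lfc| first
  expect_equal(top$direction, c("down", "up"))
  expect_equal(nrow(topDEGenes(de, 0)), 0L)
  expect_warning(all3 <- topDEGenes(de, 10), "tested")
  expect_equal(nrow(all3), 3L)
})

test_that("planted effects are recovered and the null is calibrated", {
  s2 <- simulateCounts(twoPopulationConfig(n_genes = 300, n_per_group = 40,
                                           n_de = 20, effect = 2, seed = 13))
  tc <- s2$truth$cells
  A <- tc$cell_id[tc$population == "A"]
  B <- tc$cell_id[tc$population == "B"]
  de <- runDE(s2$counts, nrpkm(s2$counts), A, B)
  hit <- de[s2$truth$de_map$gene_id, ]
  expect_gte(mean(hit$p_adjusted < 0.05 & hit$lfc > 0), 0.9)

  s0 <- simulateCounts(singlePopulationConfig(n_genes = 1000, n_cells = 60,
                                              seed = 14))
  ids <- cellData(s0$counts)$cell_id
  de0 <- runDE(s0$counts, nrpkm(s0$counts), ids[1:30], ids[31:60])
  fp <- mean(de0$p_value[de0$tested] < 0.05)
  expect_gte(fp, 0.03); expect_lte(fp, 0.07)
})
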