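test_that("the marker rule applies inclusive boundaries exactly as stated", {
  # 4 T cells, 4 U cells
  m <- matrix(0, nrow = 3, ncol = 8,
              dimnames = list(c("gHit", "gEdge", "gLeak"),
                              c(sprintf("t%d", 1:4), sprintf("u%d", 1:4))))
  m["gHit", 1:3] <- 1.0    # >= 1 in exactly 75% of T, zero in U -> marker
  m["gEdge", 1:4] <- 5     # expressed in all T...
  m["gEdge", 5] <- 0.2     # ...but detected in exactly 25% of U -> disqualified
  m["gLeak", 1:2] <- 5     # only 50% of T -> fails prevalence
  e <- makeExpr(m, transform = "norm_mRNA_mol")
  labels <- setNames(rep(c("T", "U"), each = 4), colnames(m))
  ms <- deriveMarkers(e, labels, markerRule())
  expect_equal(markerList(ms)$T, "gHit")
  expect_equal(markerList(ms)$U, character(0))
})

test_that("a single labelled type makes the exclusion clause vacuous", {
  m <- matrix(2, nrow = 2, ncol = 3,
              dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  e <- makeExpr(m, transform = "norm_mRNA_mol")
  expect_warning(ms <- deriveMarkers(e, setNames(rep("only", 3), colnames(m))),
                 "vacuous")
  expect_setequal(markerList(ms)$only, c("gA", "gB"))
})

test_that("pooled-scope exclusion differs from per-type scope when leakage concentrates", {
  # gene detected in 40% of U cells but 0% of V cells: per-type scope
  # disqualifies (U >= 25%), pooled scope keeps (pooled 20% < 25%)
  m <- matrix(0, nrow = 1, ncol = 14,
              dimnames = list("g1", c(sprintf("t%d", 1:4), sprintf("u%d", 1:5),
                                      sprintf("v%d", 1:5))))
  m["g1", 1:4] <- 2
  m["g1", 5:6] <- 0.5
  e <- makeExpr(m, transform = "norm_mRNA_mol")
  labels <- setNames(rep(c("T", "U", "V"), c(4, 5, 5)), colnames(m))
  each <- deriveMarkers(e, labels, markerRule(scope = "each_other_type"))
  pooled <- deriveMarkers(e, labels, markerRule(scope = "pooled_other_types"))
  expect_equal(markerList(each)$T, character(0))
  expect_equal(markerList(pooled)$T, "g1")
})

test_that("planted reference markers are recovered exactly", {
  cfg <- defaultSimConfig(seed = 7)
  ref <- simulateReference(cfg, cells_per_class = 20)
  ms <- deriveMarkers(normMrnaMol(ref$counts), ref$labels, markerRule(),
                      provenance = "reference")
  planted <- lapply(cfg$rare_types, function(r)
    geneData(ref$counts)$gene_id[r$marker_genes])
  names(planted) <- sapply(cfg$rare_types, `[[`, "name")
  for (ty in names(planted))
    expect_setequal(markerList(ms)[[ty]], planted[[ty]])
})

test_that("the >=4-marker classifier assigns, withholds and flags conflicts", {
  genes <- c(sprintf("mg%d", 1:5), sprintf("as%d", 1:5))
  m <- matrix(0, nrow = 10, ncol = 4,
              dimnames = list(genes, c("cMg", "cLow", "cDual", "cNone")))
  m[1:4, "cMg"] <- 3          # 4 of 5 microglia markers
  m[1:3, "cLow"] <- 3         # only 3 -> unassigned
  m[c(1:4, 6:9), "cDual"] <- 3  # 4 + 4 -> conflict
  e <- makeExpr(m, transform = "nRPKM")
  ms <- new("MarkerSet",
            markers = list(microglia = genes[1:5], astrocyte = genes[6:10]),
            rule = list(), provenance = "test")
  call <- classifyCells(e, ms, min_markers = 4)
  got <- callTable(call)
  expect_equal(got$assigned[got$cell_id == "cMg"], "microglia")
  expect_equal(got$assigned[got$cell_id == "cLow"], "unassigned")
  expect_equal(got$assigned[got$cell_id == "cDual"], "excluded_conflict")
  expect_equal(got$assigned[got$cell_id == "cNone"], "unassigned")
  expect_equal(hitCounts(call)["cMg", "microglia"], 4L)

  # marker order within lists does not matter; classification is idempotent
  ms2 <- new("MarkerSet",
             markers = list(microglia = rev(genes[1:5]),
                            astrocyte = rev(genes[6:10])),
             rule = list(), provenance = "test")
  expect_identical(callTable(classifyCells(e, ms2, 4)), got)
})

test_that("explicit exclusion rules fire after counting", {
  genes <- c(sprintf("ol%d", 1:4), sprintf("in%d", 1:4), sprintf("py%d", 1:4))
  m <- matrix(0, nrow = 12, ncol = 2,
              dimnames = list(genes, c("cOligoInt", "cPyr")))
  m[1:8, "cOligoInt"] <- 2    # oligodendrocyte + interneuron dual signature
  m[9:12, "cPyr"] <- 2        # pyramidal in a region that has none
  e <- makeExpr(m, transform = "nRPKM")
  ms <- new("MarkerSet",
            markers = list(oligodendrocyte = genes[1:4],
                           interneuron = genes[5:8],
                           pyramidal = genes[9:12]),
            rule = list(), provenance = "test")
  excl <- data.frame(type_a = c("oligodendrocyte", "pyramidal"),
                     type_b = c("interneuron", "*"),
                     action = c("exclude", "implausible"))
  got <- callTable(classifyCells(e, ms, 4, exclusions = excl))
  expect_equal(got$assigned[got$cell_id == "cOligoInt"], "excluded_conflict")
  expect_equal(got$assigned[got$cell_id == "cPyr"], "excluded_implausible")
  expect_error(classifyCells(e, new("MarkerSet", markers = list(),
                                    rule = list(), provenance = "")),
               class = "scmge_empty_group")
})

test_that("signature classification scores mean z and respects the margin", {
  m <- matrix(0, nrow = 4, ncol = 3,
              dimnames = list(c("u1", "u2", "d1", "d2"), c("cA", "cB", "cZ")))
  m[c("u1", "u2"), "cA"] <- 1; m[c("d1", "d2"), "cA"] <- -1
  m[c("u1", "u2"), "cB"] <- -1; m[c("d1", "d2"), "cB"] <- 1
  e <- makeExpr(m, transform = "zscore")
  got <- signatureClassify(e, c("u1", "u2"), c("d1", "d2"))
  expect_equal(unname(got[c("cA", "cB", "cZ")]),
               c("classA", "classB", "ambiguous"))
  got2 <- signatureClassify(e, c("u1", "u2"), c("d1", "d2"), margin = 5)
  expect_true(all(got2 == "ambiguous"))
  expect_warning(signatureClassify(e, c("u1", "nope"), c("d1", "d2")),
                 "absent")
  expect_error(suppressWarnings(signatureClassify(e, "nope", c("d1", "d2"))),
               class = "scmge_empty_group")
})

test_that("signature transfer labels held-out simulated cells correctly", {
  sim <- simulateCounts(defaultSimConfig(seed = 21))
  truth <- sim$truth$cells
  kept <- suppressWarnings(filterCells(computeQCMetrics(sim$counts)))
  nr <- nrpkm(sim$counts)
  e11 <- intersect(truth$cell_id[truth$condition == "E11.5" &
                                 is.na(truth$rare_type) & !truth$low_quality],
                   kept)
  lab11 <- truth$population[match(e11, truth$cell_id)]
  de <- runDE(sim$counts, nr, e11[lab11 == "neuron"],
              e11[lab11 == "progenitor"])
  top <- topDEGenes(de, 100)
  later <- truth$cell_id[truth$condition != "E11.5" &
                         is.na(truth$rare_type) & !truth$low_quality]
  z <- suppressWarnings(heatmapValues(nr[, later]))
  got <- signatureClassify(z, top$gene_id[top$direction == "up"],
                           top$gene_id[top$direction == "down"],
                           class_labels = c("neuron", "progenitor"))
  expect_gte(mean(got[later] == truth$population[match(later, truth$cell_id)]),
             0.95)
})

test_that("proportion trends use the exact hypergeometric tail and are monotone", {
  same <- proportionTrend(data.frame(condition = c("b", "c"),
                                     successes = c(10, 10),
                                     total = c(20, 20)), "b")
  expect_gte(same$p_value, 0.5)
  extreme <- proportionTrend(data.frame(condition = c("b", "c"),
                                        successes = c(0, 20),
                                        total = c(20, 20)), "b")
  expect_equal(extreme$p_value, 1 / choose(40, 20), tolerance = 1e-12)
  pv <- sapply(0:20, function(k)
    proportionTrend(data.frame(condition = c("b", "c"),
                               successes = c(5, k), total = c(20, 20)),
                    "b")$p_value)
  expect_true(all(diff(pv) <= 1e-12))
  zres <- proportionTrend(data.frame(condition = c("b", "c"),
                                     successes = c(5, 15), total = c(20, 20)),
                          "b", test = "two_proportion_z")
  expect_lt(zres$p_value, 0.01)
  expect_error(proportionTrend(data.frame(condition = c("b", "c"),
                                          successes = c(0, 0),
                                          total = c(0, 20)), "b"),
               class = "scmge_degenerate")
})
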