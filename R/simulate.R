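#' @include AllClasses.R
NULL

# total-read QC boundary the generator plants cells around (reads/cell)
.READS_BOUNDARY <- 2e6

.checkEffects <- function(de, n_genes, where) {
  if (is.null(de) || !nrow(de)) return(invisible())
  if (!all(c("gene", "log2_effect") %in% names(de)))
    stopc("scmge_bad_config", "%s: de_genes needs columns gene, log2_effect", where)
  if (any(de$gene < 1 | de$gene > n_genes))
    stopc("scmge_bad_config", "%s: de_genes index out of range 1..%d", where, n_genes)
  invisible()
}

#' Build a simulation configuration
#'
#' Defines the ground-truth structure of a simulated single-cell count
#' dataset: per-condition cell numbers, cell populations with planted
#' differentially expressed genes and nested sub-populations, rare
#' non-neuronal cell types carrying exclusive markers, the
#' negative-binomial noise model, cell-wise library-size variation, a
#' mitochondrial gene fraction, and per-cell total mapped reads spanning
#' the 2M-reads QC boundary (cells drawn below it are planted as
#' low-quality and additionally get their mitochondrial expression
#' scaled up, so QC gates have true positives).
#'
#' @param n_genes number of genes.
#' @param n_cells_per_condition named integer vector, cells per condition.
#' @param populations list of populations; each a list with `name`,
#'   `proportion_per_condition` (named over conditions, summing to 1
#'   across populations), `de_genes` (`data.frame(gene, log2_effect)`
#'   applied multiplicatively within the population) and optional
#'   `subpopulations` (same shape with scalar `proportion`).
#' @param rare_types list of rare cell types; each a list with `name`,
#'   `n_cells`, `marker_genes` (>= 4 gene indices, expressed exclusively
#'   by this type) and `marker_mean` (NB mean for those markers).
#' @param n_dual_signature number of planted cells co-expressing the
#'   markers of the first two rare types (classifier-conflict truth).
#' @param nb_dispersion shared NB dispersion alpha (> 0); variance is
#'   `mu + alpha * mu^2`.
#' @param library_size_lognormal `c(mu, sigma)` of the log-normal
#'   cell-wise library-size factor.
#' @param base_mean_lognormal `c(mu, sigma)` of the log-normal per-gene
#'   base mean.
#' @param mito_gene_fraction fraction of genes flagged mitochondrial.
#' @param mito_expression_scale multiplicative factor applied to
#'   mitochondrial gene means in planted low-quality cells.
#' @param total_reads_range `c(min, max)` of per-cell total mapped reads
#'   (uniform); should straddle 2e6 so the read gate is exercised.
#' @param low_quality_fraction fraction of population cells planted as
#'   low-quality (total reads drawn below 2e6, mitochondrial scale-up).
#' @param seed integer seed; all generators are reproducible given it.
#' @return A `SimConfig` list (classed).
#' @seealso [defaultSimConfig()], [simulateCounts()]
#' @export
simConfig <- function(n_genes,
                      n_cells_per_condition,
                      populations,
                      rare_types = list(),
                      n_dual_signature = 0L,
                      nb_dispersion = 0.3,
                      library_size_lognormal = c(mu = 0, sigma = 0.25),
                      base_mean_lognormal = c(mu = log(4), sigma = 1),
                      mito_gene_fraction = 0.02,
                      mito_expression_scale = 10,
                      total_reads_range = c(1.2e6, 4e6),
                      low_quality_fraction = 0.1,
                      seed = 1L) {
  if (nb_dispersion <= 0)
    stopc("scmge_bad_config", "nb_dispersion must be > 0")
  if (is.null(names(n_cells_per_condition)))
    stopc("scmge_bad_config", "n_cells_per_condition must be named by condition")
  conds <- names(n_cells_per_condition)
  if (length(populations)) {
    prop <- vapply(populations,
                   function(p) as.numeric(p$proportion_per_condition[conds]),
                   numeric(length(conds)))
    prop <- matrix(prop, nrow = length(conds))
    if (any(abs(rowSums(prop) - 1) > 1e-8))
      stopc("scmge_bad_config",
            "population proportions must sum to 1 within every condition")
  }
  for (p in populations) {
    .checkEffects(p$de_genes, n_genes, p$name)
    for (sp in p$subpopulations) .checkEffects(sp$de_genes, n_genes, sp$name)
    if (length(p$subpopulations)) {
      sprop <- sum(sapply(p$subpopulations, `[[`, "proportion"))
      if (abs(sprop - 1) > 1e-8)
        stopc("scmge_bad_config",
              "subpopulation proportions of '%s' must sum to 1", p$name)
    }
  }
  for (r in rare_types) {
    if (length(r$marker_genes) < 4L)
      stopc("scmge_bad_config", "rare type '%s' needs >= 4 markers", r$name)
    if (any(r$marker_genes < 1 | r$marker_genes > n_genes))
      stopc("scmge_bad_config", "rare type '%s': marker index out of range", r$name)
  }
  if (mito_gene_fraction < 0 || mito_gene_fraction > 1)
    stopc("scmge_bad_config", "mito_gene_fraction must lie in [0, 1]")
  structure(list(
    n_genes = as.integer(n_genes),
    n_cells_per_condition = n_cells_per_condition,
    populations = populations,
    rare_types = rare_types,
    n_dual_signature = as.integer(n_dual_signature),
    nb_dispersion = nb_dispersion,
    library_size_lognormal = library_size_lognormal,
    base_mean_lognormal = base_mean_lognormal,
    mito_gene_fraction = mito_gene_fraction,
    mito_expression_scale = mito_expression_scale,
    total_reads_range = total_reads_range,
    low_quality_fraction = low_quality_fraction,
    seed = as.integer(seed)), class = "SimConfig")
}

#' Default MGE-like simulation configuration
#'
#' The package's reference study conditions: four embryonic ages with
#' 96/48/63/18 cells, a proliferating-progenitor and an immature-neuron
#' population whose mixing shifts toward neurons with age (progenitor
#' share 0.4/0.5/0.25/0.1), four progenitor and three neuron
#' sub-populations, and three rare non-neuronal types (microglia,
#' astrocyte, vascular smooth muscle) each carrying six exclusive
#' markers, plus one planted dual-signature cell.
#'
#' @param seed integer seed.
#' @param n_genes number of genes.
#' @param conditions named integer vector of cells per condition.
#' @param progenitor_proportion optional named numeric; progenitor share
#'   per condition (defaults to the age-graded shares above, or 0.5 for
#'   unrecognized condition names).
#' @return A `SimConfig`.
#' @export
defaultSimConfig <- function(seed = 1L, n_genes = 2000L,
                             conditions = c(E11.5 = 96L, E13.5 = 48L,
                                            E15.5 = 63L, E17.5 = 18L),
                             progenitor_proportion = NULL) {
  conds <- names(conditions)
  if (is.null(progenitor_proportion)) {
    known <- c(E11.5 = 0.4, E13.5 = 0.5, E15.5 = 0.25, E17.5 = 0.1)
    progenitor_proportion <- ifelse(conds %in% names(known),
                                    known[conds], 0.5)
    names(progenitor_proportion) <- conds
  }
  eff <- function(idx, lfc) data.frame(gene = idx, log2_effect = lfc)
  # disjoint planted gene blocks
  progUp <- 1:60; neurUp <- 61:120
  progSub <- split(121:220, rep(1:4, each = 25))
  neurSub <- split(221:295, rep(1:3, each = 25))
  markers <- split(301:318, rep(1:3, each = 6))
  subnamesP <- c("VZ_ribosomal", "VZ_replication", "SVZ_Gad2", "SVZ_Arx")
  subnamesN <- c("MGE_neuron", "LGE_neuron", "mixed_neuron")
  simConfig(
    n_genes = n_genes,
    n_cells_per_condition = conditions,
    populations = list(
      list(name = "progenitor",
           proportion_per_condition = progenitor_proportion,
           de_genes = eff(progUp, 2.5),
           subpopulations = lapply(1:4, function(i)
             list(name = subnamesP[i], proportion = 0.25,
                  de_genes = eff(progSub[[i]], 2.5)))),
      list(name = "neuron",
           proportion_per_condition = 1 - progenitor_proportion,
           de_genes = eff(neurUp, 2.5),
           subpopulations = lapply(1:3, function(i)
             list(name = subnamesN[i], proportion = 1 / 3,
                  de_genes = eff(neurSub[[i]], 2.5))))),
    rare_types = list(
      list(name = "microglia", n_cells = 4L, marker_genes = markers[[1]],
           marker_mean = 50),
      list(name = "astrocyte", n_cells = 4L, marker_genes = markers[[2]],
           marker_mean = 50),
      list(name = "vsmc", n_cells = 3L, marker_genes = markers[[3]],
           marker_mean = 50)),
    n_dual_signature = 1L,
    seed = seed)
}

#' Single-population null configuration
#'
#' One homogeneous population with no planted effects; used for
#' type-I-error calibration of the differential-expression stage.
#'
#' @param n_genes,n_cells,seed see [simConfig()].
#' @return A `SimConfig`.
#' @export
singlePopulationConfig <- function(n_genes = 1000L, n_cells = 60L, seed = 1L) {
  simConfig(
    n_genes = n_genes,
    n_cells_per_condition = c(cond = as.integer(n_cells)),
    populations = list(
      list(name = "pop", proportion_per_condition = c(cond = 1),
           de_genes = data.frame(gene = integer(0), log2_effect = numeric(0)),
           subpopulations = list())),
    rare_types = list(), n_dual_signature = 0L,
    low_quality_fraction = 0, seed = seed)
}

#' Two-population configuration with planted effects
#'
#' Two equal populations with `n_de` genes up-regulated in population A
#' at `2^effect` fold; used for power/recovery checks of the
#' differential-expression and concordance stages.
#'
#' @param n_genes number of genes.
#' @param n_per_group cells per population.
#' @param n_de number of planted up-regulated genes (indices `1:n_de`).
#' @param effect planted log2 effect.
#' @param seed integer seed.
#' @return A `SimConfig`.
#' @export
twoPopulationConfig <- function(n_genes = 500L, n_per_group = 40L,
                                n_de = 20L, effect = 2, seed = 1L) {
  n <- 2L * as.integer(n_per_group)
  simConfig(
    n_genes = n_genes,
    n_cells_per_condition = c(cond = n),
    populations = list(
      list(name = "A", proportion_per_condition = c(cond = 0.5),
           de_genes = data.frame(gene = seq_len(n_de), log2_effect = effect),
           subpopulations = list()),
      list(name = "B", proportion_per_condition = c(cond = 0.5),
           de_genes = data.frame(gene = integer(0), log2_effect = numeric(0)),
           subpopulations = list())),
    rare_types = list(), n_dual_signature = 0L,
    low_quality_fraction = 0, seed = seed)
}

#' Read a SimConfig from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [simConfig()]; `de_genes` entries are given as two-column lists.
#' @return A `SimConfig`.
#' @export
simConfigFromYaml <- function(path) {
  raw <- readRunConfig(path)
  fixDE <- function(x) {
    if (is.null(x)) return(data.frame(gene = integer(0), log2_effect = numeric(0)))
    data.frame(gene = as.integer(x$gene), log2_effect = as.numeric(x$log2_effect))
  }
  raw$n_cells_per_condition <- unlist(raw$n_cells_per_condition)
  raw$populations <- lapply(raw$populations, function(p) {
    p$proportion_per_condition <- unlist(p$proportion_per_condition)
    p$de_genes <- fixDE(p$de_genes)
    p$subpopulations <- lapply(p$subpopulations, function(sp) {
      sp$de_genes <- fixDE(sp$de_genes); sp
    })
    p
  })
  raw$rare_types <- lapply(raw$rare_types, function(r) {
    r$marker_genes <- as.integer(unlist(r$marker_genes)); r
  })
  for (nm in c("library_size_lognormal", "base_mean_lognormal",
               "total_reads_range"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(simConfig, raw)
}

# deterministic integer split of n into proportions p (largest-remainder)
.splitCounts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

.geneTable <- function(config) {
  n <- config$n_genes
  nMito <- floor(config$mito_gene_fraction * n)
  isMito <- c(rep(FALSE, n - nMito), rep(TRUE, nMito))
  data.frame(
    gene_id = sprintf("G%04d", seq_len(n)),
    symbol = ifelse(isMito, sprintf("mt-Gene%04d", seq_len(n)),
                    sprintf("Gene%04d", seq_len(n))),
    length_bp = sample(500:10000, n, replace = TRUE),
    is_mitochondrial = isMito)
}

#' Simulate a single-cell count matrix with planted truth
#'
#' Draws a genes x cells read-count matrix under the configured
#' negative-binomial model: per-gene log-normal base means, population
#' and sub-population log2 effects applied multiplicatively, cell-wise
#' log-normal library factors, rare cell types expressing their
#' exclusive markers, mitochondrial genes scaled up in planted
#' low-quality cells, and per-cell total mapped reads drawn uniformly
#' over `total_reads_range` (low-quality cells below the 2M boundary,
#' others above).  Fully reproducible given `config$seed`.
#'
#' @param config a `SimConfig` from [simConfig()].
#' @return `list(counts = ScCounts, truth = list(cells, marker_map, de_map))`
#'   where `truth$cells` maps each cell to its condition, population,
#'   sub-population, rare type (or `NA`) and low-quality flag,
#'   `truth$marker_map` lists each rare type's planted marker gene ids
#'   and `truth$de_map` the planted effects per (level, label, gene).
#' @export
simulateCounts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  nG <- config$n_genes
  genes <- .geneTable(config)
  markerIdx <- sort(unique(unlist(lapply(config$rare_types, `[[`, "marker_genes"))))

  baseMean <- stats::rlnorm(nG, config$base_mean_lognormal[["mu"]],
                            config$base_mean_lognormal[["sigma"]])
  # mitochondrial genes: moderate means so the clean-cell mito share sits
  # well below the 5% gate while 10x scaling pushes low-quality cells above
  baseMean[genes$is_mitochondrial] <-
    stats::rlnorm(sum(genes$is_mitochondrial), log(3), 0.8)
  baseMean[markerIdx] <- 0  # exclusive marker genes silent outside their type
  # planted differential genes are drawn from the expressed-gene pool
  deIdx <- unique(c(unlist(lapply(config$populations, function(p)
    p$de_genes$gene)), unlist(lapply(config$populations, function(p)
      unlist(lapply(p$subpopulations, function(sp) sp$de_genes$gene))))))
  if (length(deIdx)) baseMean[deIdx] <- pmax(baseMean[deIdx], 2)

  conds <- names(config$n_cells_per_condition)
  cellRows <- list()
  for (cond in conds) {
    n <- config$n_cells_per_condition[[cond]]
    props <- sapply(config$populations, function(p)
      p$proportion_per_condition[[cond]])
    nPer <- .splitCounts(n, props)
    for (i in seq_along(config$populations)) {
      p <- config$populations[[i]]
      if (nPer[i] == 0L) next
      subs <- p$subpopulations
      subLab <- if (length(subs)) {
        nSub <- .splitCounts(nPer[i], sapply(subs, `[[`, "proportion"))
        rep(sapply(subs, `[[`, "name"), nSub)
      } else rep(NA_character_, nPer[i])
      cellRows[[length(cellRows) + 1L]] <- data.frame(
        condition = cond, population = p$name, subpopulation = subLab,
        rare_type = NA_character_)
    }
  }
  for (r in config$rare_types) {
    if (r$n_cells == 0L) next
    cellRows[[length(cellRows) + 1L]] <- data.frame(
      condition = conds[1L], population = NA_character_,
      subpopulation = NA_character_,
      rare_type = rep(r$name, r$n_cells))
  }
  if (config$n_dual_signature > 0L) {
    if (length(config$rare_types) < 2L)
      stopc("scmge_bad_config", "dual-signature cells need >= 2 rare types")
    cellRows[[length(cellRows) + 1L]] <- data.frame(
      condition = conds[1L], population = NA_character_,
      subpopulation = NA_character_,
      rare_type = rep("dual", config$n_dual_signature))
  }
  truth <- do.call(rbind, cellRows)
  nC <- nrow(truth)
  truth$cell_id <- sprintf("C%04d", seq_len(nC))
  rownames(truth) <- NULL

  # planted low-quality cells (population cells only)
  isPop <- is.na(truth$rare_type)
  truth$low_quality <- FALSE
  truth$low_quality[isPop] <-
    stats::runif(sum(isPop)) < config$low_quality_fraction

  rng <- config$total_reads_range
  lo <- truth$low_quality
  reads <- numeric(nC)
  reads[lo] <- stats::runif(sum(lo), rng[1L], min(.READS_BOUNDARY, rng[2L]))
  reads[!lo] <- stats::runif(sum(!lo), max(.READS_BOUNDARY, rng[1L]), rng[2L])
  reads <- pmin(round(reads), rng[2L])
  reads[lo] <- pmin(reads[lo], .READS_BOUNDARY - 1)

  lib <- stats::rlnorm(nC, config$library_size_lognormal[["mu"]],
                       config$library_size_lognormal[["sigma"]])

  popNames <- sapply(config$populations, `[[`, "name")
  mu <- matrix(rep(baseMean, nC), nrow = nG)
  for (p in config$populations) {
    cls <- which(!is.na(truth$population) & truth$population == p$name)
    if (!length(cls) || !nrow(p$de_genes)) next
    mu[p$de_genes$gene, cls] <- mu[p$de_genes$gene, cls] *
      2^p$de_genes$log2_effect
  }
  for (p in config$populations) for (sp in p$subpopulations) {
    cls <- which(!is.na(truth$subpopulation) & truth$subpopulation == sp$name)
    if (!length(cls) || !nrow(sp$de_genes)) next
    mu[sp$de_genes$gene, cls] <- mu[sp$de_genes$gene, cls] *
      2^sp$de_genes$log2_effect
  }
  for (r in config$rare_types) {
    cls <- which(!is.na(truth$rare_type) & truth$rare_type == r$name)
    if (length(cls)) mu[r$marker_genes, cls] <- r$marker_mean
  }
  if (config$n_dual_signature > 0L) {
    cls <- which(!is.na(truth$rare_type) & truth$rare_type == "dual")
    mu[config$rare_types[[1L]]$marker_genes, cls] <- config$rare_types[[1L]]$marker_mean
    mu[config$rare_types[[2L]]$marker_genes, cls] <- config$rare_types[[2L]]$marker_mean
  }
  mito <- genes$is_mitochondrial
  if (any(lo) && any(mito))
    mu[mito, lo] <- mu[mito, lo] * config$mito_expression_scale
  mu <- sweep(mu, 2L, lib, `*`)

  countsMat <- matrix(stats::rnbinom(nG * nC, mu = as.vector(mu),
                                     size = 1 / config$nb_dispersion),
                      nrow = nG)
  cells <- data.frame(cell_id = truth$cell_id, condition = truth$condition,
                      total_mapped_reads = reads)
  sc <- ScCounts(countsMat, genes, cells, unit = "reads")
  markerMap <- stats::setNames(
    lapply(config$rare_types, function(r) genes$gene_id[r$marker_genes]),
    sapply(config$rare_types, `[[`, "name"))
  deMap <- do.call(rbind, c(
    lapply(config$populations, function(p)
      if (nrow(p$de_genes)) data.frame(level = "population", label = p$name,
        gene_id = genes$gene_id[p$de_genes$gene],
        log2_effect = p$de_genes$log2_effect) else NULL),
    lapply(config$populations, function(p)
      do.call(rbind, lapply(p$subpopulations, function(sp)
        if (nrow(sp$de_genes)) data.frame(level = "subpopulation",
          label = sp$name, gene_id = genes$gene_id[sp$de_genes$gene],
          log2_effect = sp$de_genes$log2_effect) else NULL)))))
  list(counts = sc,
       truth = list(cells = truth[, c("cell_id", "condition", "population",
                                      "subpopulation", "rare_type",
                                      "low_quality")],
                    marker_map = markerMap, de_map = deMap,
                    base_mean = stats::setNames(baseMean, genes$gene_id)))
}

#' Simulate a labelled reference dataset (molecule counts)
#'
#' Emulates an external labelled single-cell reference used for marker
#' transfer: each rare type in `config` becomes a level-1 class whose
#' cells express the planted exclusive markers at `marker_mean` on top
#' of a shared background; counts are molecule-unit.  Under the default
#' configuration every class expresses its markers at normalized level
#' >= 1 in >= 75% of its cells, so [deriveMarkers()] recovers exactly
#' the planted sets.
#'
#' @param config a `SimConfig` whose `rare_types` define the classes.
#' @param cells_per_class cells per class; scalar or one value per class.
#'   Classes given 0 cells are omitted from the output.
#' @param base_mean_range uniform range of background gene means; the
#'   lower end is kept high enough that background genes are detected in
#'   well over 25% of every class and so never satisfy the marker rule.
#' @return `list(counts = ScCounts (unit molecules), labels = named
#'   character vector of class per cell)`.
#' @export
simulateReference <- function(config, cells_per_class = 20L,
                              base_mean_range = c(10, 50)) {
  stopifnot(inherits(config, "SimConfig"))
  if (!length(config$rare_types))
    stopc("scmge_bad_config", "reference simulation needs rare_types classes")
  set.seed(config$seed + 1L)
  nG <- config$n_genes
  genes <- .geneTable(config)
  classes <- sapply(config$rare_types, `[[`, "name")
  nPer <- rep(as.integer(cells_per_class), length.out = length(classes))
  keep <- nPer > 0L
  markerIdx <- sort(unique(unlist(lapply(config$rare_types, `[[`, "marker_genes"))))
  base <- stats::runif(nG, base_mean_range[1L], base_mean_range[2L])
  base[markerIdx] <- 0

  lab <- rep(classes[keep], nPer[keep])
  nC <- length(lab)
  lib <- stats::rlnorm(nC, 0, 0.15)
  mu <- matrix(rep(base, nC), nrow = nG)
  for (r in config$rare_types) {
    cls <- which(lab == r$name)
    if (length(cls)) mu[r$marker_genes, cls] <- r$marker_mean
  }
  mu <- sweep(mu, 2L, lib, `*`)
  countsMat <- matrix(stats::rnbinom(nG * nC, mu = as.vector(mu),
                                     size = 1 / config$nb_dispersion),
                      nrow = nG)
  cells <- data.frame(cell_id = sprintf("R%04d", seq_len(nC)),
                      condition = "reference",
                      total_mapped_reads = colSums(countsMat))
  sc <- ScCounts(countsMat, genes, cells, unit = "molecules")
  list(counts = sc, labels = stats::setNames(lab, cells$cell_id))
}

#' Simulate a single-cell qPCR Ct matrix
#'
#' Generates a genes x cells Ct matrix with two planted cell
#' populations, emulating a marker panel assembled from genes specific
#' to each population: even-indexed non-reference genes are "on" (Ct
#' drawn uniformly in 16-26 cycles) in population 2 and sit at the
#' detection limit `off_ct` in population 1, odd-indexed genes the
#' reverse.  Dropout is expression-dependent, as in real
#' single-cell qPCR: the probability an entry is missing is logistic in
#' its Ct (centered at the detection limit), rescaled so the overall
#' missing fraction equals `missing_rate`.  Ct values are clamped to
#' `[10, 35]` and the reference gene Actb is on in every cell and never
#' missing.
#'
#' @param n_genes number of genes (Actb included as the first gene when
#'   `gene_names` is `NULL`).
#' @param n_cells number of cells (split into two alternating
#'   populations).
#' @param missing_rate overall fraction of missing entries, in `[0, 1)`.
#' @param seed integer seed.
#' @param gene_names optional gene names; must contain `"Actb"`.
#' @param off_ct detection-limit Ct of off-state genes (default 33).
#' @return `list(ct = CtMatrix, truth = named integer population labels)`.
#' @export
simulateQpcr <- function(n_genes, n_cells, missing_rate = 0.1, seed = 1L,
                         gene_names = NULL, off_ct = 33) {
  if (missing_rate < 0 || missing_rate >= 1)
    stopc("scmge_bad_config", "missing_rate must lie in [0, 1)")
  if (is.null(gene_names))
    gene_names <- c("Actb", sprintf("Gene%02d", seq_len(n_genes - 1L)))
  if (!"Actb" %in% gene_names)
    stopc("scmge_missing_reference", "gene list must include Actb")
  if (length(gene_names) != n_genes)
    stopc("scmge_bad_config", "gene_names length must equal n_genes")
  set.seed(seed)
  pop <- rep(1:2, length.out = n_cells)
  onCt <- stats::runif(n_genes, 16, 26)
  onCt[gene_names == "Actb"] <- 18
  markerOf2 <- gene_names != "Actb" & seq_len(n_genes) %% 2L == 0L
  markerOf1 <- gene_names != "Actb" & seq_len(n_genes) %% 2L == 1L
  cellOff <- stats::rnorm(n_cells, 0, 0.5)
  ct <- outer(onCt, cellOff, `+`) + stats::rnorm(n_genes * n_cells, 0, 0.8)
  ct[markerOf2, pop == 1L] <- off_ct +
    stats::rnorm(sum(markerOf2) * sum(pop == 1L), 0, 0.8)
  ct[markerOf1, pop == 2L] <- off_ct +
    stats::rnorm(sum(markerOf1) * sum(pop == 2L), 0, 0.8)
  ct <- pmin(pmax(ct, 10), 35)
  rownames(ct) <- gene_names
  colnames(ct) <- sprintf("Q%04d", seq_len(n_cells))
  if (missing_rate > 0) {
    # dropout rises steeply near the detection limit; the scale c is
    # calibrated so the mean missing probability is exactly missing_rate
    isRef <- gene_names == "Actb"
    s <- stats::plogis(ct - off_ct)
    s[isRef, ] <- 0
    nEligible <- sum(!isRef) * n_cells
    target <- missing_rate * length(s) / nEligible
    f <- function(cc) mean(pmin(1, cc * s[!isRef, ])) - target
    cc <- stats::uniroot(f, lower = 0, upper = 1e12, tol = 1e-12)$root
    pMiss <- pmin(1, cc * s)
    miss <- matrix(stats::runif(n_genes * n_cells) < pMiss, n_genes)
    ct[miss] <- NA_real_
  }
  list(ct = CtMatrix(ct, reference_gene = "Actb", missing_fill = 40),
       truth = stats::setNames(pop, colnames(ct)))
}
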