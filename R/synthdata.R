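#' Simulate a two/three-group expression experiment with planted DEGs
#'
#' Draws per-gene baseline log2 intensities from Normal(8, 1.5^2) — a
#' plausible range for normalized bead-array data — adds i.i.d. Normal
#' residual noise, and shifts a recorded fraction of genes by a signed log2
#' effect in every non-control group. With three groups the third group's
#' effect is attenuated by `washout`, emulating a partial return toward
#' control after exposure ends.
#'
#' @param nGenes number of genes (>= 10).
#' @param nPerGroup samples per group (>= 2); the default matches an
#'   8-animals-per-group liver microarray design.
#' @param fracDe fraction of genes carrying a planted effect, in [0, 1).
#' @param effectRange interval of |log2 fold change| for planted effects;
#'   lower bound must be positive. Signs are assigned at random (more up
#'   than down, 2:1, as commonly seen in exposure signatures).
#' @param noiseSd residual SD on the log2 scale.
#' @param groupLabels group labels; the first is the control group.
#' @param washout multiplier applied to planted effects in the third group,
#'   if any.
#' @param baselineMean,baselineSd distribution of per-gene baseline means.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `matrix` (a
#'   [SummarizedExperiment::SummarizedExperiment], assay `exprs` on the
#'   log2 scale, `colData$group`) and `truth` (a [SyntheticTruth-class]).
#' @examples
#' sim <- simulateExpression(nGenes = 50, nPerGroup = 4, fracDe = 0.1,
#'                           seed = 1)
#' sim$truth
#' @export
simulateExpression <- function(nGenes = 10000, nPerGroup = 8, fracDe = 0.05,
                               effectRange = c(1, 3), noiseSd = 0.25,
                               groupLabels = c("FA", "DE"), washout = 0.5,
                               baselineMean = 8, baselineSd = 1.5,
                               seed = 1) {
  if (nGenes < 10) .paramError("nGenes", "must be >= 10")
  if (nPerGroup < 2) .paramError("nPerGroup", "must be >= 2")
  if (fracDe < 0 || fracDe >= 1) .paramError("fracDe", "must be in [0, 1)")
  if (effectRange[1] <= 0 || diff(effectRange) < 0)
    .paramError("effectRange", "lower bound must be > 0")
  if (length(groupLabels) < 2 || length(groupLabels) > 3)
    .paramError("groupLabels", "needs 2 or 3 group labels")
  set.seed(as.integer(seed))

  genes <- sprintf("gene%05d", seq_len(nGenes))
  nGroups <- length(groupLabels)
  groups <- rep(groupLabels, each = nPerGroup)
  samples <- paste0(rep(groupLabels, each = nPerGroup), "_",
                    rep(seq_len(nPerGroup), nGroups))

  baseline <- stats::rnorm(nGenes, baselineMean, baselineSd)
  nDe <- round(fracDe * nGenes)
  deIdx <- sort(sample.int(nGenes, nDe))
  effects <- numeric(nGenes)
  if (nDe > 0) {
    mag <- stats::runif(nDe, effectRange[1], effectRange[2])
    sign <- ifelse(stats::runif(nDe) < 2 / 3, 1, -1)
    effects[deIdx] <- mag * sign
  }

  shift <- c(0, 1, washout)[seq_len(nGroups)]
  mu <- outer(baseline, rep(0, nGroups * nPerGroup)) +
    outer(effects, rep(shift, each = nPerGroup))
  vals <- mu + matrix(stats::rnorm(nGenes * length(samples), 0, noiseSd),
                      nGenes)
  dimnames(vals) <- list(genes, samples)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = vals),
    colData = S4Vectors::DataFrame(group = groups, row.names = samples))
  truth <- new("SyntheticTruth",
    plantedDegs = data.frame(gene = genes[deIdx], log2fc = effects[deIdx],
                             stringsAsFactors = FALSE),
    params = list(generator = "simulateExpression", nGenes = nGenes,
                  nPerGroup = nPerGroup, fracDe = fracDe,
                  effectRange = effectRange, noiseSd = noiseSd,
                  groupLabels = groupLabels, washout = washout,
                  baselineMean = baselineMean, baselineSd = baselineSd,
                  seed = as.integer(seed)))
  list(matrix = se, truth = truth)
}

# fold-change palette observed at the study's scale: spans ~0.35x (strong
# depletion) up to ~104x (glycogen breakdown products), with intermediate
# effects near 18x, 9.6x, 4.5x, 3.6x, 3.3x, 2.5x, 1.7x.
.defaultMetaboliteEffects <- c(104.13, 18.13, 9.6, 4.52, 3.6, 3.26,
                               2.46, 1.72, 0.35)

#' Simulate a metabolite abundance table with planted fold changes
#'
#' Abundances are log-normal: per-metabolite location ~ Normal(10, 1) and
#' residual SD `sigmaLog` on the natural-log scale (coefficient of
#' variation ~40%, typical of untargeted profiling). Planted metabolites
#' are multiplied by their fold effect in the treated group. Values below
#' `detectionFloor` are recorded as missing.
#'
#' @param nMetabolites total number of metabolites; the planted ones are
#'   the first `length(plantedEffects)`.
#' @param nPerGroup samples per group (default 5, a typical small
#'   metabolomics design).
#' @param plantedEffects multiplicative fold changes (> 0); effects equal
#'   to 1 are applied but not recorded as truth. The default palette spans
#'   0.35x to ~104x.
#' @param detectionFloor abundances below this are set missing.
#' @param sigmaLog residual SD on the natural-log scale.
#' @param groupLabels control label first, then treated.
#' @param nPathwayLabels number of distinct super-pathway labels to assign.
#' @param seed integer seed.
#' @return list with `table` (SummarizedExperiment, assay `abundance` on
#'   the original scale with NA for sub-floor values, rowData
#'   `super_pathway`/`sub_pathway`) and `truth`.
#' @examples
#' sim <- simulateMetabolome(nMetabolites = 20, plantedEffects = c(10, 0.5),
#'                           seed = 1)
#' @export
simulateMetabolome <- function(nMetabolites = 500, nPerGroup = 5,
                               plantedEffects = .defaultMetaboliteEffects,
                               detectionFloor = 0, sigmaLog = 0.4,
                               groupLabels = c("FA", "DE"),
                               nPathwayLabels = 8, seed = 1) {
  if (nPerGroup < 2) .paramError("nPerGroup", "must be >= 2")
  if (any(plantedEffects <= 0))
    .paramError("plantedEffects", "fold changes must be > 0")
  if (length(plantedEffects) > nMetabolites)
    .paramError("nMetabolites", "fewer metabolites than planted effects")
  set.seed(as.integer(seed))

  mets <- sprintf("met%04d", seq_len(nMetabolites))
  samples <- paste0(rep(groupLabels, each = nPerGroup), "_",
                    rep(seq_len(nPerGroup), 2))
  groups <- rep(groupLabels, each = nPerGroup)

  loc <- stats::rnorm(nMetabolites, 10, 1)
  logv <- outer(loc, rep(0, 2 * nPerGroup)) +
    matrix(stats::rnorm(nMetabolites * 2 * nPerGroup, 0, sigmaLog),
           nMetabolites)
  folds <- rep(1, nMetabolites)
  folds[seq_along(plantedEffects)] <- plantedEffects
  treated <- groups != groupLabels[1]
  logv[, treated] <- logv[, treated] + log(folds)
  vals <- exp(logv)
  dimnames(vals) <- list(mets, samples)

  below <- !is.na(vals) & vals < detectionFloor
  if (any(below)) {
    vals[below] <- NA_real_
    if (all(is.na(vals)))
      warning("detection floor above all simulated abundances: ",
              "table is entirely missing")
    logMsg(sum(below), " abundances below detection floor set missing")
  }

  superLabels <- paste0("super_pathway_",
                        seq_len(max(1, nPathwayLabels)))
  rowAnn <- S4Vectors::DataFrame(
    super_pathway = sample(superLabels, nMetabolites, replace = TRUE),
    sub_pathway = paste0("sub_", sample(3 * max(1, nPathwayLabels),
                                        nMetabolites, replace = TRUE)),
    row.names = mets)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = vals), rowData = rowAnn,
    colData = S4Vectors::DataFrame(group = groups, row.names = samples))
  planted <- folds != 1
  truth <- new("SyntheticTruth",
    plantedMetabolites = data.frame(metabolite = mets[planted],
                                    fold = folds[planted],
                                    stringsAsFactors = FALSE),
    params = list(generator = "simulateMetabolome",
                  nMetabolites = nMetabolites, nPerGroup = nPerGroup,
                  plantedEffects = plantedEffects,
                  detectionFloor = detectionFloor, sigmaLog = sigmaLog,
                  groupLabels = groupLabels, seed = as.integer(seed)))
  list(table = se, truth = truth)
}

#' Simulate a directed scale-free gene network with planted key drivers
#'
#' Grows an undirected preferential-attachment graph (`edgesPerNode` edges
#' per arriving node), orients each edge uniformly at random, places the
#' planted drivers among the top-decile total-degree nodes, and emits a
#' gene signature that includes each 1-hop driver neighbor with
#' probability `rhoIn` and every other non-driver node with probability
#' `rhoBg`. The density default gives hub neighborhoods large enough for a
#' Fisher test to have power under Bonferroni correction.
#'
#' @param nNodes number of genes.
#' @param nDrivers number of planted key drivers (< nNodes).
#' @param rhoIn,rhoBg signature inclusion probabilities inside driver
#'   neighborhoods vs background; requires `rhoBg < rhoIn`.
#' @param edgesPerNode preferential-attachment edges per node (graph
#'   density).
#' @param seed integer seed.
#' @return list with `network` ([GeneNetwork-class]), `signature`
#'   (character vector of signature genes) and `truth`.
#' @examples
#' sim <- simulateNetwork(nNodes = 100, nDrivers = 2, seed = 1)
#' sim$network
#' @export
simulateNetwork <- function(nNodes = 1000, nDrivers = 10, rhoIn = 0.7,
                            rhoBg = 0.05, edgesPerNode = 6, seed = 1) {
  if (nDrivers >= nNodes) .paramError("nDrivers", "must be < nNodes")
  if (rhoBg < 0 || rhoIn > 1) .paramError("rhoIn", "need 0 <= rhoBg < rhoIn <= 1")
  if (rhoIn <= rhoBg)
    .paramError("rhoIn",
                "must exceed rhoBg, otherwise no enrichment is planted")
  set.seed(as.integer(seed))

  g <- igraph::sample_pa(nNodes, power = 1, m = edgesPerNode,
                         directed = FALSE)
  ids <- sprintf("gene%05d", seq_len(nNodes))
  el <- igraph::as_edgelist(g, names = FALSE)
  flip <- stats::runif(nrow(el)) < 0.5
  el[flip, ] <- el[flip, c(2, 1)]
  net <- geneNetwork(data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
                                stringsAsFactors = FALSE), nodes = ids)

  drivers <- character()
  if (nDrivers > 0) {
    deg <- igraph::degree(g)
    topDecile <- order(deg, decreasing = TRUE)[seq_len(max(nDrivers,
                                                           ceiling(nNodes / 10)))]
    drivers <- ids[sort(sample(topDecile, nDrivers))]
  }

  nbr <- igraph::adjacent_vertices(g, igraph::V(g))
  driverIdx <- match(drivers, ids)
  nbhdIdx <- setdiff(unique(unlist(lapply(nbr[driverIdx], as.integer))),
                     driverIdx)
  bgIdx <- setdiff(seq_len(nNodes), c(nbhdIdx, driverIdx))
  signature <- sort(c(ids[nbhdIdx][stats::runif(length(nbhdIdx)) < rhoIn],
                      ids[bgIdx][stats::runif(length(bgIdx)) < rhoBg]))

  truth <- new("SyntheticTruth", plantedDrivers = drivers,
    params = list(generator = "simulateNetwork", nNodes = nNodes,
                  nDrivers = nDrivers, rhoIn = rhoIn, rhoBg = rhoBg,
                  edgesPerNode = edgesPerNode, seed = as.integer(seed)))
  list(network = net, signature = signature, truth = truth)
}

#' Simulate overlapping pathway annotations over gene and metabolite
#' universes
#'
#' Draws random member sets (disjointness not required). A stated number of
#' pathways is seeded with planted features — half of each seeded pathway's
#' members are drawn from `seededGenes`/`seededMetabolites` when provided —
#' and those pathway names are recorded as enriched by construction.
#'
#' @param genes gene identifier universe.
#' @param metabolites metabolite identifier universe (may be empty).
#' @param nPathways number of pathways.
#' @param sizeRange min/max members per pathway (per universe).
#' @param nSeeded how many pathways to seed with planted features.
#' @param seededGenes,seededMetabolites planted feature ids to concentrate
#'   into the seeded pathways.
#' @param seed integer seed.
#' @return list with `geneSets` and `metaboliteSets` (both
#'   [GeneSetCollection-class]; the latter empty when no metabolites) and
#'   `truth` recording the seeded pathway names.
#' @export
simulatePathways <- function(genes, metabolites = character(),
                             nPathways = 30, sizeRange = c(10, 50),
                             nSeeded = 0, seededGenes = character(),
                             seededMetabolites = character(), seed = 1) {
  if (length(genes) == 0) .paramError("genes", "empty universe")
  if (sizeRange[1] < 1 || sizeRange[2] > length(genes))
    .paramError("sizeRange", "sizes must fit inside the gene universe")
  if (nSeeded > nPathways) .paramError("nSeeded", "more seeded than pathways")
  set.seed(as.integer(seed))

  nm <- sprintf("pathway%03d", seq_len(nPathways))
  seeded <- nm[seq_len(nSeeded)]
  drawSet <- function(universe, planted, isSeeded, size) {
    size <- min(size, length(universe))
    if (isSeeded && length(planted)) {
      nPl <- min(length(planted), ceiling(size / 2))
      pl <- sample(planted, nPl)
      rest <- sample(setdiff(universe, pl), size - nPl)
      sort(c(pl, rest))
    } else sort(sample(universe, size))
  }
  sizes <- sample(seq(sizeRange[1], sizeRange[2]), nPathways,
                  replace = TRUE)
  gsets <- lapply(seq_len(nPathways), function(i)
    drawSet(genes, seededGenes, nm[i] %in% seeded, sizes[i]))
  names(gsets) <- nm

  msets <- list()
  if (length(metabolites)) {
    msizes <- pmin(pmax(round(sizes / 3), 2), length(metabolites))
    msets <- lapply(seq_len(nPathways), function(i)
      drawSet(metabolites, seededMetabolites, nm[i] %in% seeded,
              msizes[i]))
    names(msets) <- nm
  }

  truth <- new("SyntheticTruth", seededPathways = seeded,
    params = list(generator = "simulatePathways", nPathways = nPathways,
                  sizeRange = sizeRange, nSeeded = nSeeded,
                  seed = as.integer(seed)))
  list(geneSets = geneSetCollection(gsets,
                                    rep("simulated pathway", nPathways)),
       metaboliteSets = if (length(msets))
         geneSetCollection(msets, rep("simulated pathway", nPathways))
       else geneSetCollection(list()),
       truth = truth)
}
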