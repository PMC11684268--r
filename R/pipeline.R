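#' Default pipeline configuration
#'
#' Flat per-stage configuration with every tunable default of the
#' package. [runPipeline()] merges a config file and in-call overrides
#' over these defaults; unknown keys are rejected, and the effective
#' configuration is written next to the outputs.
#'
#' @return nested named list of stage parameter defaults.
#' @export
defaultConfig <- function() {
  list(
    seed = 1,
    expression = list(nGenes = 10000, nPerGroup = 8, fracDe = 0.05,
                      effectRange = c(1, 3), noiseSd = 0.25,
                      groupLabels = c("FA", "DE"), washout = 0.5),
    metabolome = list(nMetabolites = 500, nPerGroup = 5,
                      plantedEffects = .defaultMetaboliteEffects,
                      detectionFloor = 0, sigmaLog = 0.4),
    network = list(nNodes = 1000, nDrivers = 10, rhoIn = 0.7,
                   rhoBg = 0.05, edgesPerNode = 6),
    pathways = list(nPathways = 30, sizeRange = c(10, 50), nSeeded = 5),
    deg = list(threshold = 0.05, test = "welch"),
    metab = list(threshold = 0.05, test = "welch"),
    gsea = list(nPermutations = 1000, permutationType = "gene_set",
                weightExponent = 1, minSize = 15, maxSize = 500),
    kda = list(radius = 1, direction = "both", alpha = 0.05,
               minNeighborhood = 5),
    classify = list(nTrees = 500, scheme = "loocv"),
    integrate = list(geneCutoff = 0.05, metaboliteCutoff = 0.05),
    inputs = list(expression = NULL, expressionGroups = NULL,
                  metabolome = NULL, metabolomeGroups = NULL,
                  metabolomeAnnotations = NULL, network = NULL,
                  geneSets = NULL, reactions = NULL)
  )
}

# merge user values over defaults, rejecting unknown keys at any level
.mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    .usageError(paste0("invalid config key: ", path, unknown[1]))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

.pipelineStages <- c("simulate-expression", "simulate-metabolome",
                     "simulate-network", "simulate-pathways", "normalize",
                     "deg", "metab-diff", "gsea", "ora", "kda", "subnet",
                     "classify", "integrate", "all")

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.needInput <- function(cfg, key, fallback) {
  p <- cfg$inputs[[key]] %||% fallback
  if (is.null(p) || !file.exists(p))
    .usageError(paste0("missing input for '", key, "': ",
                       p %||% "(no path configured)"))
  p
}

#' Run pipeline stages
#'
#' Orchestrates the package end to end. `stage = "all"` simulates every
#' input with planted truth, runs normalization, differential analysis on
#' both omics, GSEA and ORA, key driver analysis, random-forest
#' classification and pathway integration, and writes a truth-recovery
#' report plus a per-stage count summary (`run-report.json`). Individual
#' stage names run one step against configured input paths. Every run
#' logs its effective seed; identical seeds give byte-identical output
#' trees. Diagnostics go to standard error only.
#'
#' @param stage one of `simulate-expression`, `simulate-metabolome`,
#'   `simulate-network`, `simulate-pathways`, `normalize`, `deg`,
#'   `metab-diff`, `gsea`, `ora`, `kda`, `subnet`, `classify`,
#'   `integrate`, `all`.
#' @param outDir output directory (created if needed).
#' @param config named list of overrides over [defaultConfig()]; unknown
#'   keys are an error.
#' @param configFile optional YAML or JSON config file, applied below
#'   `config`.
#' @param seed optional global seed overriding the config's.
#' @return invisibly, a named list of the paths written (for `all`, also
#'   `recovery`, the recovery report list).
#' @export
runPipeline <- function(stage = "all", outDir, config = list(),
                        configFile = NULL, seed = NULL) {
  if (!stage %in% .pipelineStages)
    .usageError(paste0("unknown stage '", stage, "'"))
  cfg <- defaultConfig()
  if (!is.null(configFile)) {
    if (!file.exists(configFile))
      .usageError(paste0("missing config file: ", configFile))
    fileCfg <- if (grepl("\\.ya?ml$", configFile))
      yaml::read_yaml(configFile)
    else jsonlite::read_json(configFile, simplifyVector = TRUE)
    cfg <- .mergeConfig(cfg, fileCfg)
  }
  cfg <- .mergeConfig(cfg, config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logMsg("stage '", stage, "' with seed ", cfg$seed)
  jsonlite::write_json(cfg[setdiff(names(cfg), "inputs")],
                       file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pth <- function(f) file.path(outDir, f)
  written <- list(config = pth("config.json"))

  simExpr <- function() {
    e <- cfg$expression
    sim <- simulateExpression(e$nGenes, e$nPerGroup, e$fracDe,
                              e$effectRange, e$noiseSd, e$groupLabels,
                              e$washout,
                              seed = childSeed(cfg$seed, "expression"))
    writeOmicsMatrix(sim$matrix, pth("expression.tsv"),
                     pth("expression_groups.tsv"))
    writeTruth(sim$truth, pth("truth_expression.json"))
    sim
  }
  simMetab <- function() {
    m <- cfg$metabolome
    sim <- simulateMetabolome(m$nMetabolites, m$nPerGroup,
                              m$plantedEffects, m$detectionFloor,
                              m$sigmaLog,
                              seed = childSeed(cfg$seed, "metabolome"))
    writeOmicsMatrix(sim$table, pth("metabolome.tsv"),
                     pth("metabolome_groups.tsv"),
                     pth("metabolome_annotations.tsv"))
    writeTruth(sim$truth, pth("truth_metabolome.json"))
    sim
  }
  simNet <- function() {
    n <- cfg$network
    sim <- simulateNetwork(n$nNodes, n$nDrivers, n$rhoIn, n$rhoBg,
                           n$edgesPerNode,
                           seed = childSeed(cfg$seed, "network"))
    writeNetwork(sim$network, pth("network.sif"))
    writeLines(sim$signature, pth("network_signature.txt"))
    writeTruth(sim$truth, pth("truth_network.json"))
    sim
  }
  loadExpr <- function()
    readOmicsMatrix(.needInput(cfg, "expression", pth("expression.tsv")),
                    .needInput(cfg, "expressionGroups",
                               pth("expression_groups.tsv")),
                    type = "expression")
  loadMetab <- function()
    readOmicsMatrix(.needInput(cfg, "metabolome", pth("metabolome.tsv")),
                    .needInput(cfg, "metabolomeGroups",
                               pth("metabolome_groups.tsv")),
                    type = "metabolite",
                    annotationsPath = cfg$inputs$metabolomeAnnotations %||%
                      pth("metabolome_annotations.tsv"))

  labsOf <- function(se) {
    g <- unique(sampleGroups(se))
    list(control = g[1], treated = g[2])
  }

  if (stage == "simulate-expression") { simExpr()
  } else if (stage == "simulate-metabolome") { simMetab()
  } else if (stage == "simulate-network") { simNet()
  } else if (stage == "simulate-pathways") {
    exprSe <- loadExpr()
    p <- cfg$pathways
    sim <- simulatePathways(rownames(exprSe), nPathways = p$nPathways,
                            sizeRange = p$sizeRange, nSeeded = 0,
                            seed = childSeed(cfg$seed, "pathways"))
    writeGmt(sim$geneSets, pth("gene_sets.gmt"))
  } else if (stage == "normalize") {
    se <- rankInvariantNormalize(loadExpr())
    writeOmicsMatrix(se, pth("expression_normalized.tsv"),
                     pth("expression_groups.tsv"))
  } else if (stage == "deg") {
    se <- loadExpr(); lab <- labsOf(se)
    res <- differentialTable(se, lab$control, lab$treated,
                             test = cfg$deg$test)
    .writeTsv(res, pth("deg_results.tsv"))
  } else if (stage == "metab-diff") {
    se <- loadMetab(); lab <- labsOf(se)
    res <- differentialTable(se, lab$control, lab$treated,
                             test = cfg$metab$test,
                             valueScale = "natural")
    .writeTsv(res, pth("metab_results.tsv"))
  } else if (stage == "gsea") {
    se <- loadExpr(); lab <- labsOf(se)
    gmt <- readGmt(.needInput(cfg, "geneSets", pth("gene_sets.gmt")))
    g <- cfg$gsea
    res <- gsea(se, lab$control, lab$treated, gmt, g$nPermutations,
                g$permutationType, g$weightExponent,
                minSize = g$minSize, maxSize = g$maxSize,
                seed = childSeed(cfg$seed, "gsea"))
    .writeTsv(res, pth("gsea_results.tsv"))
  } else if (stage == "ora") {
    se <- loadExpr(); lab <- labsOf(se)
    gmt <- readGmt(.needInput(cfg, "geneSets", pth("gene_sets.gmt")))
    res <- differentialTable(se, lab$control, lab$treated)
    sig <- makeSignature(res, cfg$deg$threshold, "DE")
    tab <- ora(intersect(signatureGenes(sig), res$feature[res$tested]),
               res$feature[res$tested], gmt)
    .writeTsv(tab, pth("ora_results.tsv"))
  } else if (stage %in% c("kda", "subnet")) {
    net <- readNetwork(.needInput(cfg, "network", pth("network.sif")))
    sigPath <- pth("network_signature.txt")
    if (!file.exists(sigPath))
      .usageError(paste0("missing input for 'signature': ", sigPath))
    signature <- readLines(sigPath)
    if (stage == "kda") {
      k <- cfg$kda
      res <- keyDriverAnalysis(net, signature, k$radius, k$direction,
                               k$alpha, k$minNeighborhood)
      .writeTsv(res, pth("kda_results.tsv"))
      kds <- res$gene[res$is_kd]
      if (length(kds)) {
        sub <- extractSubnetwork(net, kds, expand = k$radius)
        writeGraphML(sub, annotations = list(
          in_signature = stats::setNames(
            as.integer(networkNodes(sub) %in% signature),
            networkNodes(sub)),
          is_kd = stats::setNames(
            as.integer(networkNodes(sub) %in% kds),
            networkNodes(sub))), pth("kd_subnetwork.graphml"))
      }
    } else {
      sub <- extractSubnetwork(net, signature, expand = 1)
      writeNetwork(sub, pth("subnetwork.sif"))
      .writeTsv(sub@metadata$componentRanking,
                pth("subnetwork_ranking.tsv"))
    }
  } else if (stage == "classify") {
    se <- loadMetab()
    cl <- cfg$classify
    rep <- rfClassify(se, cl$nTrees, cl$scheme,
                      seed = childSeed(cfg$seed, "classify"))
    .writeTsv(importanceTable(rep), pth("importance.tsv"))
    jsonlite::write_json(list(accuracy = rep@accuracy,
                              scheme = rep@scheme, n_trees = rep@nTrees,
                              confusion = as.data.frame(rep@confusion)),
                         pth("classification_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (stage == "integrate") {
    need <- function(f) {
      p <- pth(f)
      if (!file.exists(p))
        .usageError(paste0("missing input for 'integrate': ", p))
      p
    }
    degRes <- utils::read.delim(need("deg_results.tsv"))
    metabRes <- utils::read.delim(need("metab_results.tsv"))
    joint <- jointPathwayTable(degRes, metabRes,
                               readGmt(need("gene_sets.gmt")),
                               readGmt(need("metabolite_sets.gmt")),
                               cfg$integrate$geneCutoff,
                               cfg$integrate$metaboliteCutoff)
    .writeTsv(joint, pth("joint_pathways.tsv"))
  } else if (stage == "all") {
    written <- c(written, .runAll(cfg, pth))
  }
  invisible(c(written, list(outDir = outDir)))
}

# the full synthetic end-to-end benchmark with truth recovery
.runAll <- function(cfg, pth) {
  exprSim <- local({
    e <- cfg$expression
    simulateExpression(e$nGenes, e$nPerGroup, e$fracDe, e$effectRange,
                       e$noiseSd, e$groupLabels, e$washout,
                       seed = childSeed(cfg$seed, "expression"))
  })
  writeOmicsMatrix(exprSim$matrix, pth("expression.tsv"),
                   pth("expression_groups.tsv"))
  writeTruth(exprSim$truth, pth("truth_expression.json"))

  m <- cfg$metabolome
  metabSim <- simulateMetabolome(m$nMetabolites, m$nPerGroup,
                                 m$plantedEffects, m$detectionFloor,
                                 m$sigmaLog,
                                 seed = childSeed(cfg$seed, "metabolome"))
  writeOmicsMatrix(metabSim$table, pth("metabolome.tsv"),
                   pth("metabolome_groups.tsv"),
                   pth("metabolome_annotations.tsv"))
  writeTruth(metabSim$truth, pth("truth_metabolome.json"))

  n <- cfg$network
  netSim <- simulateNetwork(n$nNodes, n$nDrivers, n$rhoIn, n$rhoBg,
                            n$edgesPerNode,
                            seed = childSeed(cfg$seed, "network"))
  writeNetwork(netSim$network, pth("network.sif"))
  writeLines(netSim$signature, pth("network_signature.txt"))
  writeTruth(netSim$truth, pth("truth_network.json"))

  labs <- cfg$expression$groupLabels
  degRes <- differentialTable(exprSim$matrix, labs[1], labs[2],
                              test = cfg$deg$test)
  .writeTsv(degRes, pth("deg_results.tsv"))
  degSig <- makeSignature(degRes, cfg$deg$threshold, labs[2])

  mlabs <- metabSim$truth@params$groupLabels
  metabRes <- differentialTable(metabSim$table, mlabs[1], mlabs[2],
                                test = cfg$metab$test,
                                valueScale = "natural")
  .writeTsv(metabRes, pth("metab_results.tsv"))
  metabSig <- makeSignature(metabRes, cfg$metab$threshold, mlabs[2])

  p <- cfg$pathways
  pwSim <- simulatePathways(rownames(exprSim$matrix),
                            rownames(metabSim$table),
                            nPathways = p$nPathways,
                            sizeRange = p$sizeRange, nSeeded = p$nSeeded,
                            seededGenes = exprSim$truth@plantedDegs$gene,
                            seededMetabolites =
                              metabSim$truth@plantedMetabolites$metabolite,
                            seed = childSeed(cfg$seed, "pathways"))
  writeGmt(pwSim$geneSets, pth("gene_sets.gmt"))
  writeGmt(pwSim$metaboliteSets, pth("metabolite_sets.gmt"))
  writeTruth(pwSim$truth, pth("truth_pathways.json"))

  g <- cfg$gsea
  gseaRes <- gsea(exprSim$matrix, labs[1], labs[2], pwSim$geneSets,
                  g$nPermutations, g$permutationType, g$weightExponent,
                  minSize = g$minSize, maxSize = g$maxSize,
                  seed = childSeed(cfg$seed, "gsea"))
  .writeTsv(gseaRes, pth("gsea_results.tsv"))

  detected <- degRes$feature[degRes$tested]
  oraRes <- ora(intersect(signatureGenes(degSig), detected), detected,
                pwSim$geneSets)
  .writeTsv(oraRes, pth("ora_results.tsv"))

  k <- cfg$kda
  kdaRes <- keyDriverAnalysis(netSim$network, netSim$signature,
                              k$radius, k$direction, k$alpha,
                              k$minNeighborhood)
  .writeTsv(kdaRes, pth("kda_results.tsv"))
  kds <- kdaRes$gene[kdaRes$is_kd]
  if (length(kds)) {
    sub <- extractSubnetwork(netSim$network, kds, expand = k$radius)
    writeGraphML(sub, annotations = list(
      in_signature = stats::setNames(
        as.integer(networkNodes(sub) %in% netSim$signature),
        networkNodes(sub)),
      is_kd = stats::setNames(as.integer(networkNodes(sub) %in% kds),
                              networkNodes(sub))),
      pth("kd_subnetwork.graphml"))
  }

  cl <- cfg$classify
  rfRep <- rfClassify(metabSim$table, cl$nTrees, cl$scheme,
                      seed = childSeed(cfg$seed, "classify"))
  .writeTsv(importanceTable(rfRep), pth("importance.tsv"))
  jsonlite::write_json(list(accuracy = rfRep@accuracy,
                            scheme = rfRep@scheme,
                            n_trees = rfRep@nTrees,
                            confusion = as.data.frame(rfRep@confusion)),
                       pth("classification_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  joint <- jointPathwayTable(degRes, metabRes, pwSim$geneSets,
                             pwSim$metaboliteSets,
                             cfg$integrate$geneCutoff,
                             cfg$integrate$metaboliteCutoff)
  .writeTsv(joint, pth("joint_pathways.tsv"))

  # truth recovery
  planted <- exprSim$truth@plantedDegs$gene
  called <- signatureGenes(degSig)
  degRecall <- if (length(planted)) mean(planted %in% called) else NA
  degFdr <- if (length(called)) mean(!called %in% planted) else 0
  plantedM <- metabSim$truth@plantedMetabolites$metabolite
  calledM <- signatureGenes(metabSig)
  drivers <- netSim$truth@plantedDrivers
  kdaPrecision <- if (length(kds)) mean(kds %in% drivers) else NA
  kdaRecall <- if (length(drivers)) mean(drivers %in% kds) else NA
  recovery <- list(
    seed = cfg$seed,
    deg = list(planted = length(planted), called = length(called),
               recall = degRecall, observed_fdr = degFdr),
    metabolites = list(planted = length(plantedM),
                       called = length(calledM),
                       recall = if (length(plantedM))
                         mean(plantedM %in% calledM) else NA),
    kda = list(planted = length(drivers), called = length(kds),
               precision = kdaPrecision, recall = kdaRecall),
    classification = list(accuracy = rfRep@accuracy,
                          scheme = rfRep@scheme),
    integration = list(
      seeded_pathways = length(pwSim$truth@seededPathways),
      combined_flagged = sum(joint$combined),
      combined_in_seeded = sum(joint$pathway[joint$combined] %in%
                                 pwSim$truth@seededPathways)))
  jsonlite::write_json(recovery, pth("recovery_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  runReport <- list(
    genes_tested = sum(degRes$tested), degs_called = length(called),
    metabolites_tested = sum(metabRes$tested),
    metabolites_significant = length(calledM),
    gene_sets_tested = nrow(gseaRes),
    gene_sets_significant_fdr05 = sum(gseaRes$q < 0.05, na.rm = TRUE),
    network_nodes = length(networkNodes(netSim$network)),
    network_edges = nrow(networkEdges(netSim$network)),
    kda_candidates = nrow(kdaRes), kds_called = length(kds),
    rf_accuracy = rfRep@accuracy,
    combined_pathways = sum(joint$combined))
  jsonlite::write_json(runReport, pth("run-report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(recovery = recovery, runReport = runReport)
}
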