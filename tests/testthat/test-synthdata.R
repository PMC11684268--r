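test_that("expression generator is deterministic and records exactly the planted genes", {
  a <- simulateExpression(nGenes = 200, nPerGroup = 4, fracDe = 0.1, seed = 11)
  b <- simulateExpression(nGenes = 200, nPerGroup = 4, fracDe = 0.1, seed = 11)
  expect_identical(SummarizedExperiment::assay(a$matrix),
                   SummarizedExperiment::assay(b$matrix))
  expect_identical(a$truth@plantedDegs, b$truth@plantedDegs)
  expect_equal(nrow(a$truth@plantedDegs), 20)
  expect_true(all(a$truth@plantedDegs$gene %in% rownames(a$matrix)))
  expect_true(all(a$truth@plantedDegs$log2fc != 0))

  none <- simulateExpression(nGenes = 50, nPerGroup = 3, fracDe = 0, seed = 2)
  expect_equal(nrow(none$truth@plantedDegs), 0)

  big <- simulateExpression(nGenes = 10000, nPerGroup = 8, fracDe = 0.05,
                            seed = 3)
  expect_equal(nrow(big$truth@plantedDegs), 500)
})

test_that("expression generator rejects invalid parameters by name", {
  expect_error(simulateExpression(nGenes = 5), "nGenes")
  expect_error(simulateExpression(nPerGroup = 1), "nPerGroup")
  expect_error(simulateExpression(fracDe = 1), "fracDe")
  expect_error(simulateExpression(effectRange = c(0, 2)), "effectRange")
})

test_that("planted expression effects are recovered empirically at large n", {
  sim <- simulateExpression(nGenes = 300, nPerGroup = 100, fracDe = 0.1,
                            effectRange = c(1, 2), noiseSd = 0.25, seed = 5)
  vals <- SummarizedExperiment::assay(sim$matrix)
  g <- sampleGroups(sim$matrix)
  diff <- rowMeans(vals[, g == "DE"]) - rowMeans(vals[, g == "FA"])
  truth <- sim$truth@plantedDegs
  se <- 0.25 * sqrt(2 / 100)
  expect_true(all(abs(diff[truth$gene] - truth$log2fc) < 3.5 * se +
                    .Machine$double.eps))
})

test_that("metabolome generator plants multiplicative fold changes at the stated scale", {
  # Monte-Carlo: the treated/control ratio of arithmetic group means
  # should concentrate on the planted 104.13-fold effect
  ratios <- vapply(1:100, function(s) {
    sim <- simulateMetabolome(nMetabolites = 10, nPerGroup = 5,
                              plantedEffects = 104.13, seed = s)
    v <- SummarizedExperiment::assay(sim$table)
    g <- sampleGroups(sim$table)
    mean(v[1, g == "DE"]) / mean(v[1, g == "FA"])
  }, 0)
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 104.13), 3 * se)
})

test_that("metabolome generator handles unit folds, floors and bad input", {
  sim <- simulateMetabolome(nMetabolites = 10, plantedEffects = c(2, 1.0),
                            seed = 1)
  expect_false("met0002" %in% sim$truth@plantedMetabolites$metabolite)
  expect_true("met0001" %in% sim$truth@plantedMetabolites$metabolite)

  expect_warning(
    allNa <- simulateMetabolome(nMetabolites = 10, plantedEffects = 2,
                                detectionFloor = 1e12, seed = 1),
    "entirely missing")
  expect_true(all(is.na(SummarizedExperiment::assay(allNa$table))))

  expect_error(simulateMetabolome(plantedEffects = c(2, -1)),
               "plantedEffects")
  a <- simulateMetabolome(seed = 4); b <- simulateMetabolome(seed = 4)
  expect_identical(SummarizedExperiment::assay(a$table),
                   SummarizedExperiment::assay(b$table))
})

test_that("network generator plants drivers with enriched neighborhoods", {
  sim <- simulateNetwork(nNodes = 1000, nDrivers = 10, rhoIn = 0.7,
                         rhoBg = 0.05, seed = 9)
  net <- sim$network
  expect_s4_class(net, "GeneNetwork")
  expect_true(all(sim$truth@plantedDrivers %in% networkNodes(net)))

  # direct counting on the emitted graph: signature fraction inside
  # driver neighborhoods beats the background fraction
  insideFrac <- outsideFrac <- numeric(0)
  for (s in 1:8) {
    sm <- simulateNetwork(nNodes = 300, nDrivers = 5, rhoIn = 0.7,
                          rhoBg = 0.05, seed = s)
    nbhd <- unique(unlist(lapply(sm$truth@plantedDrivers, function(d)
      neighborhood(sm$network, d, 1, "both"))))
    nbhd <- setdiff(nbhd, sm$truth@plantedDrivers)
    rest <- setdiff(networkNodes(sm$network),
                    c(nbhd, sm$truth@plantedDrivers))
    insideFrac <- c(insideFrac, mean(nbhd %in% sm$signature))
    outsideFrac <- c(outsideFrac, mean(rest %in% sm$signature))
  }
  expect_gt(mean(insideFrac), mean(outsideFrac))
})

test_that("network generator limit cases and parameter checks", {
  lim <- simulateNetwork(nNodes = 200, nDrivers = 3, rhoIn = 1,
                         rhoBg = 0, seed = 2)
  nbhd <- unique(unlist(lapply(lim$truth@plantedDrivers, function(d)
    neighborhood(lim$network, d, 1, "both"))))
  expect_setequal(lim$signature,
                  setdiff(nbhd, lim$truth@plantedDrivers))

  none <- simulateNetwork(nNodes = 100, nDrivers = 0, rhoIn = 0.7,
                          rhoBg = 0.05, seed = 3)
  expect_length(none$truth@plantedDrivers, 0)

  expect_error(simulateNetwork(nDrivers = 1000, nNodes = 100), "nDrivers")
  expect_error(simulateNetwork(rhoIn = 0.05, rhoBg = 0.05), "rhoIn")
})

test_that("pathway generator seeds pathways and is reproducible", {
  genes <- sprintf("g%03d", 1:200)
  mets <- sprintf("m%03d", 1:60)
  pw <- simulatePathways(genes, mets, nPathways = 10, sizeRange = c(5, 20),
                         nSeeded = 3, seededGenes = genes[1:30],
                         seededMetabolites = mets[1:10], seed = 7)
  expect_length(pw$truth@seededPathways, 3)
  for (nm in pw$truth@seededPathways)
    expect_gt(length(intersect(pw$geneSets[[nm]], genes[1:30])), 0)

  f1 <- tempfile(); f2 <- tempfile()
  writeGmt(pw$geneSets, f1)
  pw2 <- simulatePathways(genes, mets, nPathways = 10, sizeRange = c(5, 20),
                          nSeeded = 3, seededGenes = genes[1:30],
                          seededMetabolites = mets[1:10], seed = 7)
  writeGmt(pw2$geneSets, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simulatePathways(character()), "genes")

  # one pathway covering every gene: ORA fold enrichment is forced to 1
  all1 <- geneSetCollection(list(everything = genes))
  res <- ora(genes[1:20], genes, all1)
  expect_equal(res$fold_enrichment, 1)
})

test_that("a third washout group receives the attenuated planted effect", {
  sim <- simulateExpression(nGenes = 400, nPerGroup = 30, fracDe = 0.1,
                            effectRange = c(2, 2), noiseSd = 0.2,
                            groupLabels = c("FA", "DE", "DE+FA"),
                            washout = 0.5, seed = 6)
  vals <- SummarizedExperiment::assay(sim$matrix)
  g <- sampleGroups(sim$matrix)
  expect_equal(ncol(vals), 90)
  planted <- sim$truth@plantedDegs
  de <- rowMeans(vals[planted$gene, g == "DE"]) -
    rowMeans(vals[planted$gene, g == "FA"])
  wash <- rowMeans(vals[planted$gene, g == "DE+FA"]) -
    rowMeans(vals[planted$gene, g == "FA"])
  expect_equal(mean(wash / de), 0.5, tolerance = 0.05)

  # two contrasts against the same control overlap in the Venn table
  r1 <- differentialTable(sim$matrix, "FA", "DE")
  r2 <- differentialTable(sim$matrix, "FA", "DE+FA")
  v <- vennCounts(makeSignature(r1, 0.05, "DE"),
                  makeSignature(r2, 0.05, "DE+FA"))
  expect_gt(sum(v$shared), 0)
})
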