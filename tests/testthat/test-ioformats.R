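test_that("omics matrices round-trip losslessly with group maps", {
  vals <- matrix(c(1.5, 2.25, 3, 4, 5.125, 6, 7, 8, 9, 10, 11, 12), 3,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("s1", "s2", "s3", "s4")))
  se <- makeExprSE(vals, c("FA", "FA", "DE", "DE"))
  mp <- tempfile(); gp <- tempfile()
  writeOmicsMatrix(se, mp, gp)
  back <- readOmicsMatrix(mp, gp, type = "expression")
  expect_equal(SummarizedExperiment::assay(back),
               SummarizedExperiment::assay(se))
  expect_identical(sampleGroups(back), sampleGroups(se))
})

test_that("matrix reader enforces its contracts", {
  mp <- tempfile(); gp <- tempfile()
  writeLines(c("feature\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), mp)
  writeLines(c("sample\tgroup", "s1\tFA", "s2\tDE"), gp)
  expect_error(readOmicsMatrix(mp, gp), "g1")

  writeLines(c("feature\ts1\ts2", "g1\t1\t2", "g2\tabc\t4"), mp)
  expect_error(readOmicsMatrix(mp, gp), "g2")

  # "NA" is a missing value, not zero, and missing group mapping is fatal
  writeLines(c("feature\ts1\ts2", "g1\tNA\t2"), mp)
  out <- readOmicsMatrix(mp, gp)
  expect_true(is.na(SummarizedExperiment::assay(out)["g1", "s1"]))

  writeLines(c("sample\tgroup", "s1\tFA"), gp)
  expect_error(readOmicsMatrix(mp, gp), "s2")
})

test_that("GMT reading preserves order, deduplicates and validates", {
  f <- tempfile()
  writeLines("S1\tdesc\tg1\tg2", f)
  gsc <- readGmt(f)
  expect_identical(gsc[["S1"]], c("g1", "g2"))

  writeLines(c("S1\tdesc\tg1\tg2\tg2"), f)
  expect_warning(gsc <- readGmt(f), "duplicate")
  expect_length(gsc[["S1"]], 2)

  writeLines("S1\tonlydesc", f)
  expect_error(readGmt(f), "line 1")

  writeLines(character(), f)
  expect_warning(empty <- readGmt(f), "empty")
  expect_length(empty, 0)

  pw <- geneSetCollection(list(A = c("x", "y"), B = "z"),
                          c("da", "db"))
  writeGmt(pw, f)
  back <- readGmt(f)
  expect_identical(geneSets(back), geneSets(pw))
})

test_that("network reading handles SIF, TSV, duplicates and self-loops", {
  f <- tempfile()
  writeLines("a\treg\tb", f)
  expect_identical(networkEdges(readNetwork(f)),
                   data.frame(from = "a", to = "b",
                              stringsAsFactors = FALSE))

  writeLines(c("a\treg\tb", "a\treg\tb"), f)
  expect_equal(nrow(networkEdges(readNetwork(f))), 1)

  writeLines("a\treg\ta", f)
  net <- readNetwork(f)
  expect_equal(nrow(networkEdges(net)), 0)
  expect_equal(net@droppedSelfLoops, 1L)
  expect_true("a" %in% networkNodes(net))

  # two-column TSV dialect and SIF multi-target lines
  writeLines(c("a\tb", "b\tc"), f)
  expect_equal(nrow(networkEdges(readNetwork(f))), 2)
  writeLines("a\treg\tb\tc\td", f)
  expect_equal(nrow(networkEdges(readNetwork(f))), 3)

  net2 <- geneNetwork(data.frame(from = c("a", "b"), to = c("b", "c")),
                      nodes = c("a", "b", "c", "iso"))
  writeNetwork(net2, f, format = "sif")
  expect_true("iso" %in% networkNodes(readNetwork(f)))
})

test_that("downstream statistics are invariant to input row order", {
  vals <- matrix(rnorm(40, 8), 10,
                 dimnames = list(sprintf("g%02d", 1:10),
                                 c("s1", "s2", "s3", "s4")))
  se <- makeExprSE(vals, c("FA", "FA", "DE", "DE"))
  perm <- sample(nrow(vals))
  seP <- makeExprSE(vals[perm, ], c("FA", "FA", "DE", "DE"))
  r1 <- differentialTable(se, "FA", "DE")
  r2 <- differentialTable(seP, "FA", "DE")
  r2 <- r2[match(r1$feature, r2$feature), ]
  rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("GraphML export round-trips through independent parsers", {
  net <- geneNetwork(data.frame(from = "a", to = "b"))
  f <- tempfile(fileext = ".graphml")
  writeGraphML(net, annotations = list(is_kd = c(a = TRUE)), path = f)

  g2 <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::vertex_attr(g2, "name"), c("a", "b"))
  expect_equal(sum(igraph::vertex_attr(g2, "is_kd")), 1)

  # second, XML-level parser: node and key structure
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns(doc)
  nodes <- xml2::xml_find_all(doc, ".//d1:node", ns)
  expect_length(nodes, 2)
  edges <- xml2::xml_find_all(doc, ".//d1:edge", ns)
  expect_length(edges, 1)

  expect_error(writeGraphML(net, annotations = list(x = c(zz = 1)),
                            path = f), "zz")

  empty <- geneNetwork(data.frame(from = character(), to = character()))
  writeGraphML(empty, path = f)
  expect_no_error(xml2::read_xml(f))
})

test_that("truth JSON round-trips", {
  tr <- methods::new("SyntheticTruth",
    plantedDegs = data.frame(gene = c("g1", "g2"), log2fc = c(1.5, -2),
                             stringsAsFactors = FALSE),
    plantedMetabolites = data.frame(metabolite = "m1", fold = 104.13,
                                    stringsAsFactors = FALSE),
    plantedDrivers = "g9", seededPathways = "p1",
    params = list(seed = 3L))
  f <- tempfile(fileext = ".json")
  writeTruth(tr, f)
  back <- readTruth(f)
  expect_equal(back@plantedDegs, tr@plantedDegs)
  expect_equal(back@plantedMetabolites, tr@plantedMetabolites)
  expect_identical(back@plantedDrivers, tr@plantedDrivers)
})
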