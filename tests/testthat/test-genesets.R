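test_that("fold enrichment follows the (k/K)/(n/N) definition exactly", {
  # k=5 of K=10 pathway members significant, n=50 of N=1000 overall
  detected <- sprintf("f%04d", 1:1000)
  pathway <- geneSetCollection(list(P = c(detected[1:5], detected[101:105])))
  significant <- detected[1:50]
  res <- ora(significant, detected, pathway)
  expect_identical(res$k, 5L); expect_identical(res$K, 10L)
  expect_identical(res$n, 50L); expect_identical(res$N, 1000L)
  expect_identical(res$fold_enrichment, 10)

  # k/K == n/N forces enrichment exactly 1, at several scales
  for (mult in c(1L, 3L, 7L)) {
    N <- 100L * mult; K <- 10L * mult; n <- 20L * mult; k <- 2L * mult
    det <- sprintf("x%04d", seq_len(N))
    pw <- geneSetCollection(list(P = det[seq_len(K)]))
    sig <- c(det[seq_len(k)], det[(K + 1):(K + n - k)])
    expect_identical(ora(sig, det, pw)$fold_enrichment, 1)
  }

  expect_error(ora(c("a", "zz"), c("a", "b"),
                   geneSetCollection(list(P = "a"))), "zz")
})

test_that("ORA p-values equal exhaustive hypergeometric enumeration", {
  set.seed(5)
  for (i in 1:50) {
    N <- sample(10:25, 1)
    K <- sample(1:N, 1)
    n <- sample(0:N, 1)
    det <- sprintf("f%02d", seq_len(N))
    pw <- geneSetCollection(list(P = det[seq_len(K)]))
    sig <- sample(det, n)
    res <- ora(sig, det, pw)
    k <- length(intersect(sig, det[seq_len(K)]))
    expect_lt(abs(res$p - hyperTailEnum(k, K - k, n - k, N - K - n + k)),
              1e-12)
  }
})

test_that("feature ranking is deterministic, descending and tie-stable", {
  res <- data.frame(feature = c("b", "a", "c"),
                    log2fc = c(1, -1, 1), t = c(2, -2, 2),
                    p = c(0.01, 0.01, 0.5))
  r <- rankFeatures(res, "t")
  expect_identical(r$feature, c("b", "c", "a"))

  ties <- data.frame(feature = c("z", "m", "a"), log2fc = 1,
                     t = 1, p = 0.5)
  expect_identical(rankFeatures(ties, "t")$feature, c("a", "m", "z"))

  perm <- res[c(3, 1, 2), ]
  expect_identical(rankFeatures(perm, "t"), rankFeatures(res, "t"))
  expect_error(rankFeatures(rbind(res, res), "t"), "duplicate")
})

test_that("enrichment score matches the hand-evaluated running sum", {
  r <- data.frame(feature = paste0("g", 1:5), score = c(5, 4, 3, 2, 1))
  out <- gseaES(r, c("g1", "g3"), weightExponent = 0)
  expect_equal(out$runningSum,
               c(0.5, 0.5 - 1 / 3, 0.5 - 1 / 3 + 0.5, 2 / 3 - 1 / 3, 0),
               tolerance = 1e-12)
  expect_equal(out$ES, 2 / 3, tolerance = 1e-12)

  bottom <- gseaES(r, c("g4", "g5"), weightExponent = 0)
  expect_lt(bottom$ES, 0)

  top <- gseaES(r, c("g1", "g2"), weightExponent = 0)
  expect_equal(top$ES, 1, tolerance = 1e-12)

  expect_error(gseaES(r, c("zz")), "disjoint")
  expect_error(gseaES(r, paste0("g", 1:5)), "entire")
})

test_that("enrichment score equals the brute-force oracle on random instances", {
  set.seed(8)
  for (i in 1:60) {
    N <- sample(5:50, 1)
    feat <- sprintf("f%02d", seq_len(N))
    score <- sort(rnorm(N), decreasing = TRUE)
    s <- sample(seq_len(min(10, N - 1)), 1)
    set <- sample(feat, s)
    expo <- sample(c(0, 1, 2), 1)
    r <- data.frame(feature = feat, score = score)
    expect_equal(gseaES(r, set, expo)$ES, bruteES(feat, score, set, expo),
                 tolerance = 1e-12)
    # the fast hit-position path used in permutations agrees too
    expect_equal(OmicKDA:::.esAtPositions(abs(score)^expo,
                                          sort(match(intersect(set, feat),
                                                     feat)), N),
                 bruteES(feat, score, set, expo), tolerance = 1e-12)
  }
})

test_that("enrichment score is antisymmetric under ranking reversal at exponent 0", {
  set.seed(21)
  for (i in 1:20) {
    N <- 30
    feat <- sprintf("f%02d", 1:N)
    score <- sort(rnorm(N), decreasing = TRUE)
    set <- sample(feat, 6)
    run <- gseaES(data.frame(feature = feat, score = score), set, 0)
    # at an exact |max| = |min| tie the sign is a convention, not a
    # property; antisymmetry holds whenever the extremum is unique
    if (abs(max(run$runningSum) + min(run$runningSum)) < 1e-12) next
    rev <- gseaES(data.frame(feature = rev(feat), score = rev(-score)),
                  set, 0)$ES
    expect_equal(rev, -run$ES, tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  set.seed(13)
  for (i in 1:20) {
    N <- 40
    stats <- sort(rnorm(N), decreasing = TRUE)
    names(stats) <- sprintf("f%02d", 1:N)
    idx <- sort(sample(N, 7))
    mine <- gseaES(data.frame(feature = names(stats),
                              score = unname(stats)),
                   names(stats)[idx], weightExponent = 1)$ES
    ref <- fgsea::calcGseaStat(stats, idx, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("gsea recovers a planted set, is deterministic and calibrated", {
  sim <- simulateExpression(nGenes = 600, nPerGroup = 8, fracDe = 0.05,
                            effectRange = c(1.5, 2.5), seed = 31)
  planted <- sim$truth@plantedDegs$gene[sim$truth@plantedDegs$log2fc > 0]
  sets <- geneSetCollection(list(
    hot = planted[1:20],
    cold = setdiff(rownames(sim$matrix), planted)[1:30]))
  res <- gsea(sim$matrix, "FA", "DE", sets, nPermutations = 200,
              minSize = 5, seed = 4)
  expect_lt(res$p[res$set == "hot"], 0.05)
  expect_gt(abs(res$NES[res$set == "hot"]), 1)
  le <- strsplit(res$leading_edge[res$set == "hot"], ",")[[1]]
  expect_true(all(le %in% planted[1:20]))

  res2 <- gsea(sim$matrix, "FA", "DE", sets, nPermutations = 200,
               minSize = 5, seed = 4)
  expect_identical(res, res2)

  expect_warning(
    gsea(makeExprSE(SummarizedExperiment::assay(sim$matrix)[, c(1, 2, 9, 10)],
                    c("FA", "FA", "DE", "DE")),
         "FA", "DE", sets, nPermutations = 100, minSize = 5,
         permutationType = "phenotype", seed = 1),
    "falling back")
})

test_that("gsea nominal p is uniform under the null", {
  set.seed(17)
  ps <- vapply(1:40, function(s) {
    sim <- simulateExpression(nGenes = 150, nPerGroup = 5, fracDe = 0,
                              seed = 1000 + s)
    sets <- geneSetCollection(list(S = rownames(sim$matrix)[
      sample(150, 20)]))
    gsea(sim$matrix, "FA", "DE", sets, nPermutations = 200,
         minSize = 5, seed = s)$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
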