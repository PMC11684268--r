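test_that("rank-invariant normalization maps proportional samples onto the reference", {
  set.seed(1)
  base <- 2^rnorm(200, 8, 1)
  vals <- log2(cbind(ref = base, same = base, double = 2 * base))
  rownames(vals) <- sprintf("g%03d", 1:200)
  se <- makeExprSE(vals, c("FA", "FA", "DE"))

  norm <- rankInvariantNormalize(se, reference = "ref")
  out <- 2^SummarizedExperiment::assay(norm)
  expect_equal(out[, "ref"], base, ignore_attr = TRUE)
  expect_equal(out[, "same"], base, ignore_attr = TRUE)
  expect_equal(out[, "double"], base, ignore_attr = TRUE)
})

test_that("rank-invariant normalization errors when no probes are invariant", {
  vals <- log2(cbind(a = as.numeric(1:50), b = as.numeric(50:1)))
  rownames(vals) <- sprintf("g%02d", 1:50)
  se <- makeExprSE(vals, c("FA", "DE"))
  expect_error(rankInvariantNormalize(se, reference = "a"),
               "rank-invariant")
})

test_that("welch test matches the closed form, t.test and its symmetry", {
  r <- welchTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(r$df, 4, tolerance = 1e-10)
  expect_equal(r$p.value, 2 * pt(-sqrt(3 / 2), 4), tolerance = 1e-10)

  same <- welchTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  set.seed(42)
  for (i in 1:50) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), sd = 2)
    mine <- welchTest(x, y)
    ref <- t.test(x, y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
    flip <- welchTest(y, x)
    expect_equal(flip$statistic, -mine$statistic, tolerance = 1e-12)
    expect_equal(flip$p.value, mine$p.value, tolerance = 1e-12)
  }

  expect_true(is.na(welchTest(1, c(1, 2))$p.value))
  degen <- welchTest(c(1, 1, 1), c(2, 2, 2))
  expect_equal(degen$p.value, 0)
})

test_that("BH adjustment matches the step-up oracle and its contracts", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "index 2")
  expect_identical(bhAdjust(c(0.01, NA, 0.5)),
                   c(stats::p.adjust(c(0.01, 0.5), "BH")[1], NA,
                     stats::p.adjust(c(0.01, 0.5), "BH")[2]))

  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    mine <- bhAdjust(p)
    expect_lt(max(abs(mine - stepUpBH(p))), 1e-12)
    o <- sample(length(p))
    expect_equal(bhAdjust(p[o]), mine[o], tolerance = 1e-15)
    expect_true(all(diff(mine[order(p)]) > -1e-15))
  }
})

test_that("Storey q-values estimate pi0 near 1 under the null", {
  set.seed(12)
  p <- runif(10000)
  q <- qValues(p, method = "storey")
  pi0 <- attr(q, "pi0")
  expect_gt(pi0, 0.9)
  expect_lt(pi0, 1.1)
  expect_true(all(q <= 1))

  expect_identical(qValues(p, method = "bh"), bhAdjust(p))
  expect_equal(unname(qValues(rep(1, 200), method = "storey")),
               rep(1, 200), ignore_attr = TRUE)
  expect_warning(qValues(runif(20), method = "storey"), "fewer than 100")
})

test_that("differential table recovers planted fold changes", {
  fcs <- vapply(1:20, function(s) {
    sim <- simulateExpression(nGenes = 300, nPerGroup = 8, fracDe = 0.1,
                              effectRange = c(1, 1), noiseSd = 0.25,
                              seed = s)
    res <- differentialTable(sim$matrix, "FA", "DE")
    mean(res$fold_change[match(sim$truth@plantedDegs$gene, res$feature)] /
           2^sign(sim$truth@plantedDegs$log2fc))
  }, 0)
  se <- sd(fcs) / sqrt(length(fcs))
  expect_lt(abs(mean(fcs) - 1), 3 * se + 0.01)
})

test_that("differential table flags untestable features and excludes them from m", {
  vals <- matrix(c(10, 11, 12, 20, 21, 22,
                   NA, NA, NA, 5, 6, 7,
                   1, 2, 3, NA, 4, 5), 3, byrow = TRUE,
                 dimnames = list(c("ok", "gone", "partial"),
                                 c("c1", "c2", "c3", "t1", "t2", "t3")))
  se <- makeMetabSE(vals, rep(c("FA", "DE"), each = 3))
  res <- differentialTable(se, "FA", "DE", valueScale = "natural")
  expect_false(res$tested[res$feature == "gone"])
  expect_true(is.na(res$p[res$feature == "gone"]))
  expect_true(all(res$tested[res$feature != "gone"]))
  # family m excludes the untested feature
  tested <- !is.na(res$p)
  expect_equal(res$adj_p[tested], bhAdjust(res$p[tested]),
               ignore_attr = TRUE)
  expect_error(differentialTable(se, "FA", "nope"), "nope")
})

test_that("signatures obey direction, threshold monotonicity and ties", {
  res <- data.frame(feature = c("a", "b", "c", "d"),
                    fold_change = c(2, 0.5, 1, 3),
                    adj_p = c(0.01, 0.04, 0.01, 0.5))
  sig <- makeSignature(res, 0.05, "t")
  expect_identical(upGenes(sig), "a")
  expect_identical(downGenes(sig), "b")   # c: fold exactly 1, excluded

  none <- makeSignature(transform(res, adj_p = 0.9), 0.05)
  expect_length(signatureGenes(none), 0)

  loose <- makeSignature(res, 0.5)
  expect_true(all(signatureGenes(sig) %in% signatureGenes(loose)))
})

test_that("venn counts equal brute-force set arithmetic", {
  set.seed(3)
  for (i in 1:20) {
    a <- degSignature("a", sample(letters, 8), sample(LETTERS, 5))
    b <- degSignature("b", sample(letters, 6), sample(LETTERS, 7))
    v <- vennCounts(a, b)
    expect_equal(v$shared[1], length(intersect(upGenes(a), upGenes(b))))
    expect_equal(v$a_only[1], length(setdiff(upGenes(a), upGenes(b))))
    expect_equal(v$b_only[2], length(setdiff(downGenes(b), downGenes(a))))
  }
  same <- degSignature("x", c("u1", "u2"), "d1")
  v <- vennCounts(same, same)
  expect_equal(v$a_only, c(0, 0))
  expect_equal(v$b_only, c(0, 0))
})
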