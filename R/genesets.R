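#' Over-representation analysis with hypergeometric fold enrichment
#'
#' For each pathway, counts k significant members among K detected members
#' and reports the fold enrichment (k/K)/(n/N) — the pathway's significant
#' fraction relative to the global significant fraction — together with
#' the one-sided (enrichment) hypergeometric tail p = P(X >= k) and
#' BH-adjusted p across pathways. Pathways are intersected with the
#' detected universe first; pathways with no detected members are dropped.
#'
#' @param significant character vector of significant feature ids; must be
#'   a subset of `detected`.
#' @param detected character vector, the detected feature universe.
#' @param pathways a [GeneSetCollection-class] (gene or metabolite sets).
#' @param depletion also test the depletion tail P(X <= k) (off by
#'   default; the enrichment tail is the primary question).
#' @return data.frame with columns set, k, K, n, N, fold_enrichment, p,
#'   adj_p (and depletion_p when requested), one row per pathway with at
#'   least one detected member.
#' @examples
#' pw <- geneSetCollection(list(P = paste0("g", 1:10)))
#' ora(paste0("g", 1:5), paste0("g", 1:1000), pw)
#' @export
ora <- function(significant, detected, pathways, depletion = FALSE) {
  significant <- unique(significant)
  detected <- unique(detected)
  offenders <- setdiff(significant, detected)
  if (length(offenders))
    stop("significant features not in the detected universe: ",
         paste(utils::head(offenders, 5), collapse = ", "),
         if (length(offenders) > 5) ", ...")
  N <- length(detected)
  n <- length(significant)
  rows <- lapply(names(pathways), function(nm) {
    members <- intersect(pathways[[nm]], detected)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, significant))
    fe <- if (n == 0) NA_real_ else (k / K) / (n / N)
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               fold_enrichment = fe,
               p = fisherOneSided(k, K - k, n - k, N - K - n + k),
               depletion_p = stats::phyper(k, n, N - n, K),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(),
                      fold_enrichment = numeric(), p = numeric(),
                      adj_p = numeric(), stringsAsFactors = FALSE))
  out$adj_p <- bhAdjust(out$p)
  if (!depletion) out$depletion_p <- NULL
  rownames(out) <- NULL
  out[order(out$p, out$set), ]
}

#' Rank features for GSEA
#'
#' Produces the descending ranked list GSEA consumes. Metrics:
#' `signed_log_p` (sign of the log2 fold change times -log10 p, capped at
#' 300), `log2fc`, or the t statistic. Ties are broken by feature id
#' (ascending), so the ranking is deterministic and input-order
#' invariant.
#'
#' @param results data.frame from [differentialTable()]; untested
#'   features are dropped.
#' @param metric ranking metric.
#' @return data.frame (feature, score) in descending score order.
#' @export
rankFeatures <- function(results,
                         metric = c("signed_log_p", "log2fc", "t")) {
  metric <- match.arg(metric)
  if (anyDuplicated(results$feature))
    stop("duplicate feature ids in results")
  res <- results[!is.na(results$p), , drop = FALSE]
  score <- switch(metric,
    signed_log_p = sign(res$log2fc) * pmin(-log10(pmax(res$p, 1e-300)), 300),
    log2fc = res$log2fc,
    t = res$t)
  if (any(!is.finite(score)))
    stop("non-finite ranking scores; choose a different metric")
  o <- order(-score, res$feature)
  data.frame(feature = res$feature[o], score = score[o],
             row.names = NULL, stringsAsFactors = FALSE)
}

# weighted-KS enrichment score evaluated only at hit positions.
# w: |score|^exponent for every rank; pos: sorted hit ranks.
# Exact: between hits the running sum decreases linearly, so the maximum
# is attained at a hit and the minimum just before a hit (or at the ends).
.esAtPositions <- function(w, pos, N) {
  s <- length(pos)
  wh <- w[pos]
  W <- sum(wh)
  if (W == 0) { wh <- rep(1, s); W <- s }
  miss <- 1 / (N - s)
  cw <- cumsum(wh) / W
  atHit <- cw - (pos - seq_len(s)) * miss
  beforeHit <- c(0, cw[-s]) - (pos - seq_len(s)) * miss
  hi <- max(atHit)
  lo <- min(beforeHit, 0)
  if (hi >= -lo - 1e-12) hi else lo
}

#' GSEA enrichment score (weighted Kolmogorov-Smirnov running sum)
#'
#' Walks the ranked list; at each set member the running sum increases by
#' that member's |score|^exponent (normalized so the hit increments sum to
#' 1), at each non-member it decreases by 1/(N - |S|). The enrichment
#' score is the extremum of largest magnitude, sign preserved. Exponent 0
#' gives the classic unweighted KS statistic.
#'
#' @param ranked data.frame (feature, score) from [rankFeatures()], or a
#'   named numeric vector in descending order.
#' @param geneSet character vector of member ids; must hit the ranked
#'   universe but not cover it.
#' @param weightExponent nonnegative weight exponent (default 1, classic
#'   weighted GSEA).
#' @return list with `ES` and the full `runningSum` vector (length N).
#' @examples
#' r <- data.frame(feature = paste0("g", 1:5), score = 5:1)
#' gseaES(r, c("g1", "g3"), weightExponent = 0)$ES
#' @export
gseaES <- function(ranked, geneSet, weightExponent = 1) {
  if (is.numeric(ranked))
    ranked <- data.frame(feature = names(ranked), score = unname(ranked))
  if (weightExponent < 0) .paramError("weightExponent", "must be >= 0")
  N <- nrow(ranked)
  hit <- ranked$feature %in% geneSet
  s <- sum(hit)
  if (s == 0L) stop("gene set is disjoint from the ranked universe")
  if (s == N) stop("gene set covers the entire ranked universe")
  w <- abs(ranked$score)^weightExponent
  wh <- w * hit
  W <- sum(wh)
  if (W == 0) { wh <- as.numeric(hit); W <- s }
  inc <- wh / W
  inc[!hit] <- -1 / (N - s)
  running <- cumsum(inc)
  hi <- max(running)
  lo <- min(running)
  # exact |max| = |min| ties resolve toward the positive extremum
  ES <- if (hi >= -lo - 1e-12) hi else lo
  list(ES = ES, runningSum = running)
}

#' Gene set enrichment analysis with permutation NES and FDR
#'
#' Computes each set's weighted-KS enrichment score on the ranked
#' differential statistics, then normalizes by permutation:
#' NES = ES / mean(|permuted ES of the same sign|), nominal p from the
#' same-sign permutation tail with add-one continuity, and a
#' sign-stratified pooled-permutation FDR q (the permuted NES of all sets
#' form the null pool for each sign). Permutations are either of set
#' membership (`gene_set`, the default: random sets of the same size) or
#' of phenotype labels (`phenotype`, which re-runs the differential
#' ranking per permutation; with fewer than 3 samples per group it falls
#' back to gene-set permutation with a warning).
#'
#' @param se expression SummarizedExperiment with `colData$group`.
#' @param control,treated group labels to contrast.
#' @param pathways a [GeneSetCollection-class].
#' @param nPermutations number of permutations (>= 100).
#' @param permutationType "gene_set" or "phenotype".
#' @param weightExponent hit-weight exponent, see [gseaES()].
#' @param metric ranking metric, see [rankFeatures()].
#' @param minSize,maxSize set-size filters after intersection with the
#'   ranked universe.
#' @param seed integer seed; results are deterministic given the seed.
#' @return data.frame with set, size, ES, NES, p, q, adj_p (BH of nominal
#'   p, reported alongside the permutation FDR), leading_edge (comma
#'   list).
#' @export
gsea <- function(se, control, treated, pathways, nPermutations = 1000,
                 permutationType = c("gene_set", "phenotype"),
                 weightExponent = 1, metric = "signed_log_p",
                 minSize = 15, maxSize = 500, seed = 1) {
  permutationType <- match.arg(permutationType)
  if (nPermutations < 100) .paramError("nPermutations", "must be >= 100")
  groups <- sampleGroups(se)
  if (permutationType == "phenotype" &&
      min(sum(groups == control), sum(groups == treated)) < 3) {
    warning("fewer than 3 samples/group: falling back to gene_set ",
            "permutation")
    permutationType <- "gene_set"
  }
  res <- differentialTable(se, control, treated, qMethod = "bh")
  ranked <- rankFeatures(res, metric)
  N <- nrow(ranked)
  w <- abs(ranked$score)^weightExponent

  sets <- lapply(geneSets(pathways),
                 function(s) intersect(s, ranked$feature))
  sizes <- lengths(sets)
  keep <- sizes >= minSize & sizes <= maxSize & sizes < N
  sets <- sets[keep]
  if (!length(sets))
    stop("no gene set within the size filters after intersection")
  sizes <- lengths(sets)

  esObs <- vapply(names(sets), function(nm)
    .esAtPositions(w, sort(match(sets[[nm]], ranked$feature)), N), 0)

  set.seed(as.integer(seed))
  nSet <- length(sets)
  permES <- matrix(NA_real_, nSet, nPermutations)
  if (permutationType == "gene_set") {
    # permutations are shared across sets of equal size
    for (sz in unique(sizes)) {
      which_sets <- which(sizes == sz)
      es <- vapply(seq_len(nPermutations), function(i)
        .esAtPositions(w, sort(sample.int(N, sz)), N), 0)
      for (j in which_sets) permES[j, ] <- es
    }
  } else {
    vals <- SummarizedExperiment::assay(se, 1)
    labs <- groups
    posSets <- lapply(sets, function(s) s)
    for (i in seq_len(nPermutations)) {
      pl <- sample(labs)
      xc <- vals[, pl == control, drop = FALSE]
      xt <- vals[, pl == treated, drop = FALSE]
      r <- .rowTTest(xt, xc)
      score <- switch(metric,
        signed_log_p = sign(r$mx - r$my) *
          pmin(-log10(pmax(r$p, 1e-300)), 300),
        log2fc = r$mx - r$my,
        t = r$t)
      o <- order(-score, rownames(vals))
      feat <- rownames(vals)[o]
      wp <- abs(score[o])^weightExponent
      permES[, i] <- vapply(posSets, function(s)
        .esAtPositions(wp, sort(match(s, feat)), N), 0)
    }
  }

  normalize <- function(es, pool) {
    same <- pool[sign(pool) == sign(es) & pool != 0]
    if (!length(same)) return(NA_real_)
    es / mean(abs(same))
  }
  NES <- vapply(seq_len(nSet), function(j)
    normalize(esObs[j], permES[j, ]), 0)
  pNom <- vapply(seq_len(nSet), function(j) {
    same <- permES[j, sign(permES[j, ]) == sign(esObs[j])]
    (1 + sum(abs(same) >= abs(esObs[j]))) / (1 + length(same))
  }, 0)

  # sign-stratified pooled FDR on the NES scale
  permNES <- permES
  for (j in seq_len(nSet)) {
    pos <- permES[j, ] > 0; neg <- permES[j, ] < 0
    mp <- mean(permES[j, pos]); mn <- mean(abs(permES[j, neg]))
    permNES[j, pos] <- permES[j, pos] / mp
    permNES[j, neg] <- permES[j, neg] / mn
  }
  poolPos <- permNES[permNES > 0]; poolNeg <- permNES[permNES < 0]
  q <- vapply(seq_len(nSet), function(j) {
    nes <- NES[j]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      nullFrac <- if (length(poolPos)) mean(poolPos >= nes) else 0
      obsFrac <- mean(NES[NES >= 0] >= nes)
    } else {
      nullFrac <- if (length(poolNeg)) mean(poolNeg <= nes) else 0
      obsFrac <- mean(NES[NES < 0] <= nes)
    }
    min(1, nullFrac / obsFrac)
  }, 0)

  leading <- vapply(seq_len(nSet), function(j) {
    gs <- gseaES(ranked, sets[[j]], weightExponent)
    peak <- if (gs$ES >= 0) which.max(gs$runningSum)
            else which.min(gs$runningSum)
    hits <- ranked$feature[ranked$feature %in% sets[[j]]]
    le <- if (gs$ES >= 0) {
      intersect(ranked$feature[seq_len(peak)], sets[[j]])
    } else {
      intersect(ranked$feature[peak:N], sets[[j]])
    }
    paste(le, collapse = ",")
  }, "")

  out <- data.frame(set = names(sets), size = sizes, ES = esObs,
                    NES = NES, p = pNom, q = q, adj_p = bhAdjust(pNom),
                    leading_edge = leading, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$p, out$set), ]
}
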