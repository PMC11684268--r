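#' Rank-invariant normalization
#'
#' Scales each sample to a reference using the rank-invariant probe set:
#' probes whose rank in the sample differs from their rank in the
#' reference by at most `tol * n` probes. Selection is iterated (default
#' twice), re-ranking within the surviving set. The per-sample scaling
#' factor is the median reference/sample ratio over the invariant set, so
#' a sample identical (or exactly proportional) to the reference maps onto
#' it exactly and the reference sample itself is unchanged.
#'
#' @param se expression SummarizedExperiment. Intensities are log2 by
#'   default (`logScale = TRUE`): they are exponentiated, scaled
#'   multiplicatively and re-logged.
#' @param reference a sample id, or "median" for a per-probe median
#'   pseudo-reference.
#' @param tol rank-difference tolerance as a fraction of the probe count.
#' @param maxIter number of selection passes.
#' @param minInvariant minimum invariant-set size; default is 50 probes or
#'   5% of probes, whichever is smaller. A smaller set is an error
#'   (advice: pick a different reference).
#' @param logScale whether the assay is log2 (TRUE) or original-scale
#'   positive intensities (FALSE, which must be strictly positive).
#' @return a SummarizedExperiment of the same shape, normalized.
#' @export
rankInvariantNormalize <- function(se, reference = "median", tol = 0.05,
                                   maxIter = 2, minInvariant = NULL,
                                   logScale = TRUE) {
  if (ncol(se) < 2) .paramError("se", "need at least 2 samples")
  vals <- SummarizedExperiment::assay(se, 1)
  raw <- if (logScale) 2^vals else vals
  if (any(!is.finite(raw)) || any(raw <= 0))
    .paramError("se", "intensities must be strictly positive and finite")
  n <- nrow(raw)
  minInvariant <- minInvariant %||% min(50L, max(1L, ceiling(tol * n)))

  ref <- if (identical(reference, "median")) {
    apply(raw, 1, stats::median)
  } else {
    if (!reference %in% colnames(raw))
      .paramError("reference", paste0("unknown sample '", reference, "'"))
    raw[, reference]
  }

  out <- raw
  for (s in colnames(raw)) {
    keep <- seq_len(n)
    for (it in seq_len(maxIter)) {
      rs <- rank(raw[keep, s], ties.method = "average")
      rr <- rank(ref[keep], ties.method = "average")
      keep <- keep[abs(rs - rr) <= tol * length(keep)]
      if (!length(keep)) break
    }
    if (length(keep) < minInvariant)
      stop("rank-invariant set for sample '", s, "' has ", length(keep),
           " probes (< ", minInvariant,
           "); consider a different reference")
    fac <- stats::median(ref[keep] / raw[keep, s])
    out[, s] <- raw[, s] * fac
  }
  SummarizedExperiment::assay(se, 1) <- if (logScale) log2(out) else out
  se
}

# vectorized Welch / Student t over rows of two matrices (NAs allowed)
.rowTTest <- function(x, y, var.equal = FALSE) {
  nx <- rowSums(!is.na(x)); ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- rowSums((x - mx)^2, na.rm = TRUE) / pmax(nx - 1, 1)
  vy <- rowSums((y - my)^2, na.rm = TRUE) / pmax(ny - 1, 1)
  if (var.equal) {
    sp <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se2 <- sp * (1 / nx + 1 / ny)
    df <- nx + ny - 2
  } else {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate zero-variance rows: identical means -> no evidence (t = 0,
  # p = 1); different means -> p = 0 (reported, with a note upstream)
  degen <- is.finite(mx) & is.finite(my) & se2 == 0
  t[degen] <- ifelse(mx[degen] == my[degen], 0, Inf * sign(mx - my)[degen])
  p[degen] <- ifelse(mx[degen] == my[degen], 1, 0)
  bad <- nx < 2 | ny < 2
  t[bad] <- NA; df[bad] <- NA; p[bad] <- NA
  list(t = t, df = df, p = p, nx = nx, ny = ny, mx = mx, my = my)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value. Fewer than two non-missing values in
#' either group yields an all-NA result rather than an error, so callers
#' can map it over features. When both groups have zero variance but
#' different means the p value is reported as 0 with a logged note.
#'
#' @param x,y numeric vectors (NAs dropped).
#' @return list with `statistic`, `df`, `p.value`.
#' @examples
#' welchTest(c(1, 2, 3), c(2, 3, 4))
#' @export
welchTest <- function(x, y) {
  r <- .rowTTest(matrix(x, 1), matrix(y, 1))
  if (is.finite(r$p) && r$p == 0 && is.infinite(r$t))
    logMsg("zero variance in both groups with different means: p = 0",
           level = "WARN")
  list(statistic = unname(r$t), df = unname(r$df), p.value = unname(r$p))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wraps [stats::p.adjust()] with the package's missing-value contract:
#' missing entries pass through and are excluded from the family size m,
#' which is the number of features actually tested.
#'
#' @param p numeric vector of p values in \[0, 1\] (NAs allowed).
#' @return adjusted p values in the original order, NA where p was NA.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad))
    stop("p value out of [0, 1] at index ", bad[1])
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' q values (FDR estimates)
#'
#' `method = "bh"` returns the Benjamini-Hochberg adjusted values.
#' `method = "storey"` estimates the null proportion pi0 on the lambda
#' grid 0.05, 0.10, ..., 0.95 with a smoothing spline (evaluated at
#' lambda = 0.95, clamped to (0, 1\]) and rescales the BH-style step-up
#' quantities by pi0. Storey estimation needs at least 100 p values;
#' smaller inputs fall back to BH with a warning.
#'
#' @param p numeric p values (NAs pass through).
#' @param method "storey" or "bh".
#' @return q values in the original order.
#' @export
qValues <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad))
    stop("p value out of [0, 1] at index ", bad[1])
  ok <- !is.na(p)
  m <- sum(ok)
  if (method == "bh") return(bhAdjust(p))
  if (m < 100) {
    warning("fewer than 100 p values: falling back to BH q values")
    return(bhAdjust(p))
  }
  pv <- p[ok]
  lam <- seq(0.05, 0.95, by = 0.05)
  pi0l <- vapply(lam, function(l) mean(pv > l) / (1 - l), 0)
  fit <- stats::smooth.spline(lam, pi0l, df = 3)
  pi0 <- stats::predict(fit, x = 0.95)$y
  pi0 <- min(1, max(pi0, 1 / m))
  o <- order(pv)
  q <- pi0 * m * pv[o] / seq_len(m)
  q <- rev(cummin(rev(pmin(q, 1))))
  out <- rep(NA_real_, length(p))
  out[ok][o] <- q
  attr(out, "pi0") <- pi0
  out
}

# per-feature minimum imputation of partial missingness (profiling
# convention: undetected values sit at the feature's detection limit)
.imputeMin <- function(vals) {
  for (i in which(rowSums(is.na(vals)) > 0)) {
    obs <- vals[i, !is.na(vals[i, ])]
    if (length(obs)) vals[i, is.na(vals[i, ])] <- min(obs)
  }
  vals
}

#' Two-group differential table
#'
#' One row per feature: group means and fold change on the original scale
#' (ratio of arithmetic means, treated/control), t test on the log2 scale,
#' BH-adjusted p and q values. For metabolite tables
#' (`valueScale = "natural"`) partial missingness is min-imputed per
#' feature before log transform and testing; features with fewer than two
#' observed values in either group are flagged untested (`tested = FALSE`,
#' NA statistics) and excluded from the FDR family m.
#'
#' @param se expression (log2) or metabolite (natural-scale)
#'   SummarizedExperiment with `colData$group`.
#' @param control,treated group labels to contrast.
#' @param test "welch" (default) or "student".
#' @param valueScale "log2" for expression, "natural" for abundances.
#' @param qMethod q-value method passed to [qValues()]; the default picks
#'   Storey when at least 100 features are tested.
#' @return data.frame with columns feature, n_control, n_treated,
#'   mean_control, mean_treated, fold_change, log2fc, t, df, p, adj_p, q,
#'   tested.
#' @export
differentialTable <- function(se, control, treated,
                              test = c("welch", "student"),
                              valueScale = c("log2", "natural"),
                              qMethod = NULL) {
  test <- match.arg(test)
  valueScale <- match.arg(valueScale)
  groups <- sampleGroups(se)
  for (lab in c(control, treated))
    if (!lab %in% groups)
      stop("unknown group label '", lab, "'")
  vals <- SummarizedExperiment::assay(se, 1)
  xc <- vals[, groups == control, drop = FALSE]
  xt <- vals[, groups == treated, drop = FALSE]

  if (valueScale == "natural") {
    nObsC <- rowSums(!is.na(xc)); nObsT <- rowSums(!is.na(xt))
    testable <- nObsC >= 2 & nObsT >= 2
    xc <- .imputeMin(xc); xt <- .imputeMin(xt)
    posFloor <- function(m) {
      if (any(m <= 0, na.rm = TRUE)) {
        mn <- min(m[m > 0], na.rm = TRUE)
        m[m <= 0] <- mn / 2
      }
      m
    }
    xc <- posFloor(xc); xt <- posFloor(xt)
    lc <- log2(xc); lt <- log2(xt)
    meanC <- rowMeans(xc, na.rm = TRUE); meanT <- rowMeans(xt, na.rm = TRUE)
  } else {
    nObsC <- rowSums(!is.na(xc)); nObsT <- rowSums(!is.na(xt))
    lc <- xc; lt <- xt
    meanC <- rowMeans(2^xc, na.rm = TRUE); meanT <- rowMeans(2^xt, na.rm = TRUE)
    testable <- nObsC >= 2 & nObsT >= 2
  }

  r <- .rowTTest(lt, lc, var.equal = (test == "student"))
  r$t[!testable] <- NA; r$df[!testable] <- NA; r$p[!testable] <- NA
  nUntested <- sum(!testable)
  if (nUntested)
    logMsg(nUntested, " feature(s) with <2 observed values per group ",
           "flagged untested and excluded from the FDR family")
  if (any(!is.na(r$p) & r$p == 0 & is.infinite(r$t)))
    logMsg("zero-variance feature(s) with different means: p reported as 0",
           level = "WARN")
  adj <- bhAdjust(r$p)
  qMethod <- qMethod %||% if (sum(testable) >= 100) "storey" else "bh"
  q <- suppressWarnings(qValues(r$p, method = qMethod))
  logMsg("FDR family m = ", sum(testable), " tested features")

  data.frame(feature = rownames(vals),
             n_control = nObsC, n_treated = nObsT,
             mean_control = meanC, mean_treated = meanT,
             fold_change = meanT / meanC,
             log2fc = log2(meanT / meanC),
             t = r$t, df = r$df, p = r$p, adj_p = adj, q = q,
             tested = testable, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call a directional signature from a differential table
#'
#' Up = adjusted p at or below the cutoff and fold change > 1; down =
#' fold change < 1. A significant feature with fold change exactly 1 is
#' assigned to neither direction (logged).
#'
#' @param results data.frame from [differentialTable()].
#' @param threshold adjusted-p cutoff.
#' @param name contrast label for the signature.
#' @return a [Signature-class].
#' @export
makeSignature <- function(results, threshold = 0.05, name = "signature") {
  if (!nrow(results)) .paramError("results", "empty differential table")
  sig <- !is.na(results$adj_p) & results$adj_p <= threshold
  ties <- sig & results$fold_change == 1
  if (any(ties))
    logMsg(sum(ties), " significant feature(s) with fold change exactly 1",
           " assigned to neither direction")
  degSignature(name,
               up = results$feature[sig & results$fold_change > 1],
               down = results$feature[sig & results$fold_change < 1],
               threshold = threshold)
}

#' Signature overlap counts (Venn table)
#'
#' Per direction: features only in `a`, shared, and only in `b`.
#'
#' @param a,b [Signature-class] objects.
#' @return data.frame with columns direction, a_only, shared, b_only.
#' @export
vennCounts <- function(a, b) {
  row <- function(sa, sb)
    c(a_only = length(setdiff(sa, sb)),
      shared = length(intersect(sa, sb)),
      b_only = length(setdiff(sb, sa)))
  up <- row(upGenes(a), upGenes(b))
  dn <- row(downGenes(a), downGenes(b))
  data.frame(direction = c("up", "down"),
             a_only = c(up[1], dn[1]), shared = c(up[2], dn[2]),
             b_only = c(up[3], dn[3]), row.names = NULL)
}
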