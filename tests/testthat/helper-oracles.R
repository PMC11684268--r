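# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and the library calls they wrap).

# Benjamini-Hochberg step-up, written from the definition
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}

# upper-tail hypergeometric P(X >= a) by direct enumeration of the table
# probabilities (lchoose arithmetic, no distribution functions)
hyperTailEnum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  xs <- max(0, k - r2):min(r1, k)
  logp <- lchoose(r1, xs) + lchoose(r2, k - xs) - lchoose(r1 + r2, k)
  sum(exp(logp)[xs >= a])
}

# weighted-KS running sum evaluated the slow, literal way
bruteES <- function(feature, score, set, exponent = 0) {
  N <- length(feature)
  hit <- feature %in% set
  s <- sum(hit)
  w <- abs(score)^exponent
  W <- sum(w[hit])
  if (W == 0) { w[] <- 1; W <- s }
  run <- 0; runs <- numeric(N)
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) w[i] / W else -1 / (N - s)
    runs[i] <- run
  }
  if (max(runs) >= -min(runs) - 1e-12) max(runs) else min(runs)
}

# radius-h reachability by adjacency-matrix powers
neighborhoodOracle <- function(edges, nodes, v, radius, mode = "both") {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) A[cbind(edges$from, edges$to)] <- 1
  if (mode == "in") A <- t(A)
  if (mode == "both") A <- pmax(A, t(A))
  reach <- A
  R <- A
  if (radius > 1) for (h in seq_len(radius - 1)) {
    R <- R %*% A
    reach <- reach + R
  }
  setdiff(nodes[reach[v, ] > 0], v)
}

# small expression SummarizedExperiment built in code
makeExprSE <- function(vals, groups) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = vals),
    colData = S4Vectors::DataFrame(group = groups,
                                   row.names = colnames(vals)))
}

makeMetabSE <- function(vals, groups, super = NULL) {
  rowAnn <- S4Vectors::DataFrame(
    super_pathway = super %||% rep("unknown", nrow(vals)),
    sub_pathway = rep("unknown", nrow(vals)),
    row.names = rownames(vals))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = vals), rowData = rowAnn,
    colData = S4Vectors::DataFrame(group = groups,
                                   row.names = colnames(vals)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
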