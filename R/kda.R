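#' One-sided Fisher's exact test (enrichment tail)
#'
#' Upper-tail hypergeometric probability P(X >= a) for the 2x2 table
#' (a, b / c, d) conditioned on its margins — the enrichment p value used
#' by the key-driver analysis. Vectorized over tables.
#'
#' @param a,b,c,d nonnegative integer cell counts (row 1 = a, b; row 2 =
#'   c, d).
#' @return the one-sided p value(s).
#' @examples
#' fisherOneSided(3, 2, 7, 88)
#' @export
fisherOneSided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) .paramError("a", "counts must be nonnegative")
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' h-step neighborhood of a gene in a directed network
#'
#' Breadth-first set of nodes within `radius` hops of `gene` following
#' outgoing edges, incoming edges, or both; the gene itself is excluded.
#'
#' @param network a [GeneNetwork-class].
#' @param gene node id; unknown ids are an error.
#' @param radius hop count (>= 1).
#' @param direction "out", "in" or "both".
#' @return character vector of neighbor ids (possibly empty).
#' @examples
#' net <- geneNetwork(data.frame(from = c("a", "b"), to = c("b", "c")))
#' neighborhood(net, "b", direction = "both")
#' @export
neighborhood <- function(network, gene, radius = 1,
                         direction = c("both", "out", "in")) {
  direction <- match.arg(direction)
  if (radius < 1) .paramError("radius", "must be >= 1")
  if (!gene %in% networkNodes(network))
    stop("unknown gene '", gene, "'")
  g <- .asIgraph(network)
  mode <- c(both = "all", out = "out", `in` = "in")[[direction]]
  nb <- igraph::ego(g, order = radius, nodes = gene, mode = mode,
                    mindist = 1)[[1]]
  sort(names(nb))
}

#' Extract the top most-connected subnetwork around seed genes
#'
#' Takes the induced subgraph on the seeds and their `expand`-hop
#' neighbors (undirected reach), splits it into weakly connected
#' components, ranks components by edge count and returns the top one.
#' Ties are broken by the smallest lexicographic node id. Seeds absent
#' from the network are logged, not fatal; zero overlapping seeds is an
#' error.
#'
#' @param network a [GeneNetwork-class].
#' @param seeds character vector (or [Signature-class]) of seed genes.
#' @param expand hop count for neighbor expansion (>= 0).
#' @return a [GeneNetwork-class] of the top component; its `metadata`
#'   carries `componentRanking` (data.frame: component, nodes, edges,
#'   seeds) and `missingSeeds`.
#' @export
extractSubnetwork <- function(network, seeds, expand = 1) {
  if (is(seeds, "Signature")) seeds <- signatureGenes(seeds)
  seeds <- unique(seeds)
  missing <- setdiff(seeds, networkNodes(network))
  if (length(missing))
    logMsg(length(missing), " seed(s) absent from the network")
  seeds <- setdiff(seeds, missing)
  if (!length(seeds))
    stop("no seed overlaps the network (overlap 0)")
  g <- .asIgraph(network)
  keep <- seeds
  if (expand > 0) {
    nb <- igraph::ego(g, order = expand, nodes = seeds, mode = "all")
    keep <- unique(c(seeds, unlist(lapply(nb, names))))
  }
  sub <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(sub, mode = "weak")
  ranking <- do.call(rbind, lapply(seq_len(comp$no), function(i) {
    members <- names(comp$membership)[comp$membership == i]
    csub <- igraph::induced_subgraph(sub, members)
    data.frame(component = i, nodes = length(members),
               edges = igraph::ecount(csub),
               seeds = sum(members %in% seeds),
               min_node = min(members), stringsAsFactors = FALSE)
  }))
  ranking <- ranking[order(-ranking$edges, ranking$min_node), ]
  rownames(ranking) <- NULL
  topMembers <- names(comp$membership)[comp$membership ==
                                         ranking$component[1]]
  topSub <- igraph::induced_subgraph(g, topMembers)
  el <- igraph::as_edgelist(topSub)
  out <- geneNetwork(data.frame(from = el[, 1], to = el[, 2],
                                stringsAsFactors = FALSE),
                     nodes = sort(topMembers))
  out@metadata <- list(componentRanking = ranking,
                       missingSeeds = missing)
  out
}

#' Key driver analysis
#'
#' For every candidate gene (neighborhood of at least `minNeighborhood`
#' nodes within `radius` hops), tests whether its neighborhood is
#' enriched for signature genes relative to the rest of the network
#' (excluding the candidate itself) with a one-sided Fisher's exact test,
#' then applies Bonferroni correction over the candidates actually
#' tested. Genes with Bonferroni-adjusted p below `alpha` are flagged as
#' key drivers. The background universe is the network's node set; the
#' signature is intersected with it first (discarded count logged).
#'
#' @param network a [GeneNetwork-class].
#' @param signature character vector or [Signature-class] of signature
#'   genes.
#' @param radius neighborhood hop count (default 1).
#' @param direction edge direction for the neighborhood ("both" by
#'   default: 1-hop undirected neighborhoods, the common choice in the
#'   KDA lineage).
#' @param alpha Bonferroni-adjusted significance cutoff.
#' @param minNeighborhood smallest neighborhood size tested.
#' @return data.frame sorted by ascending bonferroni_p (ties by gene id):
#'   gene, neighborhood_size, overlap, fisher_p, bonferroni_p, is_kd.
#' @export
keyDriverAnalysis <- function(network, signature, radius = 1,
                              direction = c("both", "out", "in"),
                              alpha = 0.05, minNeighborhood = 5) {
  direction <- match.arg(direction)
  if (is(signature, "Signature")) signature <- signatureGenes(signature)
  signature <- unique(signature)
  nodes <- networkNodes(network)
  discarded <- setdiff(signature, nodes)
  if (length(discarded))
    logMsg(length(discarded),
           " signature gene(s) outside the network discarded")
  sig <- intersect(signature, nodes)
  if (!length(sig))
    stop("signature does not intersect the network nodes")

  g <- .asIgraph(network)
  mode <- c(both = "all", out = "out", `in` = "in")[[direction]]
  nb <- igraph::ego(g, order = radius, mode = mode, mindist = 1)
  names(nb) <- nodes
  sizes <- vapply(nb, length, 0L)
  cand <- nodes[sizes >= minNeighborhood]
  if (!length(cand))
    stop("no candidate with neighborhood >= ", minNeighborhood,
         "; consider a smaller minNeighborhood")

  N <- length(nodes)
  inSig <- nodes %in% sig
  names(inSig) <- nodes
  nTested <- length(cand)
  overlap <- vapply(cand, function(v) sum(inSig[names(nb[[v]])]), 0L)
  k <- sizes[cand]
  m1 <- length(sig) - as.integer(inSig[cand])  # signature minus candidate
  a <- overlap
  p <- fisherOneSided(a, k - a, m1 - a, (N - 1 - k) - (m1 - a))
  bonf <- pmin(1, p * nTested)
  out <- data.frame(gene = cand, neighborhood_size = as.integer(k),
                    overlap = as.integer(overlap), fisher_p = p,
                    bonferroni_p = bonf, is_kd = bonf < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$bonferroni_p, out$gene), ]
}
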