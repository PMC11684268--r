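#' Joint gene-metabolite pathway table
#'
#' Joins transcriptomic and metabolomic differential evidence on a shared
#' pathway namespace: per pathway, the significant genes (with direction)
#' and significant metabolites (with fold change), per-omics
#' over-representation (fold enrichment + hypergeometric p, BH-adjusted
#' across pathways), and a combined flag marking pathways significant in
#' both omics at the given cutoffs.
#'
#' @param geneResults,metaboliteResults data.frames from
#'   [differentialTable()].
#' @param geneSets,metaboliteSets [GeneSetCollection-class] objects over
#'   the two feature universes; their pathway names must share a
#'   namespace (zero shared names is an error).
#' @param geneCutoff,metaboliteCutoff adjusted-p cutoffs, both for calling
#'   significant features and for the per-omics enrichment flag.
#' @return data.frame, one row per pathway with at least one detected
#'   member in either omics: pathway, de_genes, de_metabolites,
#'   gene_k, gene_fold_enrichment, gene_p, gene_adj_p, metabolite_k,
#'   metabolite_fold_enrichment, metabolite_p, metabolite_adj_p,
#'   combined.
#' @export
jointPathwayTable <- function(geneResults, metaboliteResults, geneSets,
                              metaboliteSets, geneCutoff = 0.05,
                              metaboliteCutoff = 0.05) {
  if (!nrow(geneResults) || !nrow(metaboliteResults))
    .paramError("geneResults", "both differential tables must be non-empty")
  shared <- intersect(names(geneSets), names(metaboliteSets))
  if (!length(shared))
    stop("zero shared pathway names between the gene and metabolite ",
         "annotations")

  sigOf <- function(res, cutoff)
    res$feature[!is.na(res$adj_p) & res$adj_p <= cutoff]
  detectedG <- geneResults$feature[geneResults$tested]
  detectedM <- metaboliteResults$feature[metaboliteResults$tested]
  sigG <- intersect(sigOf(geneResults, geneCutoff), detectedG)
  sigM <- intersect(sigOf(metaboliteResults, metaboliteCutoff), detectedM)

  oraG <- ora(sigG, detectedG, geneSets)
  oraM <- ora(sigM, detectedM, metaboliteSets)

  pathways <- sort(union(oraG$set, oraM$set))
  dirOf <- function(res, f) ifelse(res$fold_change[match(f, res$feature)] > 1,
                                   "up", "down")
  rows <- lapply(pathways, function(pw) {
    gMembers <- if (pw %in% names(geneSets))
      intersect(geneSets[[pw]], sigG) else character()
    mMembers <- if (pw %in% names(metaboliteSets))
      intersect(metaboliteSets[[pw]], sigM) else character()
    gi <- match(pw, oraG$set); mi <- match(pw, oraM$set)
    deg <- if (length(gMembers))
      paste0(gMembers, "(", dirOf(geneResults, gMembers), ")",
             collapse = ",") else ""
    dem <- if (length(mMembers))
      paste0(mMembers, "(",
             sprintf("%.3g",
                     metaboliteResults$fold_change[
                       match(mMembers, metaboliteResults$feature)]),
             ")", collapse = ",") else ""
    combined <- !is.na(gi) && !is.na(mi) &&
      oraG$adj_p[gi] <= geneCutoff && oraM$adj_p[mi] <= metaboliteCutoff
    data.frame(pathway = pw, de_genes = deg, de_metabolites = dem,
               gene_k = if (is.na(gi)) NA_integer_ else oraG$k[gi],
               gene_fold_enrichment = if (is.na(gi)) NA_real_
                 else oraG$fold_enrichment[gi],
               gene_p = if (is.na(gi)) NA_real_ else oraG$p[gi],
               gene_adj_p = if (is.na(gi)) NA_real_ else oraG$adj_p[gi],
               metabolite_k = if (is.na(mi)) NA_integer_ else oraM$k[mi],
               metabolite_fold_enrichment = if (is.na(mi)) NA_real_
                 else oraM$fold_enrichment[mi],
               metabolite_p = if (is.na(mi)) NA_real_ else oraM$p[mi],
               metabolite_adj_p = if (is.na(mi)) NA_real_
                 else oraM$adj_p[mi],
               combined = combined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Key-driver-centered gene-metabolite reaction map
#'
#' Builds the reaction subgraph within `radius` hops (undirected reach) of
#' a called key driver and annotates every node with its omics layer and
#' differential state: `up`/`down` when significant at the cutoff,
#' `unchanged` when measured but not significant, `unmeasured` otherwise
#' (unmeasured is deliberately distinct from unchanged).
#'
#' @param kd one row of the [keyDriverAnalysis()] result (or any
#'   list/data.frame with `gene` and `is_kd`); must be a called key
#'   driver.
#' @param reactions data.frame (`source`, `target`, `relation`) of
#'   curated reaction edges; must reference the key driver.
#' @param geneResults,metaboliteResults data.frames from
#'   [differentialTable()].
#' @param radius hop radius around the center (0 = center only).
#' @param cutoff adjusted-p cutoff for up/down states (same convention as
#'   [makeSignature()]).
#' @return a [KdMap-class].
#' @export
kdMap <- function(kd, reactions, geneResults, metaboliteResults,
                  radius = 2, cutoff = 0.05) {
  center <- as.character(kd$gene[1] %||% kd$gene)
  if (!isTRUE(as.logical(kd$is_kd[1])))
    .paramError("kd", "gene is not a called key driver")
  reactions <- data.frame(source = as.character(reactions$source),
                          target = as.character(reactions$target),
                          relation = as.character(reactions$relation %||%
                                                    rep("reaction",
                                                        nrow(reactions))),
                          stringsAsFactors = FALSE)
  allNodes <- unique(c(reactions$source, reactions$target))
  if (!center %in% allNodes)
    stop("key driver '", center, "' absent from the reaction annotation")

  keep <- center
  if (radius > 0) {
    frontier <- center
    for (h in seq_len(radius)) {
      nxt <- unique(c(reactions$target[reactions$source %in% frontier],
                      reactions$source[reactions$target %in% frontier]))
      frontier <- setdiff(nxt, keep)
      keep <- union(keep, frontier)
      if (!length(frontier)) break
    }
  }
  edges <- reactions[reactions$source %in% keep &
                       reactions$target %in% keep, , drop = FALSE]
  rownames(edges) <- NULL

  stateOf <- function(id) {
    lookup <- function(res) {
      i <- match(id, res$feature)
      if (is.na(i) || !isTRUE(res$tested[i])) return(NA_character_)
      if (!is.na(res$adj_p[i]) && res$adj_p[i] <= cutoff)
        (if (res$fold_change[i] > 1) "up" else "down")
      else "unchanged"
    }
    g <- lookup(geneResults)
    if (!is.na(g)) return(c(g, "gene"))
    m <- lookup(metaboliteResults)
    if (!is.na(m)) return(c(m, "metabolite"))
    c("unmeasured",
      if (id %in% geneResults$feature) "gene"
      else if (id %in% metaboliteResults$feature) "metabolite"
      else "unknown")
  }
  st <- vapply(keep, stateOf, character(2))
  nodes <- data.frame(id = keep, layer = st[2, ], state = st[1, ],
                      row.names = NULL, stringsAsFactors = FALSE)
  new("KdMap", center = center, nodes = nodes, edges = edges)
}

#' Export a KdMap to GraphML
#'
#' Node attributes `layer` and `state` plus a `center` flag are attached
#' for rendering in Cytoscape-like viewers.
#'
#' @param map a [KdMap-class].
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
writeKdMapGraphML <- function(map, path) {
  net <- geneNetwork(data.frame(from = map@edges$source,
                                to = map@edges$target,
                                stringsAsFactors = FALSE),
                     nodes = map@nodes$id)
  writeGraphML(net, annotations = list(
    layer = stats::setNames(map@nodes$layer, map@nodes$id),
    state = stats::setNames(map@nodes$state, map@nodes$id),
    center = stats::setNames(as.integer(map@nodes$id == map@center),
                             map@nodes$id)), path)
}
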