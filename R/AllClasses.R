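#' Directed gene network
#'
#' Thin S4 container for a directed gene-gene network: an edge table plus
#' the node universe (which may contain isolated nodes). Self-loops are not
#' allowed; readers drop them and record the count.
#'
#' @slot nodes character vector of node identifiers (unique).
#' @slot edges data.frame with columns `from`, `to` (directed edges,
#'   duplicates collapsed).
#' @slot droppedSelfLoops number of self-loop edges removed on construction.
#' @slot metadata free-form list (e.g. component ranking from
#'   [extractSubnetwork()]).
#' @aliases GeneNetwork-class
#' @export
setClass("GeneNetwork",
  representation(nodes = "character", edges = "data.frame",
                 droppedSelfLoops = "integer", metadata = "list"),
  prototype(nodes = character(), droppedSelfLoops = 0L, metadata = list(),
            edges = data.frame(from = character(), to = character(),
                               stringsAsFactors = FALSE)))

setValidity("GeneNetwork", function(object) {
  e <- object@edges
  if (!all(c("from", "to") %in% names(e)))
    return("edges must have columns 'from' and 'to'")
  if (anyDuplicated(object@nodes))
    return("duplicate node ids")
  if (nrow(e) && !all(c(e$from, e$to) %in% object@nodes))
    return("node universe must contain all edge endpoints")
  if (nrow(e) && any(e$from == e$to))
    return("self-loops are not allowed")
  if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
    return("duplicate edges are not allowed")
  TRUE
})

#' Construct a GeneNetwork
#'
#' @param edges two-column data.frame (`from`, `to`) of directed edges.
#'   Duplicate edges are collapsed; self-loops are dropped and counted.
#' @param nodes optional node universe; defaults to the edge endpoints.
#'   Must be a superset of the endpoints.
#' @return a [GeneNetwork-class] object.
#' @examples
#' geneNetwork(data.frame(from = "a", to = "b"))
#' @export
geneNetwork <- function(edges, nodes = NULL) {
  edges <- data.frame(from = as.character(edges[[1]]),
                      to = as.character(edges[[2]]),
                      stringsAsFactors = FALSE)
  self <- edges$from == edges$to
  nSelf <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  endpoints <- unique(c(edges$from, edges$to))
  nodes <- if (is.null(nodes)) endpoints else unique(as.character(nodes))
  if (!all(endpoints %in% nodes))
    .paramError("nodes", "must contain every edge endpoint")
  new("GeneNetwork", nodes = nodes, edges = edges,
      droppedSelfLoops = as.integer(nSelf))
}

#' @describeIn geneNetwork node universe accessor
#' @param network a `GeneNetwork`.
#' @export
networkNodes <- function(network) network@nodes

#' @describeIn geneNetwork edge table accessor
#' @export
networkEdges <- function(network) network@edges

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork: %d nodes, %d directed edges",
              length(object@nodes), nrow(object@edges)))
  if (object@droppedSelfLoops > 0L)
    cat(sprintf(" (%d self-loops dropped)", object@droppedSelfLoops))
  cat("\n")
  if (length(object@metadata))
    cat("metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

# internal: igraph view of the network (vertices carry the full universe)
.asIgraph <- function(network) {
  igraph::graph_from_data_frame(network@edges, directed = TRUE,
                                vertices = data.frame(name = network@nodes))
}

#' Named collection of gene (or metabolite) sets
#'
#' GMT-semantics container: uniquely named, non-empty member sets with an
#' optional free-text description per set. Used both for gene pathways and
#' for metabolite pathway maps (the member universe is whatever identifier
#' space the sets were defined over).
#'
#' @slot sets named list of character vectors.
#' @slot descriptions named character vector, parallel to `sets`.
#' @aliases GeneSetCollection-class
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character"),
  prototype(sets = list(), descriptions = character()))

setValidity("GeneSetCollection", function(object) {
  if (length(object@sets) == 0L) return(TRUE)
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    return("set names must be present and unique")
  if (any(lengths(object@sets) == 0L))
    return("every set must be non-empty")
  if (!identical(names(object@sets), names(object@descriptions)))
    return("descriptions must parallel sets")
  TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character member vectors; duplicate members
#'   within a set are removed.
#' @param descriptions optional character vector of descriptions (recycled
#'   empty string).
#' @return a [GeneSetCollection-class].
#' @examples
#' geneSetCollection(list(S1 = c("g1", "g2")))
#' @export
geneSetCollection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  else
    descriptions <- stats::setNames(as.character(descriptions), names(sets))
  new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' @describeIn geneSetCollection member sets as a named list
#' @param collection a `GeneSetCollection`.
#' @export
geneSets <- function(collection) collection@sets

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d sets", length(object@sets)))
  if (length(object@sets))
    cat(sprintf(", sizes %d-%d", min(lengths(object@sets)),
                max(lengths(object@sets))))
  cat("\n")
})

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' Directional differential signature
#'
#' The up/down gene (or metabolite) sets called at a given adjusted-p
#' threshold for one contrast (e.g. exposure vs control).
#'
#' @slot name contrast label (e.g. "DE" or "DE+FA").
#' @slot up,down disjoint character sets of feature ids.
#' @slot threshold adjusted-p cutoff used to call the signature.
#' @aliases Signature-class
#' @export
setClass("Signature",
  representation(name = "character", up = "character", down = "character",
                 threshold = "numeric"),
  prototype(name = "signature", threshold = 0.05))

setValidity("Signature", function(object) {
  if (length(intersect(object@up, object@down)))
    return("up and down sets must be disjoint")
  TRUE
})

#' Construct a Signature
#' @param name contrast label.
#' @param up,down disjoint character sets of up-/down-called features.
#' @param threshold the adjusted-p cutoff that produced the calls.
#' @return a [Signature-class].
#' @export
degSignature <- function(name, up, down, threshold = 0.05) {
  new("Signature", name = name, up = unique(as.character(up)),
      down = unique(as.character(down)), threshold = threshold)
}

#' @describeIn degSignature up-regulated members
#' @param signature a `Signature`.
#' @export
upGenes <- function(signature) signature@up

#' @describeIn degSignature down-regulated members
#' @export
downGenes <- function(signature) signature@down

#' @describeIn degSignature all members regardless of direction
#' @export
signatureGenes <- function(signature) c(signature@up, signature@down)

setMethod("show", "Signature", function(object) {
  cat(sprintf("Signature '%s': %d up, %d down (adj-p <= %g)\n",
              object@name, length(object@up), length(object@down),
              object@threshold))
})

#' Planted ground truth of a synthetic data set
#'
#' Record of everything the generators planted, used downstream as the
#' recovery oracle: which features carry real effects, which network nodes
#' are key drivers, which pathways were seeded, and the full generator
#' parameterization (including the seed) so the data can be regenerated
#' byte-for-byte.
#'
#' @slot plantedDegs data.frame (`gene`, `log2fc`) of genes with a planted
#'   signed log2 effect (all nonzero).
#' @slot plantedMetabolites data.frame (`metabolite`, `fold`) of metabolites
#'   with a planted multiplicative fold effect (all != 1).
#' @slot plantedDrivers character vector of planted key-driver node ids.
#' @slot seededPathways character vector of pathway names seeded with
#'   planted features ("enriched by construction").
#' @slot params list of generator parameters, including the seed.
#' @aliases SyntheticTruth-class
#' @export
setClass("SyntheticTruth",
  representation(plantedDegs = "data.frame",
                 plantedMetabolites = "data.frame",
                 plantedDrivers = "character",
                 seededPathways = "character",
                 params = "list"),
  prototype(
    plantedDegs = data.frame(gene = character(), log2fc = numeric(),
                             stringsAsFactors = FALSE),
    plantedMetabolites = data.frame(metabolite = character(),
                                    fold = numeric(),
                                    stringsAsFactors = FALSE),
    plantedDrivers = character(), seededPathways = character(),
    params = list()))

setValidity("SyntheticTruth", function(object) {
  if (nrow(object@plantedDegs) && any(object@plantedDegs$log2fc == 0))
    return("planted log2 effects must be nonzero")
  if (nrow(object@plantedMetabolites) &&
      any(object@plantedMetabolites$fold == 1))
    return("planted fold effects must differ from 1")
  TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(paste0("SyntheticTruth: %d planted genes, %d planted ",
                     "metabolites, %d drivers, %d seeded pathways\n"),
              nrow(object@plantedDegs), nrow(object@plantedMetabolites),
              length(object@plantedDrivers), length(object@seededPathways)))
})

#' Random-forest classification report
#'
#' @slot accuracy estimated proportion correct (out-of-bag or
#'   leave-one-out, see `scheme`).
#' @slot scheme "oob" or "loocv".
#' @slot confusion per-class confusion counts (true class in rows).
#' @slot importance data.frame (`metabolite`, `importance`) ranked by
#'   permutation importance, descending, ties broken by id.
#' @slot nTrees number of trees in the ensemble.
#' @slot seed the seed the ensemble was grown with.
#' @slot annotations data.frame of per-feature pathway annotations carried
#'   from the input table.
#' @aliases ClassificationReport-class
#' @export
setClass("ClassificationReport",
  representation(accuracy = "numeric", scheme = "character",
                 confusion = "matrix", importance = "data.frame",
                 nTrees = "integer", seed = "integer",
                 annotations = "data.frame"))

setValidity("ClassificationReport", function(object) {
  if (object@accuracy < 0 || object@accuracy > 1)
    return("accuracy must be in [0, 1]")
  TRUE
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport (%s, %d trees): accuracy %.3f\n",
              object@scheme, object@nTrees, object@accuracy))
  print(object@confusion)
})

#' Key-driver-centered gene-metabolite reaction map
#'
#' Subgraph of a user-supplied reaction annotation within a hop radius of a
#' called key driver, with each node annotated by omics layer and
#' differential state. States are `up`, `down`, `unchanged` (measured, not
#' significant) and `unmeasured`; unmeasured is deliberately distinct from
#' unchanged.
#'
#' @slot center the key-driver gene at the map's center.
#' @slot nodes data.frame (`id`, `layer`, `state`).
#' @slot edges data.frame (`source`, `target`, `relation`).
#' @aliases KdMap-class
#' @export
setClass("KdMap",
  representation(center = "character", nodes = "data.frame",
                 edges = "data.frame"))

setValidity("KdMap", function(object) {
  if (!object@center %in% object@nodes$id)
    return("center must be among the map's nodes")
  if (!all(object@nodes$state %in% c("up", "down", "unchanged", "unmeasured")))
    return("node states must be up/down/unchanged/unmeasured")
  TRUE
})

setMethod("show", "KdMap", function(object) {
  cat(sprintf("KdMap centered on '%s': %d nodes, %d reaction edges\n",
              object@center, nrow(object@nodes), nrow(object@edges)))
})
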