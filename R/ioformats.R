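#' Read a feature-by-sample matrix with a sample group map
#'
#' Reads a TSV matrix (first column = feature id, header = sample ids) and
#' a two-column sample-to-group TSV (header `sample`, `group`). Accepted
#' missing-value tokens are the empty cell, `NA` and `NaN` (a per-file
#' count is logged); any other non-numeric cell is an error naming its
#' row/column. Gene and sample identifier matching everywhere in the
#' package is case-sensitive exact string match.
#'
#' @param path matrix TSV path.
#' @param groupsPath group-map TSV path.
#' @param type "expression" (assay `exprs`) or "metabolite" (assay
#'   `abundance`, nonnegative, missing allowed).
#' @param annotationsPath optional TSV (`metabolite`, `super_pathway`,
#'   `sub_pathway`); metabolites without a row are annotated "unknown".
#' @return a [SummarizedExperiment::SummarizedExperiment] with
#'   `colData$group` (and metabolite rowData annotations).
#' @export
readOmicsMatrix <- function(path, groupsPath,
                            type = c("expression", "metabolite"),
                            annotationsPath = NULL) {
  type <- match.arg(type)
  if (!file.exists(path)) .usageError(paste0("missing input file: ", path))
  if (!file.exists(groupsPath))
    .usageError(paste0("missing group map: ", groupsPath))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  ids <- raw[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s) in ", path)

  cells <- as.matrix(raw[, -1, drop = FALSE])
  missingTok <- is.na(cells) | cells %in% c("", "NA", "NaN")
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !missingTok, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 ids[bad[1, 1]], samples[bad[1, 2]], path))
  vals[missingTok] <- NA_real_
  if (any(missingTok))
    logMsg(sum(missingTok), " missing cells in ", path)
  dimnames(vals) <- list(ids, samples)

  gm <- utils::read.delim(groupsPath, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("sample", "group") %in% names(gm)))
    stop("group map must have columns 'sample' and 'group'")
  unmapped <- setdiff(samples, gm$sample)
  if (length(unmapped))
    stop("sample(s) missing from group map: ",
         paste(unmapped, collapse = ", "))
  groups <- gm$group[match(samples, gm$sample)]

  rowAnn <- NULL
  if (type == "metabolite") {
    if (any(vals < 0, na.rm = TRUE))
      stop("metabolite abundances must be nonnegative")
    ann <- data.frame(super_pathway = rep("unknown", length(ids)),
                      sub_pathway = rep("unknown", length(ids)),
                      row.names = ids, stringsAsFactors = FALSE)
    if (!is.null(annotationsPath)) {
      at <- utils::read.delim(annotationsPath, sep = "\t", header = TRUE,
                              colClasses = "character")
      hit <- match(ids, at[[1]])
      ann$super_pathway[!is.na(hit)] <- at$super_pathway[hit[!is.na(hit)]]
      ann$sub_pathway[!is.na(hit)] <- at$sub_pathway[hit[!is.na(hit)]]
    }
    rowAnn <- S4Vectors::DataFrame(ann)
  }

  SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(vals),
                             if (type == "expression") "exprs" else "abundance"),
    rowData = rowAnn,
    colData = S4Vectors::DataFrame(group = groups, row.names = samples))
}

#' Write a feature-by-sample matrix, its group map and (optionally)
#' metabolite annotations
#'
#' Inverse of [readOmicsMatrix()]: UTF-8 tab-delimited with headers,
#' missing values written as `NA`, full precision.
#'
#' @param se the SummarizedExperiment to write.
#' @param path matrix TSV destination.
#' @param groupsPath group-map TSV destination.
#' @param annotationsPath optional annotation TSV destination (written when
#'   the rowData carries `super_pathway`).
#' @return invisibly, `path`.
#' @export
writeOmicsMatrix <- function(se, path, groupsPath,
                             annotationsPath = NULL) {
  vals <- SummarizedExperiment::assay(se, 1)
  df <- data.frame(feature = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gm <- data.frame(sample = colnames(se), group = sampleGroups(se))
  utils::write.table(gm, groupsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rd <- SummarizedExperiment::rowData(se)
  if (!is.null(annotationsPath) && "super_pathway" %in% names(rd)) {
    ann <- data.frame(metabolite = rownames(se),
                      super_pathway = rd$super_pathway,
                      sub_pathway = rd$sub_pathway)
    utils::write.table(ann, annotationsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>member...`. Order is preserved;
#' duplicate members within a set are dropped with a warning; lines with
#' fewer than three fields are an error naming the line number.
#'
#' @param path GMT file path.
#' @return a [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) .usageError(paste0("missing GMT file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(geneSetCollection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields in %s", short[1],
                 path))
  nms <- vapply(fields, `[[`, "", 1L)
  sets <- lapply(fields, function(f) f[-c(1, 2)])
  nDup <- sum(vapply(sets, function(s) sum(duplicated(s)), 0L))
  if (nDup > 0)
    warning(nDup, " duplicate member(s) within sets dropped in ", path)
  geneSetCollection(stats::setNames(sets, nms),
                    vapply(fields, `[[`, "", 2L))
}

#' Write a GeneSetCollection in GMT format
#' @param collection a [GeneSetCollection-class].
#' @param path destination.
#' @return invisibly, `path`.
#' @export
writeGmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, collection@descriptions[[nm]], collection@sets[[nm]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a network from SIF or two-column TSV
#'
#' SIF lines are `source<TAB>relation<TAB>target[<TAB>target...]`; a line
#' with a single field declares an isolated node. A file whose every line
#' has exactly two fields is read as a `from<TAB>to` edge list (no
#' header). Duplicate edges are collapsed; self-loops are dropped with a
#' logged count.
#'
#' @param path network file path.
#' @return a [GeneNetwork-class].
#' @export
readNetwork <- function(path) {
  if (!file.exists(path)) .usageError(paste0("missing network file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(geneNetwork(data.frame(from = character(), to = character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  edges <- list(); isolated <- character()
  if (all(nf == 2L)) {
    edges <- lapply(fields, function(f) cbind(f[1], f[2]))
  } else {
    bad <- which(nf == 2L)
    if (length(bad))
      stop(sprintf("malformed SIF line %d (2 fields) in %s", bad[1], path))
    for (f in fields) {
      if (length(f) == 1L) isolated <- c(isolated, f)
      else edges[[length(edges) + 1L]] <- cbind(f[1], f[-c(1, 2)])
    }
  }
  em <- do.call(rbind, edges)
  net <- geneNetwork(
    data.frame(from = if (is.null(em)) character() else em[, 1],
               to = if (is.null(em)) character() else em[, 2],
               stringsAsFactors = FALSE),
    nodes = unique(c(if (is.null(em)) character() else c(em[, 1], em[, 2]),
                     isolated)))
  if (net@droppedSelfLoops > 0L)
    logMsg(net@droppedSelfLoops, " self-loop(s) dropped from ", path)
  net
}

#' Write a network as SIF or two-column TSV
#' @param network a [GeneNetwork-class].
#' @param path destination.
#' @param format "sif" (relation `reg`) or "tsv".
#' @param relation relation label used in SIF output.
#' @return invisibly, `path`.
#' @export
writeNetwork <- function(network, path, format = c("sif", "tsv"),
                         relation = "reg") {
  format <- match.arg(format)
  e <- networkEdges(network)
  lines <- if (format == "sif")
    paste(e$from, relation, e$to, sep = "\t")
  else paste(e$from, e$to, sep = "\t")
  isolated <- setdiff(networkNodes(network), c(e$from, e$to))
  if (format == "sif" && length(isolated))
    lines <- c(lines, isolated)
  writeLines(lines, path)
  invisible(path)
}

#' Export a network to GraphML with node annotations
#'
#' Produces GraphML loadable by standard graph viewers (Cytoscape, yEd).
#' Node annotations (e.g. signature membership, key-driver flag,
#' differential state) become typed node attributes; the node identifier
#' is carried in the `name` attribute.
#'
#' @param network a [GeneNetwork-class].
#' @param annotations named list of per-node attribute vectors, each named
#'   by node id. Unknown node ids are an error. Logical vectors are
#'   written as 0/1.
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
writeGraphML <- function(network, annotations = list(), path) {
  g <- .asIgraph(network)
  nodes <- networkNodes(network)
  for (attr in names(annotations)) {
    v <- annotations[[attr]]
    if (is.null(names(v)))
      stop("annotation '", attr, "' must be named by node id")
    unknown <- setdiff(names(v), nodes)
    if (length(unknown))
      stop("annotation '", attr, "' refers to unknown node(s): ",
           paste(unknown, collapse = ", "))
    if (is.logical(v)) v <- stats::setNames(as.integer(v), names(v))
    full <- if (is.numeric(v)) rep(0, length(nodes))
            else rep("", length(nodes))
    names(full) <- nodes
    full[names(v)] <- v
    g <- igraph::set_vertex_attr(g, attr, value = unname(full))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write / read planted truth as JSON
#'
#' @param truth a [SyntheticTruth-class].
#' @param path JSON destination.
#' @return `writeTruth` returns `path` invisibly; `readTruth` a
#'   [SyntheticTruth-class].
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(list(
    planted_degs = truth@plantedDegs,
    planted_metabolites = truth@plantedMetabolites,
    planted_drivers = truth@plantedDrivers,
    seeded_pathways = truth@seededPathways,
    generator_params = truth@params), path, auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  if (!file.exists(path)) .usageError(paste0("missing truth file: ", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  asDf <- function(d, cols) {
    if (is.null(d) || !length(d))
      return(stats::setNames(data.frame(character(), numeric(),
                                        stringsAsFactors = FALSE), cols))
    stats::setNames(data.frame(d, stringsAsFactors = FALSE), cols)
  }
  new("SyntheticTruth",
      plantedDegs = asDf(x$planted_degs, c("gene", "log2fc")),
      plantedMetabolites = asDf(x$planted_metabolites,
                                c("metabolite", "fold")),
      plantedDrivers = as.character(x$planted_drivers %||% character()),
      seededPathways = as.character(x$seeded_pathways %||% character()),
      params = as.list(x$generator_params %||% list()))
}
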