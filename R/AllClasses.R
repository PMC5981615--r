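#' @import methods
NULL

#' SignalingNetwork: a protein-protein signaling network with cancer labels
#'
#' An S4 container for an undirected (by default) simple graph over gene
#' symbols, together with the subset of nodes labeled as cancer genes. The
#' graph itself is held as an \pkg{igraph} object; all user-facing access goes
#' through the accessors ([nodeNames()], [cancerGenes()], [numNodes()], ...).
#'
#' @slot graph An `igraph` object whose vertices carry unique `name`
#'   attributes (normalized gene symbols).
#' @slot cancerGenes Character vector, a subset of the node names.
#' @slot directed Logical flag; the screening semantics are undirected and
#'   this is `FALSE` throughout the published pipeline.
#'
#' @seealso [readNetwork()], [cleanNetwork()], [synthNetwork()]
#' @export
setClass("SignalingNetwork",
  representation(graph = "ANY", cancerGenes = "character",
                 directed = "logical"))

setValidity("SignalingNetwork", function(object) {
  g <- object@graph
  if (!inherits(g, "igraph")) {
    return("slot 'graph' must be an igraph object")
  }
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    return("all vertices must carry non-empty 'name' attributes")
  }
  if (anyDuplicated(nm)) {
    return("vertex names must be unique")
  }
  if (length(object@directed) != 1L || is.na(object@directed)) {
    return("'directed' must be a single TRUE/FALSE")
  }
  if (object@directed != igraph::is_directed(g)) {
    return("'directed' flag disagrees with the igraph object")
  }
  bad <- setdiff(object@cancerGenes, nm)
  if (length(bad)) {
    return(paste0("cancer genes absent from the network: ",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (anyDuplicated(object@cancerGenes)) {
    return("cancer gene labels must be unique")
  }
  TRUE
})

#' Construct a SignalingNetwork
#'
#' @param graph An `igraph` object with named vertices, or a two-column
#'   data.frame / matrix of edges (symbols are normalized).
#' @param cancerGenes Character vector of cancer gene symbols; silently
#'   intersected with the node set when `restrict = TRUE`.
#' @param directed Logical; build a directed graph from an edge table.
#' @param restrict Logical; drop cancer genes not present in the network
#'   (with a log line) instead of erroring.
#' @return A [SignalingNetwork-class] object.
#' @examples
#' net <- SignalingNetwork(data.frame(a = c("A", "B"), b = c("B", "C")),
#'                         cancerGenes = "A")
#' numNodes(net)
#' @export
SignalingNetwork <- function(graph, cancerGenes = character(),
                             directed = FALSE, restrict = TRUE) {
  if (!inherits(graph, "igraph")) {
    el <- as.data.frame(graph)[, 1:2]
    el[] <- lapply(el, normalizeSymbols)
    graph <- igraph::graph_from_data_frame(el, directed = directed)
    graph <- igraph::simplify(graph, remove.multiple = TRUE,
                              remove.loops = FALSE)
  }
  cancerGenes <- unique(normalizeSymbols(cancerGenes))
  if (restrict) {
    missing <- setdiff(cancerGenes, igraph::V(graph)$name)
    if (length(missing)) {
      vlog("%d cancer genes not in network, dropped", length(missing))
    }
    cancerGenes <- intersect(cancerGenes, igraph::V(graph)$name)
  }
  new("SignalingNetwork", graph = graph, cancerGenes = cancerGenes,
      directed = igraph::is_directed(graph))
}

#' GeneSetCollection: named gene sets for enrichment screening
#'
#' Holds the gene-set collection that backs the function-based screen: each set
#' has a unique ID, a free-text description and a deduplicated vector of
#' normalized member symbols. An optional background universe can be attached.
#'
#' @slot sets Named list of character vectors (members per set ID).
#' @slot descriptions Named character vector, parallel to `sets`.
#' @slot background Character vector (possibly empty) of background symbols.
#'
#' @seealso [readGMT()], [enrich()]
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character",
                 background = "character"))

setValidity("GeneSetCollection", function(object) {
  ids <- names(object@sets)
  if (length(object@sets) == 0L) return("collection has no sets")
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    return("every set needs a non-empty ID")
  }
  if (anyDuplicated(ids)) return("set IDs must be unique")
  if (!identical(names(object@descriptions), ids)) {
    return("descriptions must be named parallel to the sets")
  }
  for (i in seq_along(object@sets)) {
    mem <- object@sets[[i]]
    if (!is.character(mem) || length(mem) == 0L) {
      return(sprintf("set '%s' has no members", ids[i]))
    }
    if (anyDuplicated(mem)) {
      return(sprintf("set '%s' has duplicated members", ids[i]))
    }
  }
  TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param descriptions Optional named character vector of set descriptions.
#' @param background Optional character vector of background symbols.
#' @return A [GeneSetCollection-class] object.
#' @examples
#' gsc <- GeneSetCollection(list(P1 = c("A", "B"), P2 = c("B", "C")))
#' nSets(gsc)
#' @export
GeneSetCollection <- function(sets, descriptions = NULL,
                              background = character()) {
  sets <- lapply(sets, function(m) unique(normalizeSymbols(m)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  descriptions <- as.character(descriptions[names(sets)])
  descriptions[is.na(descriptions)] <- ""
  names(descriptions) <- names(sets)
  new("GeneSetCollection", sets = sets, descriptions = descriptions,
      background = unique(normalizeSymbols(background)))
}

#' FixtureBundle: a seeded synthetic test universe for the SL screen
#'
#' Bundles a synthetic signaling network with planted bridge pairs and all the
#' companion tables the downstream screens and validations consume, so the
#' whole pipeline runs offline and reproducibly from a single seed.
#'
#' @slot network A [SignalingNetwork-class] with planted bridge pairs.
#' @slot plantedPairs data.frame with columns `cancer_gene`, `non_cancer_gene`.
#' @slot geneSets A [GeneSetCollection-class] co-annotating planted pairs.
#' @slot drugTargets data.frame (gene, target_accession, drug, category).
#' @slot slReference data.frame of canonical unordered pairs (gene_a, gene_b).
#' @slot sensitivity data.frame
#'   (cell_line, mutated_cancer_gene, drug, target_gene, log_ic50).
#' @slot literature data.frame (gene, K, x, context).
#' @slot litGlobals list with per-context global counts `M` and `N`.
#' @slot seed Integer seed the bundle was generated from.
#' @slot params List of generator parameters.
#'
#' @seealso [synthBundle()], [writeFixtureBundle()]
#' @export
setClass("FixtureBundle",
  representation(network = "SignalingNetwork", plantedPairs = "data.frame",
                 geneSets = "GeneSetCollection", drugTargets = "data.frame",
                 slReference = "data.frame", sensitivity = "data.frame",
                 literature = "data.frame", litGlobals = "list",
                 seed = "integer", params = "list"))

setValidity("FixtureBundle", function(object) {
  pp <- object@plantedPairs
  if (!all(c("cancer_gene", "non_cancer_gene") %in% names(pp))) {
    return("plantedPairs needs columns cancer_gene, non_cancer_gene")
  }
  nm <- nodeNames(object@network)
  cg <- cancerGenes(object@network)
  if (!all(pp$cancer_gene %in% cg)) {
    return("planted cancer genes must be cancer-labeled network nodes")
  }
  if (!all(pp$non_cancer_gene %in% setdiff(nm, cg))) {
    return("planted non-cancer genes must be non-cancer network nodes")
  }
  TRUE
})
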