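#' @rdname SignalingNetwork-class
#' @aliases nodeNames,SignalingNetwork-method
setMethod("nodeNames", "SignalingNetwork", function(x) {
  igraph::V(x@graph)$name
})

#' @rdname SignalingNetwork-class
setMethod("numNodes", "SignalingNetwork", function(x) {
  igraph::vcount(x@graph)
})

#' @rdname SignalingNetwork-class
setMethod("numEdges", "SignalingNetwork", function(x) {
  igraph::ecount(x@graph)
})

#' @rdname SignalingNetwork-class
setMethod("cancerGenes", "SignalingNetwork", function(x) x@cancerGenes)

#' @rdname SignalingNetwork-class
setMethod("cancerGenes<-", "SignalingNetwork", function(x, value) {
  value <- unique(normalizeSymbols(value))
  missing <- setdiff(value, nodeNames(x))
  if (length(missing)) {
    vlog("%d cancer genes not in network, dropped", length(missing))
    value <- intersect(value, nodeNames(x))
  }
  x@cancerGenes <- value
  validObject(x)
  x
})

#' @rdname SignalingNetwork-class
setMethod("nonCancerGenes", "SignalingNetwork", function(x) {
  setdiff(nodeNames(x), x@cancerGenes)
})

#' @rdname SignalingNetwork-class
setMethod("isDirected", "SignalingNetwork", function(x) x@directed)

#' @rdname SignalingNetwork-class
setMethod("networkGraph", "SignalingNetwork", function(x) x@graph)

setMethod("show", "SignalingNetwork", function(object) {
  cat(sprintf(
    "SignalingNetwork: %d nodes, %d edges (%s)\n  cancer genes: %d | non-cancer: %d\n",
    numNodes(object), numEdges(object),
    if (isDirected(object)) "directed" else "undirected",
    length(cancerGenes(object)), length(nonCancerGenes(object))))
})

#' @rdname GeneSetCollection-class
#' @aliases geneSets,GeneSetCollection-method
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
setMethod("setIds", "GeneSetCollection", function(x) names(x@sets))

#' @rdname GeneSetCollection-class
setMethod("nSets", "GeneSetCollection", function(x) length(x@sets))

#' @rdname GeneSetCollection-class
setMethod("setDescriptions", "GeneSetCollection", function(x) x@descriptions)

#' @rdname GeneSetCollection-class
setMethod("setBackground", "GeneSetCollection", function(x) x@background)

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@sets)
  cat(sprintf(
    "GeneSetCollection: %d sets (member counts %d-%d)%s\n",
    nSets(object), min(sz), max(sz),
    if (length(object@background)) {
      sprintf(", background of %d genes", length(object@background))
    } else ""))
})

setMethod("show", "FixtureBundle", function(object) {
  cat(sprintf(
    "FixtureBundle (seed %d): %d-node network, %d planted pairs, %d gene sets\n",
    object@seed, numNodes(object@network), nrow(object@plantedPairs),
    nSets(object@geneSets)))
})
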