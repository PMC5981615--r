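#' @rdname SignalingNetwork-class
#' @param object,x A [SignalingNetwork-class] or [GeneSetCollection-class].
#' @param value Replacement value.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname SignalingNetwork-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname SignalingNetwork-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname SignalingNetwork-class
#' @export
setGeneric("cancerGenes", function(x) standardGeneric("cancerGenes"))

#' @rdname SignalingNetwork-class
#' @export
setGeneric("cancerGenes<-", function(x, value) standardGeneric("cancerGenes<-"))

#' @rdname SignalingNetwork-class
#' @export
setGeneric("nonCancerGenes", function(x) standardGeneric("nonCancerGenes"))

#' @rdname SignalingNetwork-class
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))

#' @rdname SignalingNetwork-class
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("nSets", function(x) standardGeneric("nSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setBackground", function(x) standardGeneric("setBackground"))
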