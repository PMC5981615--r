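#' Clean a signaling network
#'
#' Removes self-loops, collapses duplicate (redundant) edges and drops orphan
#' (degree-0) nodes. With `pruneLeaves = TRUE` one additional single pass
#' removes all nodes that have degree 1 at the start of the pass (peripheral
#' nodes and their interactions); orphans created by that pass are removed
#' afterwards. The operation is idempotent.
#'
#' @param net A [SignalingNetwork-class].
#' @param pruneLeaves Logical; also strip degree-1 leaf nodes in one
#'   (non-iterative) pass. Off by default.
#' @return A cleaned [SignalingNetwork-class]; cancer labels are intersected
#'   with the surviving node set.
#' @examples
#' net <- SignalingNetwork(data.frame(a = c("A", "A"), b = c("B", "B")))
#' numEdges(cleanNetwork(net))
#' @export
cleanNetwork <- function(net, pruneLeaves = FALSE) {
  stopifnot(is(net, "SignalingNetwork"))
  g <- networkGraph(net)
  if (igraph::vcount(g) == 0L) stop("cannot clean an empty network")
  n0 <- igraph::vcount(g); e0 <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  orphans <- igraph::V(g)$name[igraph::degree(g) == 0L]
  g <- igraph::delete_vertices(g, orphans)
  nLeaves <- 0L
  if (pruneLeaves && igraph::vcount(g) > 0L) {
    leaves <- igraph::V(g)$name[igraph::degree(g) == 1L]
    nLeaves <- length(leaves)
    g <- igraph::delete_vertices(g, leaves)
    g <- igraph::delete_vertices(g, igraph::V(g)$name[igraph::degree(g) == 0L])
  }
  if (igraph::vcount(g) == 0L) stop("cleaning emptied the graph")
  vlog("clean: %d->%d nodes, %d->%d edges (%d orphans, %d leaves removed)",
       n0, igraph::vcount(g), e0, igraph::ecount(g), length(orphans), nLeaves)
  SignalingNetwork(g, cancerGenes = cancerGenes(net))
}

#' Shortest-path distance between two genes
#'
#' @param net A [SignalingNetwork-class].
#' @param a,b Gene symbols present in the network.
#' @return Minimal hop count as a number; `Inf` marks an unreachable pair.
#' @examples
#' net <- SignalingNetwork(data.frame(a = c("A", "B"), b = c("B", "C")))
#' pairDistance(net, "A", "C")
#' @export
pairDistance <- function(net, a, b) {
  stopifnot(is(net, "SignalingNetwork"))
  a <- normalizeSymbols(a); b <- normalizeSymbols(b)
  unknown <- setdiff(c(a, b), nodeNames(net))
  if (length(unknown)) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  }
  as.vector(igraph::distances(networkGraph(net), v = a, to = b))
}

# internal: CSR adjacency (0-based offsets + neighbor array) of a bare
# igraph, out-neighbors when directed, for the BFS kernel
.graphAdj <- function(g) {
  mode <- if (igraph::is_directed(g)) "out" else "all"
  al <- lapply(igraph::as_adj_list(g, mode = mode, loops = "ignore",
                                   multiple = FALSE),
               function(v) as.integer(v) - 1L)
  list(ptr = c(0L, cumsum(lengths(al))),
       nbr = as.integer(unlist(al, use.names = FALSE)))
}

# internal: average shortest path length of a bare igraph over reachable
# pairs (BFS kernel); NaN when no pair is reachable
.apl <- function(g) {
  if (igraph::vcount(g) < 2L) return(NaN)
  adj <- .graphAdj(g)
  aplMaskedCpp(adj$ptr, adj$nbr, rep(FALSE, igraph::vcount(g)))
}

#' Average shortest path length of the network
#'
#' For a connected undirected graph this is
#' \deqn{D = \frac{1}{\tfrac12 N(N-1)} \sum_{i>j} d_{ij},}
#' the mean hop distance over all unordered node pairs. Node removal can
#' disconnect the graph, in which case the mean is taken over *reachable*
#' pairs only (the igraph convention). `strict = TRUE` instead errors on a
#' disconnected graph.
#'
#' @param net A [SignalingNetwork-class] (or a bare igraph, used internally).
#' @param strict Logical; error when the graph is disconnected.
#' @return The average shortest path length as a single number.
#' @examples
#' net <- SignalingNetwork(data.frame(a = c("A", "B"), b = c("B", "C")))
#' avgShortestPathLength(net)  # (1 + 1 + 2) / 3
#' @export
avgShortestPathLength <- function(net, strict = FALSE) {
  g <- if (is(net, "SignalingNetwork")) networkGraph(net) else net
  if (igraph::vcount(g) < 2L) stop("need at least 2 nodes")
  if (strict && !igraph::is_connected(
        g, mode = if (igraph::is_directed(g)) "strong" else "weak")) {
    stop("graph is disconnected (strict mode)")
  }
  d <- .apl(g)
  if (is.nan(d)) stop("no reachable pair in the network")
  d
}

#' Shortest-path traversal frequencies of non-cancer genes
#'
#' For every reachable (cancer gene, non-cancer gene) pair, each non-cancer
#' gene that lies strictly between the endpoints on at least one shortest path
#' is credited once for that pair (endpoints excluded; path multiplicities are
#' not counted). A node `v` is interior to some shortest `c`-`g` path iff
#' `d(c,v) + d(v,g) == d(c,g)`.
#'
#' @param net A [SignalingNetwork-class] with non-empty cancer labels.
#' @return Named integer vector: traversal count per non-cancer gene
#'   (the frequency table), in node order.
#' @examples
#' net <- SignalingNetwork(data.frame(a = c("C1", "X"), b = c("X", "N1")),
#'                         cancerGenes = "C1")
#' pathFrequencies(net)  # X bridges the (C1, N1) pair
#' @export
pathFrequencies <- function(net) {
  stopifnot(is(net, "SignalingNetwork"))
  cg <- cancerGenes(net)
  nc <- nonCancerGenes(net)
  if (length(cg) == 0L) stop("network has no cancer genes")
  if (length(nc) == 0L) stop("network has no non-cancer genes")
  g <- networkGraph(net)
  D <- igraph::distances(g)
  sub <- D[nc, nc, drop = FALSE]          # interior v (rows) x target g (cols)
  freq <- stats::setNames(integer(length(nc)), nc)
  for (c in cg) {
    dcv <- D[c, nc]                       # distance c -> candidate interior v
    onPath <- (dcv + sub) == matrix(dcv, length(nc), length(nc), byrow = TRUE)
    onPath[, !is.finite(dcv)] <- FALSE    # unreachable (c,g) pairs drop out
    onPath[!is.finite(dcv), ] <- FALSE
    diag(onPath) <- FALSE                 # v == g: endpoint, never interior
    freq <- freq + as.integer(rowSums(onPath))
  }
  freq
}

#' Top fraction of genes by traversal frequency
#'
#' @param freq Named integer vector from [pathFrequencies()].
#' @param fraction Fraction in (0, 1]; `ceiling(fraction * length(freq))`
#'   genes are returned.
#' @return Character vector of gene symbols, sorted by count descending with
#'   ties broken by symbol ascending.
#' @examples
#' selectTopFraction(c(A = 5, B = 5, C = 1), 1 / 3)
#' @export
selectTopFraction <- function(freq, fraction) {
  if (length(freq) == 0L) stop("empty frequency table")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("'fraction' must lie in (0, 1]")
  }
  ord <- order(-freq, names(freq))
  utils::head(names(freq)[ord], ceiling(fraction * length(freq)))
}

#' All candidate (cancer, non-cancer) gene pairs
#'
#' Full cross product in deterministic order: cancer-major, each block sorted
#' by symbol.
#'
#' @param nonCancer,cancer Character vectors of gene symbols; must be
#'   non-empty and disjoint.
#' @return data.frame with columns `cancer_gene` and `non_cancer_gene` and
#'   `length(cancer) * length(nonCancer)` rows.
#' @examples
#' candidatePairs(c("X", "Y"), c("KRAS", "MYC"))
#' @export
candidatePairs <- function(nonCancer, cancer) {
  nonCancer <- unique(normalizeSymbols(nonCancer))
  cancer <- unique(normalizeSymbols(cancer))
  if (length(nonCancer) == 0L || length(cancer) == 0L) {
    stop("both gene lists must be non-empty")
  }
  shared <- intersect(nonCancer, cancer)
  if (length(shared)) {
    stop("gene lists overlap: ", paste(utils::head(shared, 5), collapse = ", "))
  }
  cancer <- sort(cancer); nonCancer <- sort(nonCancer)
  data.frame(
    cancer_gene = rep(cancer, each = length(nonCancer)),
    non_cancer_gene = rep(nonCancer, times = length(cancer)),
    stringsAsFactors = FALSE)
}
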