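# Independent brute-force oracles, deliberately naive and igraph-free where
# the quantity under test is computed with igraph/Rcpp machinery.

# Floyd-Warshall all-pairs hop distances from an edge matrix (undirected)
fwDistances <- function(edges, nodes) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    if (a != b) D[a, b] <- D[b, a] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# mean distance over reachable unordered pairs, from the FW matrix
fwAPL <- function(edges, nodes) {
  D <- fwDistances(edges, nodes)
  v <- D[upper.tri(D)]
  v <- v[is.finite(v)]
  if (length(v) == 0) NaN else mean(v)
}

# oracle stability score by explicit node deletion + Floyd-Warshall
fwStability <- function(edges, nodes, m, n) {
  del <- function(drop) {
    keep <- setdiff(nodes, drop)
    e <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
    fwAPL(e, keep)
  }
  D0 <- fwAPL(edges, nodes)
  (2 * del(c(m, n)) - del(m) - del(n)) / D0
}

# all shortest paths between a and b by exhaustive simple-path DFS
allShortestPaths <- function(edges, nodes, a, b) {
  adj <- lapply(setNames(nodes, nodes), function(v) {
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  })
  best <- list(len = Inf, paths = list())
  walk <- function(path) {
    v <- path[length(path)]
    if (length(path) - 1 > best$len) return()
    if (v == b) {
      if (length(path) - 1 < best$len) {
        best$len <<- length(path) - 1
        best$paths <<- list(path)
      } else {
        best$paths[[length(best$paths) + 1]] <<- path
      }
      return()
    }
    for (w in setdiff(adj[[v]], path)) walk(c(path, w))
  }
  walk(a)
  best
}

# oracle traversal frequencies: credit each non-cancer interior node once per
# reachable (cancer, non-cancer) pair
oracleFrequencies <- function(edges, nodes, cancer) {
  nc <- setdiff(nodes, cancer)
  freq <- setNames(integer(length(nc)), nc)
  for (cg in cancer) {
    for (g in nc) {
      sp <- allShortestPaths(edges, nodes, cg, g)
      if (!is.finite(sp$len)) next
      interior <- setdiff(unique(unlist(sp$paths)), c(cg, g))
      interior <- intersect(interior, nc)
      freq[interior] <- freq[interior] + 1L
    }
  }
  freq
}

# exhaustive hypergeometric upper tail P[X >= k]: enumerate all n-subsets of
# a population of N with K successes
enumHyperTail <- function(k, K, n, N) {
  pop <- c(rep(1, K), rep(0, N - K))
  subsets <- utils::combn(N, n)
  hits <- apply(subsets, 2, function(ix) sum(pop[ix]) >= k)
  mean(hits)
}

# random small graph as an edge matrix (possibly disconnected)
randomEdgeMatrix <- function(nNodes, p = 0.35) {
  nodes <- paste0("N", seq_len(nNodes))
  all <- t(utils::combn(nodes, 2))
  all[stats::runif(nrow(all)) < p, , drop = FALSE]
}

netFromEdges <- function(edges, nodes, cancerGenes = character()) {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges)) g <- igraph::add_edges(g, as.vector(t(edges)))
  SignalingNetwork(g, cancerGenes = cancerGenes)
}

# tiny planted bundle used by several fast tests
smallBundle <- function(seed = 1) {
  synthBundle(nNodes = 80, nCancer = 8, nPlanted = 2, seed = seed)
}
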