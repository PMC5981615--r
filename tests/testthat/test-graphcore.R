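test_that("cleanNetwork strips loops, duplicate edges and orphans", {
  g <- igraph::graph_from_edgelist(
    rbind(c("A", "A"), c("A", "B"), c("A", "B")), directed = FALSE)
  g <- igraph::add_vertices(g, 1, name = "C")
  net <- cleanNetwork(SignalingNetwork(g, cancerGenes = c("A", "C")))
  expect_equal(sort(nodeNames(net)), c("A", "B"))
  expect_equal(numEdges(net), 1L)
  expect_equal(cancerGenes(net), "A")  # labels follow the surviving nodes
})

test_that("leaf pruning is a single pass and can empty a path graph", {
  path <- SignalingNetwork(data.frame(a = c("A", "B"), b = c("B", "C")))
  expect_error(cleanNetwork(path, pruneLeaves = TRUE), "emptied")
  k4 <- SignalingNetwork(t(utils::combn(c("A", "B", "C", "D"), 2)))
  expect_equal(numNodes(cleanNetwork(k4, pruneLeaves = TRUE)), 4L)
})

test_that("cleanNetwork is idempotent on random graphs", {
  withr::local_seed(42)
  for (i in 1:10) {
    e <- randomEdgeMatrix(9, 0.3)
    if (nrow(e) == 0) next
    net <- SignalingNetwork(as.data.frame(e))
    once <- cleanNetwork(net)
    twice <- cleanNetwork(once)
    expect_equal(sort(nodeNames(twice)), sort(nodeNames(once)))
    expect_equal(numEdges(twice), numEdges(once))
  }
})

test_that("pairDistance gives hop counts, 0 on identity, Inf across components", {
  net <- SignalingNetwork(data.frame(a = c("A", "B", "D"),
                                     b = c("B", "C", "E")))
  expect_equal(pairDistance(net, "A", "C"), 2)
  expect_equal(pairDistance(net, "A", "A"), 0)
  expect_equal(pairDistance(net, "A", "D"), Inf)
  expect_error(pairDistance(net, "A", "Z"), "unknown")
})

test_that("average shortest path length matches its closed forms", {
  path3 <- SignalingNetwork(data.frame(a = c("A", "B"), b = c("B", "C")))
  expect_equal(avgShortestPathLength(path3), 4 / 3)
  k4 <- SignalingNetwork(t(utils::combn(c("A", "B", "C", "D"), 2)))
  expect_equal(avgShortestPathLength(k4), 1.0)
  # disconnection convention: mean over reachable pairs only
  two <- SignalingNetwork(data.frame(a = c("A", "C"), b = c("B", "D")))
  expect_equal(avgShortestPathLength(two), 1.0)
  expect_error(avgShortestPathLength(two, strict = TRUE), "disconnected")
  lonely <- SignalingNetwork(
    igraph::add_vertices(igraph::make_empty_graph(0, directed = FALSE),
                         2, name = c("A", "B")))
  expect_error(avgShortestPathLength(lonely), "no reachable pair")
})

test_that("average path length agrees with a Floyd-Warshall oracle", {
  withr::local_seed(7)
  nChecked <- 0
  for (i in 1:40) {
    nNodes <- sample(4:12, 1)
    nodes <- paste0("N", seq_len(nNodes))
    e <- randomEdgeMatrix(nNodes, runif(1, 0.2, 0.6))
    if (nrow(e) == 0) next
    oracle <- fwAPL(e, nodes)
    if (is.nan(oracle)) next
    net <- netFromEdges(e, nodes)
    expect_equal(avgShortestPathLength(net), oracle)
    nChecked <- nChecked + 1
  }
  expect_gte(nChecked, 25)
})

test_that("traversal frequencies follow the interior-node convention", {
  chain <- netFromEdges(rbind(c("C1", "X"), c("X", "N1")),
                        c("C1", "X", "N1"), cancerGenes = "C1")
  expect_equal(pathFrequencies(chain), c(X = 1L, N1 = 0L))
  star <- netFromEdges(rbind(c("X", "C1"), c("X", "N1"), c("X", "N2")),
                       c("X", "C1", "N1", "N2"), cancerGenes = "C1")
  expect_equal(pathFrequencies(star)[["X"]], 2L)
  # both equal-length routes are credited once per pair
  diamond <- netFromEdges(rbind(c("C", "A"), c("A", "N"),
                                c("C", "B"), c("B", "N")),
                          c("C", "A", "B", "N"), cancerGenes = "C")
  f <- pathFrequencies(diamond)
  expect_equal(f[["A"]], 1L)
  expect_equal(f[["B"]], 1L)
})

test_that("traversal frequencies agree with exhaustive path enumeration", {
  withr::local_seed(11)
  nChecked <- 0
  for (i in 1:15) {
    nNodes <- sample(5:10, 1)
    nodes <- paste0("N", seq_len(nNodes))
    e <- randomEdgeMatrix(nNodes, runif(1, 0.25, 0.5))
    if (nrow(e) == 0) next
    cancer <- sample(nodes, sample(1:2, 1))
    net <- netFromEdges(e, nodes, cancerGenes = cancer)
    got <- pathFrequencies(net)
    want <- oracleFrequencies(e, nodes, cancer)
    expect_equal(got[sort(names(got))], want[sort(names(want))])
    nChecked <- nChecked + 1
  }
  expect_gte(nChecked, 10)
})

test_that("top-fraction selection uses ceiling and lexicographic ties", {
  freq <- stats::setNames(c(5L, 5L, 1L), c("B", "A", "C"))
  expect_equal(selectTopFraction(freq, 1 / 3), "A")
  ten <- stats::setNames(10:1, paste0("G", 1:10))
  expect_length(selectTopFraction(ten, 0.3), 3)
  expect_equal(selectTopFraction(ten, 1.0), names(ten))
  expect_error(selectTopFraction(ten, 0), "fraction")
  # prefix / monotone property
  full <- selectTopFraction(ten, 1.0)
  for (f in c(0.1, 0.4, 0.8)) {
    sub <- selectTopFraction(ten, f)
    expect_identical(sub, full[seq_along(sub)])
  }
})

test_that("candidate pairs form the deterministic cross product", {
  p <- candidatePairs(c("Y", "X"), c("M2", "M1"))
  expect_equal(nrow(p), 4L)
  expect_equal(p$cancer_gene, c("M1", "M1", "M2", "M2"))
  expect_equal(p$non_cancer_gene, c("X", "Y", "X", "Y"))
  expect_equal(nrow(candidatePairs("A", "B")), 1L)
  expect_error(candidatePairs(c("A", "G"), c("G", "B")), "G")
})
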