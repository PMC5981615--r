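test_that("stability score matches closed forms and the brute-force oracle", {
  # complete graph: removals change nothing, S = 0
  k5 <- t(utils::combn(paste0("V", 1:5), 2))
  netK5 <- SignalingNetwork(as.data.frame(k5), cancerGenes = "V1")
  recK5 <- stabilityScore(netK5, "V1", "V2")
  expect_equal(recK5$S, 0)
  expect_equal(recK5$D0, 1)

  # 5-cycle with adjacent m, n: D0 = 1.5, Dm = Dn = 5/3, Dmn = 4/3
  ring <- cbind(c("M", "N", "A", "B", "C"), c("N", "A", "B", "C", "M"))
  netC5 <- SignalingNetwork(as.data.frame(ring), cancerGenes = "M")
  rec <- stabilityScore(netC5, "M", "N")
  expect_equal(rec$D0, 1.5)
  expect_equal(rec$Dm, 5 / 3)
  expect_equal(rec$Dn, 5 / 3)
  expect_equal(rec$Dmn, 4 / 3)
  expect_equal(rec$S, -4 / 9)
  expect_equal(rec$S, fwStability(ring, c("M", "N", "A", "B", "C"), "M", "N"))

  # removal that strands a single node flags the record degenerate
  star <- rbind(c("M", "X"), c("N", "X"))
  netStar <- SignalingNetwork(as.data.frame(star), cancerGenes = "M")
  expect_true(stabilityScore(netStar, "M", "N")$degenerate)
})

test_that("stability score agrees with Floyd-Warshall on random graphs", {
  withr::local_seed(13)
  nChecked <- 0
  for (i in 1:25) {
    nNodes <- sample(5:12, 1)
    nodes <- paste0("N", seq_len(nNodes))
    e <- randomEdgeMatrix(nNodes, runif(1, 0.3, 0.6))
    if (nrow(e) < 3) next
    present <- unique(as.vector(e))
    if (length(present) < 4) next
    mn <- sample(present, 2)
    net <- netFromEdges(e, nodes, cancerGenes = mn[1])
    got <- stabilityScore(net, mn[1], mn[2])
    want <- fwStability(e, nodes, mn[1], mn[2])
    if (got$degenerate) {
      expect_false(is.finite(want))
    } else {
      expect_equal(got$S, want)
      nChecked <- nChecked + 1
    }
  }
  expect_gte(nChecked, 12)
})

test_that("degree-preserving randomization keeps the degree sequence exactly", {
  net <- synthNetwork(100, nCancer = 10, seed = 3)
  deg0 <- sort(igraph::degree(networkGraph(net)))
  r1 <- degreePreservingRandomize(net, seed = 42)
  r2 <- degreePreservingRandomize(net, seed = 42)
  r3 <- degreePreservingRandomize(net, seed = 43)
  g1 <- networkGraph(r1)
  expect_equal(sort(igraph::degree(g1)), deg0)
  # per-vertex degrees are preserved too, and the graph stays simple
  expect_equal(igraph::degree(g1)[nodeNames(net)],
               igraph::degree(networkGraph(net))[nodeNames(net)])
  expect_true(igraph::is_simple(g1))
  expect_identical(igraph::as_edgelist(g1),
                   igraph::as_edgelist(networkGraph(r2)))
  expect_false(identical(igraph::as_edgelist(g1),
                         igraph::as_edgelist(networkGraph(r3))))
  # K3 is the unique simple graph on its degree sequence
  k3 <- SignalingNetwork(t(utils::combn(c("A", "B", "C"), 2)))
  rk3 <- degreePreservingRandomize(k3, seed = 1)
  expect_equal(numEdges(rk3), 3L)
  # a near-empty graph is returned unchanged with a warning
  tiny <- SignalingNetwork(data.frame(a = "A", b = "B"))
  expect_warning(same <- degreePreservingRandomize(tiny, seed = 1), "unchanged")
  expect_equal(numEdges(same), 1L)
})

test_that("empirical p-values implement the strict-exceedance ratio", {
  expect_equal(empiricalPvalue(2, rep(1, 1000)), 0)
  expect_equal(empiricalPvalue(0, rep(1, 1000)), 1)
  expect_equal(empiricalPvalue(0.5, c(rep(1, 50), rep(0, 950))), 0.05)
  expect_equal(empiricalPvalue(0.5, c(0.4, 0.6), pseudocount = TRUE), 2 / 3)
  expect_error(empiricalPvalue(1, numeric()), "empty")
})

test_that("cached pair scoring equals independent single-pair evaluation", {
  b <- smallBundle()
  pairs <- candidatePairs(
    utils::head(sort(nonCancerGenes(b@network)), 4),
    utils::head(sort(cancerGenes(b@network)), 3))
  sc <- scorePairs(b@network, pairs, nRandom = 3, seed = 5)
  for (i in seq_len(nrow(pairs))) {
    single <- stabilityScore(b@network, pairs$cancer_gene[i],
                             pairs$non_cancer_gene[i])
    expect_equal(sc$S[i], single$S)
    expect_equal(sc$Dmn[i], single$Dmn)
    expect_equal(sc$distance[i], single$distance)
  }
  # determinism: identical seeds give identical p-values
  sc2 <- scorePairs(b@network, pairs, nRandom = 3, seed = 5)
  expect_identical(sc, sc2)
})

test_that("network screen filters by alpha and rejects an undefined null", {
  b <- smallBundle()
  pairs <- candidatePairs(sort(nonCancerGenes(b@network))[1:3],
                          sort(cancerGenes(b@network))[1:2])
  expect_error(scorePairs(b@network, pairs, nRandom = 0, seed = 1), "null")
  sc <- scorePairs(b@network, pairs, nRandom = 5, seed = 1)
  kept <- networkScreen(b@network, sc, alpha = 0.5)
  expect_true(all(kept$p < 0.5))
  expect_true(nrow(kept) <= nrow(sc))
  expect_error(networkScreen(b@network, sc, alpha = 1.5), "alpha")
})

test_that("ties force p = 0 on a complete graph (documented pathology)", {
  k6 <- SignalingNetwork(t(utils::combn(paste0("V", 1:6), 2)),
                         cancerGenes = c("V1", "V2"))
  pairs <- candidatePairs(c("V3", "V4"), c("V1", "V2"))
  sc <- scorePairs(k6, pairs, nRandom = 10, seed = 2)
  expect_true(all(sc$S == 0))
  expect_true(all(sc$p == 0))  # strict "<" never exceeds a tied null
})

test_that("distance screen floors the mean in auto mode", {
  rec <- data.frame(cancer_gene = paste0("M", 1:5),
                    non_cancer_gene = paste0("N", 1:5),
                    distance = c(1, 2, 3, 3, 4.5))  # mean 2.7 -> threshold 2
  out <- distanceScreen(rec, "auto")
  expect_equal(attr(out, "threshold"), 2)
  expect_equal(nrow(out), 2L)
  expect_equal(nrow(distanceScreen(rec, threshold = 2)), 2L)
  expect_equal(nrow(distanceScreen(rec, threshold = 10)), nrow(rec))
  # the reference distances, not the surviving records, set the auto threshold
  out2 <- distanceScreen(rec[rec$distance > 2, ], "auto",
                         referenceDistances = rec$distance)
  expect_equal(attr(out2, "threshold"), 2)
})

test_that("cumulative-frequency cutoff returns the shortest covering prefix", {
  freq <- c(A = 5L, B = 3L, C = 2L)
  expect_equal(cumulativeFrequencyCutoff(freq, 0.5), "A")
  expect_equal(cumulativeFrequencyCutoff(freq, 0.8), c("A", "B"))
  expect_equal(cumulativeFrequencyCutoff(freq, 1.0), c("A", "B", "C"))
  expect_error(cumulativeFrequencyCutoff(freq, 1.2), "massFraction")
  rec <- data.frame(cancer_gene = "M", non_cancer_gene = c("A", "C"))
  expect_equal(nrow(frequencyScreen(rec, c("A", "B"))), 1L)
  expect_equal(nrow(frequencyScreen(rec, character())), 0L)
  expect_equal(nrow(frequencyScreen(rec, c("A", "C"))), 2L)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  gsc <- GeneSetCollection(list(S1 = c("A", "B", "C")))
  res <- enrich(c("A", "B"), gsc, background = LETTERS[1:10])
  expect_equal(res$p, 3 / 45)  # C(3,2)/C(10,2)
  # k = 0 reports p = 1
  res0 <- enrich(c("H", "I"), gsc, background = LETTERS[1:10])
  expect_equal(res0$p, 1)
  # set covering the whole background: certain event
  gscAll <- GeneSetCollection(list(ALL = LETTERS[1:6]))
  expect_equal(enrich(c("A", "B"), gscAll, background = LETTERS[1:6])$p, 1)
  # exhaustive-oracle sweep over small populations
  withr::local_seed(23)
  for (i in 1:20) {
    N <- sample(5:12, 1)
    bg <- paste0("G", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    set <- sample(bg, K)
    query <- sample(bg, N)[seq_len(n)]
    k <- length(intersect(set, query))
    got <- enrich(query, GeneSetCollection(list(S = set)), background = bg)
    expect_equal(got$p, if (k == 0) 1 else enumHyperTail(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(enrich("A", gsc, background = character()), "background")
})

test_that("function screen keeps a pair only when both genes survive", {
  rec <- data.frame(cancer_gene = c("M1", "M1", "M2"),
                    non_cancer_gene = c("N1", "N2", "N1"),
                    stringsAsFactors = FALSE)
  gsc <- GeneSetCollection(list(SIG = c("M1", "N1"), OTHER = c("N2", "Z1")))
  enr <- data.frame(set_id = c("SIG", "OTHER"), q = c(0.001, 0.9))
  out <- functionScreen(rec, enr, gsc, alpha = 0.05)
  expect_equal(nrow(out), 1L)  # M1-N2 dropped: N2 not in a significant set
  expect_equal(out$cancer_gene, "M1")
  expect_equal(out$non_cancer_gene, "N1")
  noSig <- data.frame(set_id = c("SIG", "OTHER"), q = c(0.5, 0.9))
  expect_equal(nrow(functionScreen(rec, noSig, gsc)), 0L)
})

test_that("each screen yields a subset: pair counts are non-increasing", {
  b <- smallBundle()
  freq <- pathFrequencies(b@network)
  top <- selectTopFraction(freq, 0.3)
  pairs <- candidatePairs(top, cancerGenes(b@network))
  sc <- scorePairs(b@network, pairs, nRandom = 15, seed = 1)
  s1 <- networkScreen(b@network, sc, alpha = 0.05)
  s1d <- distanceScreen(s1, "auto", referenceDistances = sc$distance)
  kept <- cumulativeFrequencyCutoff(freq, 0.5)
  s2 <- frequencyScreen(s1d, kept)
  enr <- enrich(unique(c(s2$cancer_gene, s2$non_cancer_gene)), b@geneSets,
                background = nodeNames(b@network))
  s3 <- functionScreen(s2, enr, b@geneSets, alpha = 0.05)
  counts <- c(nrow(sc), nrow(s1), nrow(s1d), nrow(s2), nrow(s3))
  expect_true(all(diff(counts) <= 0))
  keyAll <- paste(sc$cancer_gene, sc$non_cancer_gene)
  for (step in list(s1, s1d, s2, s3)) {
    expect_true(all(paste(step$cancer_gene, step$non_cancer_gene) %in% keyAll))
  }
})
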