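#' Network-stability score of a gene pair
#'
#' Quantifies how much more the network's average shortest path length grows
#' when the cancer gene `m` and the non-cancer gene `n` are knocked out
#' together than when each is knocked out alone:
#' \deqn{S = \frac{2 D_{m,n} - D_m - D_n}{D_0},}
#' where \eqn{D_0} is the average shortest path length of the intact network
#' and \eqn{D_m}, \eqn{D_n}, \eqn{D_{m,n}} are the values after deleting
#' \eqn{\{m\}}, \eqn{\{n\}} and \eqn{\{m,n\}}. Large positive scores mark
#' pairs whose joint removal disproportionately destabilizes signaling —
#' the network signature of a synthetic-lethal interaction.
#'
#' @param net A [SignalingNetwork-class].
#' @param m Cancer gene symbol (must be cancer-labeled).
#' @param n Non-cancer gene symbol.
#' @param D0 Optional precomputed average shortest path length of `net`.
#' @return One-row data.frame with columns `cancer_gene`, `non_cancer_gene`,
#'   `D0`, `Dm`, `Dn`, `Dmn`, `S`, `distance`, `degenerate`. A removal that
#'   leaves no reachable pair flags the record degenerate (excluded
#'   downstream).
#' @examples
#' ring <- igraph::make_ring(5)
#' igraph::V(ring)$name <- c("M", "N", "A", "B", "C")
#' net <- SignalingNetwork(ring, cancerGenes = "M")
#' stabilityScore(net, "M", "N")$S  # -4/9 on the 5-cycle
#' @export
stabilityScore <- function(net, m, n, D0 = NULL) {
  stopifnot(is(net, "SignalingNetwork"))
  m <- normalizeSymbols(m); n <- normalizeSymbols(n)
  if (!m %in% cancerGenes(net)) stop("'", m, "' is not a cancer gene")
  if (n %in% cancerGenes(net)) stop("'", n, "' is a cancer gene")
  if (!n %in% nodeNames(net)) stop("unknown node '", n, "'")
  if (identical(m, n)) stop("m and n must differ")
  g <- networkGraph(net)
  if (is.null(D0)) D0 <- .apl(g)
  Dm <- .apl(igraph::delete_vertices(g, m))
  Dn <- .apl(igraph::delete_vertices(g, n))
  Dmn <- .apl(igraph::delete_vertices(g, c(m, n)))
  S <- (2 * Dmn - Dm - Dn) / D0
  data.frame(cancer_gene = m, non_cancer_gene = n, D0 = D0, Dm = Dm, Dn = Dn,
             Dmn = Dmn, S = S,
             distance = as.vector(igraph::distances(g, v = m, to = n)),
             degenerate = !is.finite(S), stringsAsFactors = FALSE)
}

#' Degree-preserving randomization of a network
#'
#' Produces a random simple graph with exactly the same node set and degree
#' sequence by repeated double edge swaps (swaps that would create self-loops
#' or multi-edges are rejected). This is the null model against which the
#' stability score is calibrated.
#'
#' @param net A [SignalingNetwork-class].
#' @param seed Integer seed; the same seed yields an identical graph.
#' @param swapsPerEdge Number of attempted swaps per edge (default 10).
#' @return A randomized [SignalingNetwork-class] with identical cancer labels.
#'   A graph with fewer than 2 edges is returned unchanged with a warning.
#' @examples
#' net <- synthNetwork(50, nCancer = 5, seed = 1)
#' rnd <- degreePreservingRandomize(net, seed = 42)
#' identical(sort(igraph::degree(networkGraph(rnd))),
#'           sort(igraph::degree(networkGraph(net))))
#' @export
degreePreservingRandomize <- function(net, seed, swapsPerEdge = 10) {
  stopifnot(is(net, "SignalingNetwork"), swapsPerEdge >= 1)
  g <- networkGraph(net)
  if (igraph::ecount(g) < 2L) {
    warning("fewer than 2 edges; returning the network unchanged")
    return(net)
  }
  g2 <- withr::with_seed(as.integer(seed),
    igraph::rewire(g, igraph::keeping_degseq(
      loops = FALSE, niter = swapsPerEdge * igraph::ecount(g))))
  SignalingNetwork(g2, cancerGenes = cancerGenes(net))
}

#' Empirical p-value of an observed stability score
#'
#' `p = #\{S_random > S_obs\} / length(sRandom)` — the fraction of null
#' scores strictly greater than the observed one, exactly as the screen
#' defines it (no pseudocount by default, so p = 0 is attainable). The
#' optional `pseudocount` switches to the (r+1)/(k+1) permutation correction.
#'
#' @param sObs Observed score.
#' @param sRandom Numeric vector of null scores (non-empty; NAs from
#'   degenerate null draws are ignored in the numerator).
#' @param pseudocount Logical; use (r+1)/(k+1) instead of r/k.
#' @return p-value in \[0, 1\].
#' @examples
#' empiricalPvalue(0.5, c(0.1, 0.6, 0.2, 0.9))  # 2/4
#' @export
empiricalPvalue <- function(sObs, sRandom, pseudocount = FALSE) {
  if (length(sRandom) == 0L) stop("empty null distribution")
  r <- sum(sRandom > sObs, na.rm = TRUE)
  k <- length(sRandom)
  if (pseudocount) (r + 1) / (k + 1) else r / k
}

# internal: stability scores for many pairs on one bare igraph, caching the
# single-removal averages per gene. The removal averages run through the
# masked-BFS kernel; results are identical to independent stabilityScore()
# calls.
.pairScores <- function(g, pairs) {
  nV <- igraph::vcount(g)
  adj <- .graphAdj(g)
  idx <- stats::setNames(seq_len(nV), igraph::V(g)$name)
  noMask <- rep(FALSE, nV)
  maskApl <- function(nodes) {
    msk <- noMask
    msk[idx[nodes]] <- TRUE
    aplMaskedCpp(adj$ptr, adj$nbr, msk)
  }
  D0 <- aplMaskedCpp(adj$ptr, adj$nbr, noMask)
  Dm <- vapply(unique(pairs$cancer_gene), maskApl, numeric(1))
  Dn <- vapply(unique(pairs$non_cancer_gene), maskApl, numeric(1))
  Dmn <- vapply(seq_len(nrow(pairs)), function(i) {
    maskApl(c(pairs$cancer_gene[i], pairs$non_cancer_gene[i]))
  }, numeric(1))
  S <- (2 * Dmn - Dm[pairs$cancer_gene] - Dn[pairs$non_cancer_gene]) / D0
  list(D0 = D0, Dm = unname(Dm[pairs$cancer_gene]),
       Dn = unname(Dn[pairs$non_cancer_gene]), Dmn = Dmn, S = unname(S))
}

#' Score candidate pairs against the degree-preserving null
#'
#' Computes the stability score of every candidate pair on the observed
#' network and on `nRandom` degree-preserving randomizations, then assigns
#' each pair the empirical p-value of its observed score. By default each
#' random network contributes its own average-path-length normalizer
#' \eqn{D_0} (the score formula applied self-consistently);
#' `nullD0 = "observed"` reuses the observed network's \eqn{D_0} instead.
#'
#' @param net A [SignalingNetwork-class].
#' @param pairs data.frame from [candidatePairs()] (columns `cancer_gene`,
#'   `non_cancer_gene`).
#' @param nRandom Number of randomized networks (>= 1).
#' @param seed Integer seed driving the whole ensemble.
#' @param swapsPerEdge Edge-swap intensity per randomization.
#' @param pseudocount Passed to [empiricalPvalue()].
#' @param nullD0 `"own"` (default) or `"observed"`.
#' @return data.frame with one row per pair: `cancer_gene`,
#'   `non_cancer_gene`, `D0`, `Dm`, `Dn`, `Dmn`, `S`, `distance`, `p`,
#'   `n_random`, `degenerate`.
#' @seealso [networkScreen()] for the p < alpha filter.
#' @export
scorePairs <- function(net, pairs, nRandom = 1000, seed = 1,
                       swapsPerEdge = 10, pseudocount = FALSE,
                       nullD0 = c("own", "observed")) {
  stopifnot(is(net, "SignalingNetwork"), nrow(pairs) >= 1L)
  nullD0 <- match.arg(nullD0)
  if (nRandom < 1L) stop("'nRandom' must be >= 1: the null is undefined")
  bad <- !(pairs$cancer_gene %in% cancerGenes(net)) |
         !(pairs$non_cancer_gene %in% nonCancerGenes(net))
  if (any(bad)) stop(sum(bad), " pairs reference invalid nodes")
  g <- networkGraph(net)
  obs <- .pairScores(g, pairs)
  dist <- igraph::distances(g, v = unique(pairs$cancer_gene),
                            to = unique(pairs$non_cancer_gene))
  exceed <- integer(nrow(pairs))
  for (k in seq_len(nRandom)) {
    rnet <- degreePreservingRandomize(net, subSeed(seed, paste0("swap", k)),
                                      swapsPerEdge)
    rs <- .pairScores(networkGraph(rnet), pairs)
    if (nullD0 == "observed") rs$S <- rs$S * rs$D0 / obs$D0
    exceed <- exceed + as.integer(!is.na(rs$S) & rs$S > obs$S)
    if (k %% 25L == 0L) vlog("scored null network %d/%d", k, nRandom)
  }
  p <- if (pseudocount) (exceed + 1) / (nRandom + 1) else exceed / nRandom
  out <- data.frame(
    cancer_gene = pairs$cancer_gene, non_cancer_gene = pairs$non_cancer_gene,
    D0 = obs$D0, Dm = obs$Dm, Dn = obs$Dn, Dmn = obs$Dmn, S = obs$S,
    distance = dist[cbind(pairs$cancer_gene, pairs$non_cancer_gene)],
    p = p, n_random = nRandom, degenerate = !is.finite(obs$S),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Network-based screen: keep pairs significant against the null
#'
#' @param net A [SignalingNetwork-class].
#' @param pairs Candidate pairs ([candidatePairs()]), or a precomputed record
#'   table from [scorePairs()] (then no rescoring happens).
#' @param nRandom,seed,swapsPerEdge,pseudocount,nullD0 Passed to
#'   [scorePairs()] when `pairs` is a raw pair list.
#' @param alpha Significance level in (0, 1); pairs with `p < alpha` are kept.
#' @return Filtered stability-record data.frame (degenerate records dropped
#'   and logged).
#' @export
networkScreen <- function(net, pairs, nRandom = 1000, seed = 1, alpha = 0.05,
                          swapsPerEdge = 10, pseudocount = FALSE,
                          nullD0 = "own") {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)")
  }
  records <- if ("p" %in% names(pairs)) {
    pairs
  } else {
    scorePairs(net, pairs, nRandom = nRandom, seed = seed,
               swapsPerEdge = swapsPerEdge, pseudocount = pseudocount,
               nullD0 = nullD0)
  }
  nDeg <- sum(records$degenerate)
  if (nDeg) vlog("excluding %d degenerate records", nDeg)
  records[!records$degenerate & records$p < alpha, , drop = FALSE]
}

#' Distance-based screen
#'
#' Discards pairs farther apart than a hop threshold. In `"auto"` mode the
#' threshold is the floor of the mean pair distance over all candidate pairs
#' (unreachable pairs excluded from the mean), mirroring "drop pairs farther
#' than average".
#'
#' @param records Stability-record data.frame with a `distance` column.
#' @param threshold `"auto"` or a positive integer hop cutoff.
#' @param referenceDistances Distances used to compute the auto threshold;
#'   defaults to `records$distance`, but the pipeline passes the distances of
#'   *all* candidate pairs so earlier filters do not shift the mean.
#' @return Records with `distance <= threshold` (finite distances only), with
#'   the threshold attached as attribute `"threshold"`.
#' @export
distanceScreen <- function(records, threshold = "auto",
                           referenceDistances = records$distance) {
  if (identical(threshold, "auto")) {
    d <- referenceDistances[is.finite(referenceDistances)]
    if (length(d) == 0L) stop("no finite distances to average")
    threshold <- floor(mean(d))
    vlog("auto distance threshold: mean %.3f -> keep <= %d", mean(d), threshold)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 1)
  out <- records[is.finite(records$distance) &
                 records$distance <= threshold, , drop = FALSE]
  attr(out, "threshold") <- threshold
  out
}

#' Cumulative-frequency cutoff
#'
#' Sorts genes by traversal count (descending, ties by symbol) and returns the
#' shortest prefix whose cumulative count reaches `massFraction` of the total
#' — the high-frequency genes that carry the bulk of cancer/non-cancer
#' shortest-path traffic.
#'
#' @param freq Named integer vector from [pathFrequencies()].
#' @param massFraction Fraction of total count in (0, 1] to cover.
#' @return Character vector of gene symbols (the kept high-frequency genes).
#' @examples
#' cumulativeFrequencyCutoff(c(A = 5, B = 3, C = 2), 0.5)  # "A"
#' @export
cumulativeFrequencyCutoff <- function(freq, massFraction) {
  if (!is.numeric(massFraction) || length(massFraction) != 1L ||
      massFraction <= 0 || massFraction > 1) {
    stop("'massFraction' must lie in (0, 1]")
  }
  total <- sum(freq)
  if (total <= 0) stop("total frequency must be positive")
  ord <- order(-freq, names(freq))
  cum <- cumsum(freq[ord])
  names(freq)[ord][seq_len(which(cum >= massFraction * total)[1])]
}

#' Frequency-based screen
#'
#' @param records Stability-record data.frame.
#' @param keptGenes High-frequency genes from [cumulativeFrequencyCutoff()].
#' @return Records whose non-cancer gene is among `keptGenes`.
#' @export
frequencyScreen <- function(records, keptGenes) {
  records[records$non_cancer_gene %in% keptGenes, , drop = FALSE]
}

#' Hypergeometric gene-set enrichment
#'
#' For each gene set, tests over-representation of the query genes with the
#' one-sided hypergeometric upper tail
#' \eqn{P[X \ge k]} for a population of size `N = |background|` containing
#' `K = |set ∩ background|` successes and `n = |query|` draws, followed by
#' Benjamini-Hochberg adjustment across the tested sets.
#'
#' @param genes Query gene symbols (normalized; genes outside the background
#'   are dropped with a log line).
#' @param collection A [GeneSetCollection-class].
#' @param background Background universe; defaults to the collection's
#'   attached background. Must be non-empty.
#' @return data.frame with columns `set_id`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   sorted by `p` then `set_id`. Sets with `k = 0` are reported with p = 1.
#' @examples
#' gsc <- GeneSetCollection(list(S1 = c("A", "B", "C")))
#' enrich(c("A", "B"), gsc, background = LETTERS[1:10])$p  # 3/45
#' @export
enrich <- function(genes, collection, background = setBackground(collection)) {
  stopifnot(is(collection, "GeneSetCollection"))
  background <- unique(normalizeSymbols(background))
  if (length(background) == 0L) stop("empty background universe")
  genes <- unique(normalizeSymbols(genes))
  outside <- setdiff(genes, background)
  if (length(outside)) {
    vlog("%d query genes outside background, dropped", length(outside))
    genes <- intersect(genes, background)
  }
  N <- length(background); n <- length(genes)
  rows <- lapply(setIds(collection), function(id) {
    set <- intersect(geneSets(collection)[[id]], background)
    K <- length(set)
    k <- length(intersect(set, genes))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Function-based screen
#'
#' A gene survives iff it belongs to at least one gene set whose BH-adjusted
#' enrichment q-value is below `alpha`; a pair is kept iff *both* its genes
#' survive.
#'
#' @param records Stability-record data.frame.
#' @param enrichment Result of [enrich()] on the union of genes in `records`.
#' @param collection The [GeneSetCollection-class] used for the enrichment.
#' @param alpha Significance level on `q` (default 0.05).
#' @return The surviving records, with attribute `"survivingGenes"`.
#' @export
functionScreen <- function(records, enrichment, collection, alpha = 0.05) {
  sig <- enrichment$set_id[enrichment$q < alpha]
  surviving <- unique(unlist(geneSets(collection)[sig], use.names = FALSE))
  out <- records[records$cancer_gene %in% surviving &
                 records$non_cancer_gene %in% surviving, , drop = FALSE]
  attr(out, "survivingGenes") <- surviving
  out
}
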