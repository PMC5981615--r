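#' Generate a seeded synthetic signaling network
#'
#' Builds a simple connected graph — scale-free (Barabási–Albert preferential
#' attachment, the default, since signaling networks are heavy-tailed) or
#' Erdős–Rényi (kept for null-calibration checks) — and labels a random subset
#' of nodes as cancer genes. Erdős–Rényi draws are retried with an
#' incremented internal seed until connected.
#'
#' @param nNodes Number of nodes.
#' @param model `"barabasi_albert"` or `"erdos_renyi"`.
#' @param nCancer Number of cancer-labeled nodes (< nNodes).
#' @param seed Integer seed; the same seed yields an identical network.
#' @param attachEdges Edges added per new node in the BA model (default 3).
#' @param meanDegree Target mean degree of the ER model (default 6).
#' @param maxRetries Connectivity retries for the ER model.
#' @return A connected [SignalingNetwork-class] with nodes `G0001`, `G0002`,
#'   ...
#' @export
synthNetwork <- function(nNodes, model = c("barabasi_albert", "erdos_renyi"),
                         nCancer, seed, attachEdges = 3, meanDegree = 6,
                         maxRetries = 50) {
  model <- match.arg(model)
  stopifnot(nNodes >= 10, nCancer >= 1)
  if (nCancer >= nNodes) stop("'nCancer' must be smaller than 'nNodes'")
  g <- withr::with_seed(subSeed(seed, "synth_network"), {
    if (model == "barabasi_albert") {
      igraph::sample_pa(nNodes, power = 1, m = attachEdges, directed = FALSE)
    } else {
      p <- meanDegree / (nNodes - 1)
      gg <- NULL
      for (try in seq_len(maxRetries)) {
        cand <- igraph::sample_gnp(nNodes, p)
        if (igraph::is_connected(cand)) { gg <- cand; break }
      }
      if (is.null(gg)) {
        stop("could not draw a connected Erdos-Renyi graph in ", maxRetries,
             " tries")
      }
      gg
    }
  })
  igraph::V(g)$name <- sprintf("G%04d", seq_len(nNodes))
  cancer <- withr::with_seed(subSeed(seed, "synth_cancer"),
                             sample(igraph::V(g)$name, nCancer))
  SignalingNetwork(g, cancerGenes = cancer)
}

#' Plant bridge pairs: ground truth for the stability score
#'
#' Rewires the network so that for each planted pair a cancer gene `m` and a
#' non-cancer gene `n` become the two short bridges between a carved-out node
#' group and the rest of the network. A long backup chain keeps the graph
#' connected when both bridges are removed, so joint removal of a planted
#' pair forces every group-to-rest path through the chain and inflates the
#' average shortest path length far beyond either single removal
#' (D_{m,n} >> max(D_m, D_n)). Planted pairs sit at distance 2 (shared group
#' neighbor), so they survive the distance screen by construction.
#'
#' @param net A connected [SignalingNetwork-class].
#' @param nPlanted Number of pairs to plant (>= 1).
#' @param seed Integer seed; same seed, identical topology.
#' @param coreSize Nodes in each carved group core (default 6).
#' @param chainLength Nodes in each backup chain (default 4).
#' @return List with `network` (rewired [SignalingNetwork-class]) and
#'   `plantedPairs` (data.frame `cancer_gene`, `non_cancer_gene`).
#' @export
plantBridgePairs <- function(net, nPlanted, seed, coreSize = 6,
                             chainLength = 4) {
  stopifnot(is(net, "SignalingNetwork"), nPlanted >= 1)
  groupSize <- coreSize + chainLength
  need <- nPlanted * (groupSize + 2) + 10
  if (numNodes(net) < need) {
    stop("graph too small to carve ", nPlanted, " groups (need >= ", need,
         " nodes)")
  }
  if (length(cancerGenes(net)) < nPlanted) {
    stop("not enough cancer genes to plant ", nPlanted, " pairs")
  }
  g <- networkGraph(net)
  withr::with_seed(subSeed(seed, "plant_bridges"), {
    protected <- character()
    planted <- data.frame(cancer_gene = character(),
                          non_cancer_gene = character(),
                          stringsAsFactors = FALSE)
    for (i in seq_len(nPlanted)) {
      freeCancer <- setdiff(cancerGenes(net), protected)
      freeNon <- setdiff(nonCancerGenes(net), protected)
      m <- sample(freeCancer, 1)
      # the non-cancer bridge is drawn from the highest-degree free nodes so
      # it carries realistic shortest-path traffic, as real bridge genes do
      deg <- igraph::degree(g)[setdiff(freeNon, m)]
      n <- sample(names(utils::head(sort(deg, decreasing = TRUE), 8)), 1)
      grp <- sample(setdiff(freeNon, c(m, n)), groupSize)
      core <- grp[seq_len(coreSize)]
      chain <- grp[coreSize + seq_len(chainLength)]
      z <- sample(setdiff(freeNon, c(m, n, grp)), 1)
      # carve the group out of the ambient network
      g <- igraph::delete_edges(
        g, unique(unlist(igraph::incident_edges(g, grp))))
      # core ring, bridged by m and n with one shared neighbor (d(m,n) = 2)
      ring <- cbind(core, core[c(2:coreSize, 1)])
      mAttach <- core[c(1, 3, 5)]
      nAttach <- core[c(2, 4, 5)]
      chainPath <- cbind(c(core[1], chain), c(chain, z))
      newEdges <- rbind(ring, cbind(m, mAttach), cbind(n, nAttach), chainPath)
      g <- igraph::add_edges(g, as.vector(t(newEdges)))
      g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
      protected <- c(protected, m, n, grp, z)
      planted[i, ] <- c(m, n)
    }
    # carving can strand nodes whose only neighbors sat inside a group;
    # re-attach every stray component to an unprotected ambient node
    comp <- igraph::components(g)
    mainComp <- which.max(comp$csize)
    anchorPool <- setdiff(igraph::V(g)$name[comp$membership == mainComp],
                          protected)
    for (cid in setdiff(seq_len(comp$no), mainComp)) {
      member <- igraph::V(g)$name[comp$membership == cid][1]
      g <- igraph::add_edges(g, c(member, sample(anchorPool, 1)))
    }
  })
  planted <- planted[order(planted$cancer_gene, planted$non_cancer_gene), ,
                     drop = FALSE]
  rownames(planted) <- NULL
  list(network = SignalingNetwork(g, cancerGenes = cancerGenes(net)),
       plantedPairs = planted)
}

#' Synthesize companion annotation tables for a planted network
#'
#' Generates every table the downstream screens and validations read, wired to
#' the planted ground truth: a gene-set collection in which all planted genes
#' share one module (plus random decoy sets), drug-target records covering a
#' fraction of the planted non-cancer genes, an SL reference containing a
#' fraction of the planted pairs plus decoy pairs, sensitivity records with
#' negative log-IC50 for planted (partner, target) combinations and
#' non-negative for decoys, and literature counts with elevated x/K for
#' planted genes.
#'
#' @param net The planted [SignalingNetwork-class].
#' @param planted data.frame of planted pairs.
#' @param seed Integer seed.
#' @param fractionTargets,fractionReference,fractionSensitivity Fractions of
#'   planted genes/pairs covered by each resource (defaults 1, 0.8, 0.8).
#' @param nDecoySets,nDecoyPairs Decoy counts for the gene-set collection and
#'   the SL reference.
#' @return List with `geneSets`, `drugTargets`, `slReference`, `sensitivity`,
#'   `literature`, `litGlobals`.
#' @export
synthAnnotations <- function(net, planted, seed, fractionTargets = 1,
                             fractionReference = 0.8,
                             fractionSensitivity = 0.8, nDecoySets = 20,
                             nDecoyPairs = 30) {
  stopifnot(nrow(planted) >= 1L)
  nodes <- nodeNames(net)
  cg <- cancerGenes(net)
  nc <- nonCancerGenes(net)
  pn <- planted$non_cancer_gene
  withr::with_seed(subSeed(seed, "synth_annotations"), {
    sets <- list(PLANTED_MODULE = sort(unique(
      c(planted$cancer_gene, planted$non_cancer_gene))))
    desc <- c(PLANTED_MODULE = "module co-annotating the planted SL pairs")
    for (j in seq_len(nDecoySets)) {
      id <- sprintf("DECOY_%02d", j)
      sets[[id]] <- sort(sample(nodes, 8))
      desc[id] <- "random decoy set"
    }
    nTarg <- max(1L, round(fractionTargets * length(pn)))
    targGenes <- pn[seq_len(nTarg)]
    decoyTargGenes <- sample(setdiff(nc, pn), 10)
    drugTargets <- data.frame(
      gene = c(targGenes, decoyTargGenes),
      target_accession = sprintf("SYN%05d",
                                 seq_len(nTarg + length(decoyTargGenes))),
      drug = paste0("DRUG_", c(targGenes, decoyTargGenes)),
      category = c(rep("Anticancer drug target", nTarg),
                   rep("other", length(decoyTargGenes))),
      stringsAsFactors = FALSE)
    nRef <- round(fractionReference * nrow(planted))
    refPairs <- planted[seq_len(nRef), , drop = FALSE]
    decoyA <- sample(cg, nDecoyPairs, replace = TRUE)
    decoyB <- sample(setdiff(nc, pn), nDecoyPairs, replace = TRUE)
    slReference <- data.frame(
      gene_a = c(pmin(refPairs$cancer_gene, refPairs$non_cancer_gene),
                 pmin(decoyA, decoyB)),
      gene_b = c(pmax(refPairs$cancer_gene, refPairs$non_cancer_gene),
                 pmax(decoyA, decoyB)),
      stringsAsFactors = FALSE)
    slReference <- slReference[!duplicated(slReference), , drop = FALSE]
    nSens <- round(fractionSensitivity * nrow(planted))
    sensPlanted <- planted[seq_len(nSens), , drop = FALSE]
    decoySensTarget <- sample(setdiff(nc, pn), 10, replace = TRUE)
    sensitivity <- data.frame(
      cell_line = sprintf("CL%03d", seq_len(nSens + 10)),
      mutated_cancer_gene = c(sensPlanted$cancer_gene,
                              sample(cg, 10, replace = TRUE)),
      drug = paste0("DRUG_", c(sensPlanted$non_cancer_gene, decoySensTarget)),
      target_gene = c(sensPlanted$non_cancer_gene, decoySensTarget),
      log_ic50 = c(round(stats::runif(nSens, -3, -0.5), 3),
                   round(stats::runif(10, 0.2, 1.5), 3)),
      stringsAsFactors = FALSE)
    litGlobals <- list(cancer = c(M = 1e5, N = 1e6), SL = c(M = 1e4, N = 1e6))
    litGene <- c(pn, decoyTargGenes)
    elevated <- c(rep(TRUE, length(pn)), rep(FALSE, length(decoyTargGenes)))
    literature <- rbind(
      data.frame(gene = litGene, K = 200L,
                 x = ifelse(elevated, 80L, 20L), context = "cancer",
                 stringsAsFactors = FALSE),
      data.frame(gene = litGene, K = 200L,
                 x = ifelse(elevated, 30L, 2L), context = "SL",
                 stringsAsFactors = FALSE))
  })
  list(geneSets = GeneSetCollection(sets, descriptions = desc,
                                    background = nodes),
       drugTargets = drugTargets, slReference = slReference,
       sensitivity = sensitivity, literature = literature,
       litGlobals = litGlobals)
}

#' Build a complete synthetic fixture bundle
#'
#' Chains [synthNetwork()], [plantBridgePairs()] and [synthAnnotations()] into
#' one reproducible [FixtureBundle-class]. The defaults (200 nodes, 20 cancer
#' genes, 5 planted bridge pairs) define the standard test universe for the
#' screen.
#'
#' @param nNodes,model,nCancer Passed to [synthNetwork()].
#' @param nPlanted Passed to [plantBridgePairs()].
#' @param seed Single integer seed for the whole bundle.
#' @param ... Further arguments to [synthAnnotations()].
#' @return A [FixtureBundle-class].
#' @examples
#' bundle <- synthBundle(nNodes = 60, nCancer = 6, nPlanted = 1, seed = 1)
#' bundle
#' @export
synthBundle <- function(nNodes = 200, model = "barabasi_albert", nCancer = 20,
                        nPlanted = 5, seed = 1, ...) {
  base <- synthNetwork(nNodes, model = model, nCancer = nCancer, seed = seed)
  pl <- plantBridgePairs(base, nPlanted = nPlanted, seed = seed)
  ann <- synthAnnotations(pl$network, pl$plantedPairs, seed = seed, ...)
  new("FixtureBundle", network = pl$network, plantedPairs = pl$plantedPairs,
      geneSets = ann$geneSets, drugTargets = ann$drugTargets,
      slReference = ann$slReference, sensitivity = ann$sensitivity,
      literature = ann$literature, litGlobals = ann$litGlobals,
      seed = as.integer(seed),
      params = list(nNodes = nNodes, model = model, nCancer = nCancer,
                    nPlanted = nPlanted, ...))
}

#' Write a fixture bundle to disk in the pipeline's input formats
#'
#' Emits exactly the files the readers consume: `network.tsv` (edge list),
#' `cancer_genes.txt`, `gene_sets.gmt`, `drug_targets.tsv`,
#' `sl_reference.tsv`, `sensitivity.tsv`, `literature.tsv` and a
#' `manifest.json` carrying the parameters, seed, literature globals and
#' planted ground truth.
#'
#' @param bundle A [FixtureBundle-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixtureBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "FixtureBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- networkGraph(bundle@network)
  el <- igraph::as_edgelist(g)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  writeLines(paste(el[, 1], el[, 2], sep = "\t"),
             file.path(dir, "network.tsv"))
  writeLines(sort(cancerGenes(bundle@network)),
             file.path(dir, "cancer_genes.txt"))
  gsc <- bundle@geneSets
  writeLines(vapply(setIds(gsc), function(id) {
    paste(c(id, setDescriptions(gsc)[[id]], geneSets(gsc)[[id]]),
          collapse = "\t")
  }, character(1)), file.path(dir, "gene_sets.gmt"))
  writeResults(bundle@drugTargets, file.path(dir, "drug_targets.tsv"))
  writeResults(bundle@slReference, file.path(dir, "sl_reference.tsv"))
  writeResults(bundle@sensitivity, file.path(dir, "sensitivity.tsv"))
  writeResults(bundle@literature, file.path(dir, "literature.tsv"))
  jsonlite::write_json(
    list(seed = bundle@seed, params = bundle@params,
         litGlobals = lapply(bundle@litGlobals, as.list),
         plantedPairs = bundle@plantedPairs),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}
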