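#' Assemble and validate a pipeline configuration
#'
#' Defaults follow the published screening choices: 1000 randomized networks
#' at alpha 0.05, top 30% of non-cancer genes by traversal frequency, a 50%
#' cumulative-frequency cutoff, an automatic (floor-of-mean) distance
#' threshold, enrichment alpha 0.05 and a log-IC50 sensitivity cutoff of 0.
#'
#' @param inputDir Directory holding the input files (a fixture-bundle layout:
#'   `network.tsv`, `cancer_genes.txt`, `gene_sets.gmt`, `drug_targets.tsv`,
#'   `sl_reference.tsv`, `sensitivity.tsv`, `literature.tsv`,
#'   `manifest.json`). Individual paths can be overridden via `...`.
#' @param outDir Output directory for stage artifacts.
#' @param ... Overrides for any config field (`networkPath`, `topFraction`,
#'   `nRandom`, `alphaNetwork`, `distanceMode`, `massFraction`,
#'   `alphaEnrich`, `ic50Cut`, `seed`, `swapsPerEdge`, `directed`,
#'   `pruneLeaves`, `litGlobals`, ...).
#' @return A validated config list of class `slnetConfig`.
#' @export
pipelineConfig <- function(inputDir, outDir, ...) {
  cfg <- list(
    networkPath = file.path(inputDir, "network.tsv"),
    networkFormat = "tsv",
    cancerGenesPath = file.path(inputDir, "cancer_genes.txt"),
    gmtPath = file.path(inputDir, "gene_sets.gmt"),
    drugTargetsPath = file.path(inputDir, "drug_targets.tsv"),
    slReferencePath = file.path(inputDir, "sl_reference.tsv"),
    sensitivityPath = file.path(inputDir, "sensitivity.tsv"),
    literaturePath = file.path(inputDir, "literature.tsv"),
    manifestPath = file.path(inputDir, "manifest.json"),
    outDir = outDir, directed = FALSE, pruneLeaves = FALSE,
    topFraction = 0.30, massFraction = 0.50, nRandom = 1000,
    alphaNetwork = 0.05, distanceMode = "auto", alphaEnrich = 0.05,
    ic50Cut = 0, seed = 1L, swapsPerEdge = 10, litGlobals = NULL)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(override)] <- override
  for (f in c("topFraction", "massFraction")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] > 1) {
      stop("config field '", f, "' must lie in (0, 1]")
    }
  }
  for (f in c("alphaNetwork", "alphaEnrich")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1) {
      stop("config field '", f, "' must lie in (0, 1)")
    }
  }
  if (cfg$nRandom < 1) stop("config field 'nRandom' must be >= 1")
  structure(cfg, class = "slnetConfig")
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file whose keys are [pipelineConfig()] fields; must
#'   contain `inputDir` and `outDir`.
#' @return A validated config list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$inputDir) || is.null(y$outDir)) {
    stop("config must name 'inputDir' and 'outDir'")
  }
  extra <- y[setdiff(names(y), c("inputDir", "outDir"))]
  do.call(pipelineConfig, c(list(inputDir = y$inputDir, outDir = y$outDir),
                            extra))
}

.requireInputs <- function(paths, hint) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing required input(s): ", paste(missing, collapse = ", "),
         if (nzchar(hint)) paste0(" (", hint, ")"))
  }
}

#' Run the screening pipeline
#'
#' Orchestrates the stages over plain on-disk TSV artifacts so any stage can
#' be inspected or rerun: `build` constructs the cleaned cancer signaling
#' network, traversal frequencies and candidate pairs; `screen` applies the
#' network/distance/frequency/function screens; `annotate` attaches
#' drug-target records; `validate` runs the three validation channels;
#' `all` chains them; `synth` writes a fresh fixture bundle into
#' `config$outDir` first and then behaves like `all`.
#'
#' @param stage One of `"build"`, `"screen"`, `"annotate"`, `"validate"`,
#'   `"all"`, `"synth"`.
#' @param config A [pipelineConfig()] list.
#' @return Invisibly, a manifest list (config, per-stage row counts, outputs).
#' @export
runPipeline <- function(stage = c("all", "build", "screen", "annotate",
                                  "validate", "synth"),
                        config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "slnetConfig"))
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), counts = list())
  if (stage == "synth") {
    bundle <- synthBundle(seed = config$seed)
    writeFixtureBundle(bundle, dirname(config$networkPath))
    stage <- "all"
  }
  stages <- if (stage == "all") {
    c("build", "screen", "annotate", "validate")
  } else {
    stage
  }
  for (st in stages) {
    manifest <- switch(st,
      build = .stageBuild(config, manifest),
      screen = .stageScreen(config, manifest),
      annotate = .stageAnnotate(config, manifest),
      validate = .stageValidate(config, manifest))
  }
  manifestPath <- file.path(out, "run_manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

.stageBuild <- function(config, manifest) {
  .requireInputs(c(config$networkPath, config$cancerGenesPath), "run synth?")
  net <- readNetwork(config$networkPath, format = config$networkFormat,
                     directed = config$directed)
  cancerGenes(net) <- readGeneList(config$cancerGenesPath)
  net <- cleanNetwork(net, pruneLeaves = config$pruneLeaves)
  if (length(cancerGenes(net)) == 0L) stop("no cancer genes mapped")
  freq <- pathFrequencies(net)
  top <- selectTopFraction(freq, config$topFraction)
  pairs <- candidatePairs(top, cancerGenes(net))
  out <- config$outDir
  el <- igraph::as_edgelist(networkGraph(net))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  writeLines(paste(el[, 1], el[, 2], sep = "\t"),
             file.path(out, "hcsn_edges.tsv"))
  writeLines(sort(cancerGenes(net)), file.path(out, "hcsn_cancer_genes.txt"))
  ftab <- data.frame(gene = names(freq), count = as.integer(freq),
                     stringsAsFactors = FALSE)
  ftab <- ftab[order(-ftab$count, ftab$gene), ]
  writeResults(ftab[, c("gene", "count")], file.path(out, "frequency.tsv"))
  writeLines(top, file.path(out, "top_genes.txt"))
  writeResults(pairs, file.path(out, "candidate_pairs.tsv"))
  manifest$counts$network_nodes <- numNodes(net)
  manifest$counts$network_edges <- numEdges(net)
  manifest$counts$candidate_pairs <- nrow(pairs)
  manifest
}

.stageScreen <- function(config, manifest) {
  out <- config$outDir
  .requireInputs(c(file.path(out, "hcsn_edges.tsv"),
                   file.path(out, "candidate_pairs.tsv"),
                   file.path(out, "frequency.tsv"), config$gmtPath),
                 "run the build stage first")
  net <- readNetwork(file.path(out, "hcsn_edges.tsv"),
                     directed = config$directed)
  cancerGenes(net) <- readGeneList(file.path(out, "hcsn_cancer_genes.txt"))
  pairs <- utils::read.delim(file.path(out, "candidate_pairs.tsv"),
                             stringsAsFactors = FALSE)
  ftab <- utils::read.delim(file.path(out, "frequency.tsv"),
                            stringsAsFactors = FALSE)
  freq <- stats::setNames(as.integer(ftab$count), ftab$gene)
  scored <- scorePairs(net, pairs, nRandom = config$nRandom,
                       seed = config$seed,
                       swapsPerEdge = config$swapsPerEdge)
  writeResults(scored, file.path(out, "scored_pairs.tsv"))
  s1 <- networkScreen(net, scored, alpha = config$alphaNetwork)
  s1 <- distanceScreen(s1, threshold = config$distanceMode,
                       referenceDistances = scored$distance)
  writeResults(s1, file.path(out, "screen1_network_distance.tsv"))
  kept <- cumulativeFrequencyCutoff(freq, config$massFraction)
  s2 <- frequencyScreen(s1, kept)
  writeResults(s2, file.path(out, "screen2_frequency.tsv"))
  collection <- readGMT(config$gmtPath)
  screenGenes <- unique(c(s2$cancer_gene, s2$non_cancer_gene))
  enr <- enrich(screenGenes, collection, background = nodeNames(net))
  writeResults(enr, file.path(out, "enrichment.tsv"))
  s3 <- functionScreen(s2, enr, collection, alpha = config$alphaEnrich)
  writeResults(s3, file.path(out, "final_pairs.tsv"))
  manifest$counts$pairs_scored <- nrow(scored)
  manifest$counts$pairs_network_distance <- nrow(s1)
  manifest$counts$pairs_frequency <- nrow(s2)
  manifest$counts$pairs_final <- nrow(s3)
  manifest
}

.stageAnnotate <- function(config, manifest) {
  out <- config$outDir
  .requireInputs(c(file.path(out, "final_pairs.tsv"),
                   config$drugTargetsPath), "run the screen stage first")
  finalPairs <- utils::read.delim(file.path(out, "final_pairs.tsv"),
                                  stringsAsFactors = FALSE)
  drugTargets <- readTable(config$drugTargetsPath, "drug_targets")
  ann <- annotateTargets(finalPairs, drugTargets)
  writeResults(ann$targets, file.path(out, "targets.tsv"))
  writeLines(ann$unannotated, file.path(out, "unannotated_candidates.txt"))
  manifest$counts$targets_annotated <- nrow(ann$targets)
  manifest$counts$targets_unannotated <- length(ann$unannotated)
  manifest
}

.stageValidate <- function(config, manifest) {
  out <- config$outDir
  .requireInputs(c(file.path(out, "final_pairs.tsv"),
                   file.path(out, "targets.tsv"), config$slReferencePath,
                   config$sensitivityPath, config$literaturePath),
                 "run the annotate stage first")
  finalPairs <- utils::read.delim(file.path(out, "final_pairs.tsv"),
                                  stringsAsFactors = FALSE)
  targets <- utils::read.delim(file.path(out, "targets.tsv"),
                               stringsAsFactors = FALSE, colClasses = "character")
  reference <- readTable(config$slReferencePath, "sl_reference")
  sensitivity <- readTable(config$sensitivityPath, "sensitivity")
  literature <- readTable(config$literaturePath, "literature_counts")
  litGlobals <- config$litGlobals
  if (is.null(litGlobals) && file.exists(config$manifestPath)) {
    mf <- jsonlite::read_json(config$manifestPath, simplifyVector = TRUE)
    litGlobals <- lapply(mf$litGlobals, function(gl) {
      c(M = as.numeric(gl[["M"]]), N = as.numeric(gl[["N"]]))
    })
  }
  if (is.null(litGlobals)) {
    stop("literature globals (M, N per context) not configured")
  }
  refResult <- referenceOverlap(finalPairs, reference)
  sensResult <- sensitivityValidate(targets, sensitivity,
                                    ic50Cut = config$ic50Cut)
  litResult <- literatureValidate(literature, litGlobals)
  report <- compileReport(targets, refResult, sensResult, litResult)
  jsonlite::write_json(
    list(counts = report$counts, tripleValidated = report$tripleValidated,
         referenceOverlap = refResult[c("pairOverlap", "geneOverlap")],
         perTarget = report$perTarget),
    file.path(out, "validation.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  writeResults(report$perTarget, file.path(out, "validation_summary.tsv"))
  manifest$counts$targets_sl_reference <- report$counts$sl_reference
  manifest$counts$targets_sensitivity <- report$counts$sensitivity
  manifest$counts$targets_literature <- report$counts$literature
  manifest$counts$targets_triple <- report$counts$triple
  manifest
}
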