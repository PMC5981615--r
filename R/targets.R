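#' Annotate final non-cancer genes with drug-target information
#'
#' Every distinct non-cancer gene in the final SL pair list that has at least
#' one drug-target record becomes an annotated candidate target; its SL
#' partners are the cancer genes it is paired with in the final list. Genes
#' without any drug-target record are returned separately as unannotated
#' candidates.
#'
#' @param finalPairs Stability-record data.frame surviving all screens.
#' @param drugTargets data.frame from `readTable(..., "drug_targets")`.
#' @return List with elements `targets` (data.frame: `gene`,
#'   `target_accession`, `drugs`, `category`, `sl_partners`, multi-valued
#'   fields `;`-collapsed and sorted) and `unannotated` (character vector).
#' @export
annotateTargets <- function(finalPairs, drugTargets) {
  if (nrow(finalPairs) == 0L) stop("no final SL pairs to annotate")
  genes <- sort(unique(finalPairs$non_cancer_gene))
  annotated <- genes[genes %in% drugTargets$gene]
  rows <- lapply(annotated, function(gn) {
    dt <- drugTargets[drugTargets$gene == gn, , drop = FALSE]
    partners <- sort(unique(
      finalPairs$cancer_gene[finalPairs$non_cancer_gene == gn]))
    data.frame(
      gene = gn,
      target_accession = paste(sort(unique(dt$target_accession)),
                               collapse = ";"),
      drugs = paste(sort(unique(dt$drug)), collapse = ";"),
      category = paste(sort(unique(dt$category)), collapse = ";"),
      sl_partners = paste(partners, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  targets <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), target_accession = character(),
               drugs = character(), category = character(),
               sl_partners = character(), stringsAsFactors = FALSE)
  list(targets = targets, unannotated = setdiff(genes, annotated))
}

# canonical "A|B" keys for unordered pairs
.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Overlap of predicted SL pairs with a reference pair set
#'
#' Both pair sets are compared as canonical unordered pairs. Counts come with
#' percentages rounded half-up to two decimals.
#'
#' @param pairs data.frame of predicted pairs (`cancer_gene`,
#'   `non_cancer_gene`).
#' @param reference data.frame of reference pairs (`gene_a`, `gene_b`,
#'   canonicalized as by [readTable()]).
#' @param referenceGenes Optional character vector of all genes in the
#'   reference resource; defaults to the genes of `reference`.
#' @return List of statistics: `pairOverlap` (count, pct of predicted, pct of
#'   reference), `targetOverlap` (predicted targets with >= 1 of their cancer
#'   partners confirmed in the reference), and `geneOverlap` (genes of the
#'   predicted pairs found among the reference genes).
#' @export
referenceOverlap <- function(pairs, reference, referenceGenes = NULL) {
  if (nrow(reference) == 0L) stop("empty reference pair set")
  predKeys <- unique(.pairKey(pairs$cancer_gene, pairs$non_cancer_gene))
  refKeys <- unique(.pairKey(reference$gene_a, reference$gene_b))
  if (is.null(referenceGenes)) {
    referenceGenes <- unique(c(reference$gene_a, reference$gene_b))
  }
  both <- intersect(predKeys, refKeys)
  targets <- sort(unique(pairs$non_cancer_gene))
  confirmed <- vapply(targets, function(gn) {
    partners <- pairs$cancer_gene[pairs$non_cancer_gene == gn]
    any(.pairKey(gn, partners) %in% refKeys)
  }, logical(1))
  predGenes <- unique(c(pairs$cancer_gene, pairs$non_cancer_gene))
  geneHits <- intersect(predGenes, referenceGenes)
  list(
    pairOverlap = list(
      count = length(both),
      pctOfPredicted = overlapPercentage(length(both), length(predKeys)),
      pctOfReference = overlapPercentage(length(both), length(refKeys))),
    targetOverlap = list(
      genes = targets[confirmed],
      count = sum(confirmed),
      pct = overlapPercentage(sum(confirmed), length(targets))),
    geneOverlap = list(
      count = length(geneHits),
      pct = overlapPercentage(length(geneHits), length(predGenes))))
}

#' Drug-sensitivity validation of annotated targets
#'
#' A target is supported when some cell line carrying a mutation in one of the
#' target's SL cancer partners is highly sensitive (log-IC50 below `ic50Cut`,
#' default 0) to a drug directed at the target. `mode = "target_only"` drops
#' the partner-mutation requirement for comparison.
#'
#' @param targets `targets` data.frame from [annotateTargets()].
#' @param sensitivity data.frame from `readTable(..., "sensitivity")`.
#' @param ic50Cut Log-IC50 threshold (records strictly below support).
#' @param mode `"partner"` (default) or `"target_only"`.
#' @return Character vector of supported target genes.
#' @export
sensitivityValidate <- function(targets, sensitivity, ic50Cut = 0,
                                mode = c("partner", "target_only")) {
  mode <- match.arg(mode)
  if (nrow(targets) == 0L) return(character())
  hits <- sensitivity[sensitivity$log_ic50 < ic50Cut, , drop = FALSE]
  supported <- vapply(seq_len(nrow(targets)), function(i) {
    gn <- targets$gene[i]
    rec <- hits[hits$target_gene == gn, , drop = FALSE]
    if (nrow(rec) == 0L) return(FALSE)
    if (mode == "target_only") return(TRUE)
    partners <- strsplit(targets$sl_partners[i], ";", fixed = TRUE)[[1]]
    any(rec$mutated_cancer_gene %in% partners)
  }, logical(1))
  targets$gene[supported]
}

#' Literature hypergeometric p-value
#'
#' Probability that at least `x` of the `K` studies mentioning a gene are
#' context-relevant (cancer- or SL-related) by chance, given `M` relevant
#' studies among `N` total:
#' \deqn{P = 1 - \sum_{i=0}^{x-1} \binom{M}{i}\binom{N-M}{K-i} /
#'   \binom{N}{K}.}
#' Computed through the hypergeometric upper tail in log space, so it is
#' stable for PubMed-scale counts.
#'
#' @param x Relevant studies mentioning the gene (0 <= x <= K).
#' @param K Studies mentioning the gene.
#' @param M Relevant studies overall (M <= N).
#' @param N Total studies.
#' @return Upper-tail p-value; significance is conventionally `P < 0.05`.
#' @examples
#' literaturePvalue(1, 2, 5, 10)  # 7/9
#' @export
literaturePvalue <- function(x, K, M, N) {
  if (any(x < 0 | x > K | K > N | M > N | M < 0)) {
    stop("counts must satisfy 0 <= x <= K <= N and 0 <= M <= N")
  }
  stats::phyper(x - 1, M, N - M, K, lower.tail = FALSE)
}

#' Literature validation of target genes
#'
#' @param literature data.frame from `readTable(..., "literature_counts")`.
#' @param globals Named list of per-context global counts, e.g.
#'   `list(cancer = c(M = 1e5, N = 1e6), SL = c(M = 1e4, N = 1e6))`.
#' @param alpha Significance level (default 0.05).
#' @return data.frame `gene`, `context`, `p`, `significant`.
#' @export
literatureValidate <- function(literature, globals, alpha = 0.05) {
  p <- vapply(seq_len(nrow(literature)), function(i) {
    ctx <- literature$context[i]
    if (!ctx %in% names(globals)) stop("no globals for context '", ctx, "'")
    gl <- globals[[ctx]]
    literaturePvalue(literature$x[i], literature$K[i], gl[["M"]], gl[["N"]])
  }, numeric(1))
  out <- data.frame(gene = literature$gene, context = literature$context,
                    p = p, significant = p < alpha, stringsAsFactors = FALSE)
  out[order(out$gene, out$context), , drop = FALSE]
}

#' Compile the three-channel validation report
#'
#' Combines the SL-reference, drug-sensitivity and literature channels into a
#' per-target flag table. The literature channel passes when the gene is
#' significant in *both* the cancer and the SL context. Triple-validated
#' targets pass all three channels; the result is invariant to channel order.
#'
#' @param targets `targets` data.frame from [annotateTargets()].
#' @param refResult Result of [referenceOverlap()] on the final pairs.
#' @param sensResult Character vector from [sensitivityValidate()].
#' @param litResult data.frame from [literatureValidate()].
#' @return List: `perTarget` data.frame of flags, `counts` per channel,
#'   `tripleValidated` gene vector.
#' @export
compileReport <- function(targets, refResult, sensResult, litResult) {
  genes <- sort(targets$gene)
  litSig <- function(gn, ctx) {
    row <- litResult$gene == gn & litResult$context == ctx
    any(row & litResult$significant)
  }
  perTarget <- data.frame(
    gene = genes,
    in_sl_reference = genes %in% refResult$targetOverlap$genes,
    sensitivity_supported = genes %in% sensResult,
    literature_cancer = vapply(genes, litSig, logical(1), ctx = "cancer"),
    literature_sl = vapply(genes, litSig, logical(1), ctx = "SL"),
    stringsAsFactors = FALSE)
  perTarget$literature_supported <-
    perTarget$literature_cancer & perTarget$literature_sl
  perTarget$triple_validated <- perTarget$in_sl_reference &
    perTarget$sensitivity_supported & perTarget$literature_supported
  rownames(perTarget) <- NULL
  list(
    perTarget = perTarget,
    counts = list(
      n_targets = length(genes),
      sl_reference = sum(perTarget$in_sl_reference),
      sensitivity = sum(perTarget$sensitivity_supported),
      literature = sum(perTarget$literature_supported),
      triple = sum(perTarget$triple_validated)),
    tripleValidated = perTarget$gene[perTarget$triple_validated])
}
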