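#' Read a signaling network from disk
#'
#' Supports three circulating formats: a tab-separated edge list (two columns,
#' any extra columns such as an interaction type are ignored), Cytoscape SIF
#' (`source <type> target1 [target2 ...]`, fanning out one edge per target;
#' a single-field row declares an isolated node), and GraphML. Symbols are
#' normalized (uppercase, trimmed); duplicate edge rows collapse to one edge.
#'
#' @param path Path to the network file.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @param directed Logical; read as a directed graph. The published screening
#'   semantics are undirected.
#' @return A [SignalingNetwork-class] (no cancer labels yet; see
#'   [cancerGenes<-]).
#' @export
readNetwork <- function(path, format = c("tsv", "sif", "graphml"),
                        directed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(igraph::V(g))
    }
    igraph::V(g)$name <- normalizeSymbols(igraph::V(g)$name)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
    net <- SignalingNetwork(g)
    vlog("read %s: %d nodes, %d edges", path, numNodes(net), numEdges(net))
    return(net)
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty network file: ", path)
  edges <- list(); isolated <- character()
  for (i in seq_along(lines)) {
    f <- if (format == "tsv" || grepl("\t", lines[i])) {
      strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    } else {
      strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    }
    f <- normalizeSymbols(f)
    if (format == "tsv") {
      if (length(f) < 2L || !all(nzchar(f[1:2]))) {
        stop(sprintf("malformed edge row at line %d of %s", lineNo[i], path))
      }
      edges[[length(edges) + 1L]] <- cbind(f[1], f[2])
    } else {                      # SIF
      if (length(f) == 1L && nzchar(f[1])) {
        isolated <- c(isolated, f[1])
      } else if (length(f) >= 3L && all(nzchar(f[c(1, 3:length(f))]))) {
        edges[[length(edges) + 1L]] <- cbind(f[1], f[3:length(f)])
      } else {
        stop(sprintf("malformed SIF row at line %d of %s", lineNo[i], path))
      }
    }
  }
  el <- do.call(rbind, edges)
  nDup <- if (is.null(el)) 0L else sum(duplicated(el))
  g <- if (is.null(el)) {
    igraph::make_empty_graph(0, directed = directed)
  } else {
    igraph::simplify(
      igraph::graph_from_data_frame(as.data.frame(el), directed = directed),
      remove.multiple = TRUE, remove.loops = FALSE)
  }
  isolated <- setdiff(unique(isolated), igraph::V(g)$name)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  net <- SignalingNetwork(g)
  vlog("read %s: %d nodes, %d edges (%d duplicate rows collapsed)",
       path, numNodes(net), numEdges(net), nDup)
  net
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and lines starting with `#` are skipped; symbols are normalized
#' and deduplicated.
#'
#' @param path Path to the list file.
#' @return Character vector of gene symbols (possibly empty, with a warning).
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  out <- unique(normalizeSymbols(x))
  if (length(out) == 0L) warning("gene list is empty: ", path)
  vlog("read %s: %d genes", path, length(out))
  out
}

#' Read a GMT gene-set file
#'
#' Each line: `set_id<TAB>description<TAB>gene1<TAB>gene2...`. Within-set
#' duplicate members are removed; duplicate set IDs are an error.
#'
#' @param path Path to the GMT file.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  sets <- list(); desc <- character()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(trimws(f))]
    if (length(f) < 3L) {
      stop(sprintf("GMT line %d of %s has fewer than 3 fields", i, path))
    }
    id <- trimws(f[1])
    if (id %in% names(sets)) {
      stop(sprintf("duplicate set ID '%s' at line %d of %s", id, i, path))
    }
    sets[[id]] <- unique(normalizeSymbols(f[-(1:2)]))
    desc[id] <- trimws(f[2])
  }
  vlog("read %s: %d gene sets", path, length(sets))
  GeneSetCollection(sets, descriptions = desc)
}

# column contracts per table schema
.schemas <- list(
  drug_targets = list(
    cols = c("gene", "target_accession", "drug", "category"),
    symbolCols = "gene", key = c("gene", "drug")),
  sl_reference = list(
    cols = c("gene_a", "gene_b"),
    symbolCols = c("gene_a", "gene_b"), key = c("gene_a", "gene_b")),
  sensitivity = list(
    cols = c("cell_line", "mutated_cancer_gene", "drug", "target_gene",
             "log_ic50"),
    symbolCols = c("mutated_cancer_gene", "target_gene"),
    key = c("cell_line", "drug", "target_gene")),
  literature_counts = list(
    cols = c("gene", "K", "x", "context"),
    symbolCols = "gene", key = c("gene", "context")))

#' Read a typed pipeline table
#'
#' Reads one of the four companion tables the pipeline consumes, validating
#' its header and row-level invariants:
#' \describe{
#'   \item{drug_targets}{`gene, target_accession, drug, category`;
#'     (gene, drug) rows deduplicated.}
#'   \item{sl_reference}{`gene_a, gene_b`; pairs canonicalized as unordered
#'     (lexicographically sorted) and deduplicated.}
#'   \item{sensitivity}{`cell_line, mutated_cancer_gene, drug, target_gene,
#'     log_ic50`; `log_ic50` must parse to a finite number.}
#'   \item{literature_counts}{`gene, K, x, context`; requires `0 <= x <= K`
#'     and context in \{cancer, SL\}.}
#' }
#'
#' @param path Path to a TSV file with a header row.
#' @param schema One of the four schema names above.
#' @return data.frame of typed, symbol-normalized records.
#' @export
readTable <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- .schemas[[schema]]
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(sc$cols, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  df <- df[, sc$cols, drop = FALSE]
  for (cc in sc$symbolCols) df[[cc]] <- normalizeSymbols(df[[cc]])
  if (schema == "sensitivity") {
    v <- suppressWarnings(as.numeric(df$log_ic50))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric log_ic50 at data line %d of %s", bad[1], path))
    }
    df$log_ic50 <- v
  }
  if (schema == "literature_counts") {
    df$K <- as.integer(df$K); df$x <- as.integer(df$x)
    bad <- which(is.na(df$K) | is.na(df$x) | df$x < 0 | df$x > df$K)
    if (length(bad)) {
      stop(sprintf("invalid counts (need 0 <= x <= K) at data line %d of %s",
                   bad[1], path))
    }
    if (!all(df$context %in% c("cancer", "SL"))) {
      stop("literature context must be 'cancer' or 'SL'")
    }
  }
  if (schema == "sl_reference") {
    ab <- cbind(pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b))
    df$gene_a <- ab[, 1]; df$gene_b <- ab[, 2]
  }
  nBefore <- nrow(df)
  df <- df[!duplicated(df[, sc$key, drop = FALSE]), , drop = FALSE]
  if (nrow(df) < nBefore) {
    vlog("%s: %d duplicate rows collapsed", path, nBefore - nrow(df))
  }
  df <- df[do.call(order, df[, sc$key, drop = FALSE]), , drop = FALSE]
  rownames(df) <- NULL
  vlog("read %s: %d %s records", path, nrow(df), schema)
  df
}

#' Write pipeline records deterministically
#'
#' Rows are sorted by the leading columns and written either as TSV (numeric
#' columns rendered with full round-trip precision) or JSON. Writing the same
#' records twice yields byte-identical files.
#'
#' @param records data.frame of pipeline output.
#' @param path Output file path; parent directories are created.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
writeResults <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  stopifnot(is.data.frame(records))
  if (nrow(records) > 1L) {
    keyCols <- seq_len(min(2L, ncol(records)))
    records <- records[do.call(order, records[, keyCols, drop = FALSE]), ,
                       drop = FALSE]
  }
  rownames(records) <- NULL
  if (format == "tsv") {
    utils::write.table(.formatNumericCols(records), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
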