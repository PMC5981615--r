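test_that("TSV edge lists are read with normalization and duplicate collapse", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tB", "B\tc", " A\tb"), f)
  net <- readNetwork(f)
  expect_equal(sort(nodeNames(net)), c("A", "B", "C"))
  expect_equal(numEdges(net), 2L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "A\t"), bad)
  expect_error(readNetwork(bad), "line 2")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(readNetwork(empty), "empty")
})

test_that("SIF rows fan out one edge per target and singletons are isolated", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A pp B C", "D"), f)
  net <- readNetwork(f, format = "sif")
  expect_equal(sort(nodeNames(net)), c("A", "B", "C", "D"))
  expect_equal(numEdges(net), 2L)
  expect_equal(pairDistance(net, "A", "C"), 1)
  expect_equal(pairDistance(net, "A", "D"), Inf)

  bad <- withr::local_tempfile(fileext = ".sif")
  writeLines("A pp", bad)
  expect_error(readNetwork(bad, format = "sif"), "line 1")
})

test_that("GraphML round-trips a small network", {
  g <- igraph::make_ring(4)
  igraph::V(g)$name <- c("A", "B", "C", "D")
  f <- withr::local_tempfile(fileext = ".graphml")
  igraph::write_graph(g, f, format = "graphml")
  net <- readNetwork(f, format = "graphml")
  expect_equal(sort(nodeNames(net)), c("A", "B", "C", "D"))
  expect_equal(numEdges(net), 4L)
})

test_that("gene lists are deduplicated after normalization, comments skipped", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("tp53", "TP53", "KRAS"), f)
  expect_equal(sort(readGeneList(f)), c("KRAS", "TP53"))

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#header", "MYC"), f2)
  expect_equal(readGeneList(f2), "MYC")

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines("", f3)
  expect_warning(out <- readGeneList(f3), "empty")
  expect_length(out, 0)
})

test_that("GMT parsing enforces field counts, unique IDs, member dedup", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tA\tB", "P2\tdesc\tA\tA"), f)
  gsc <- readGMT(f)
  expect_equal(geneSets(gsc)$P1, c("A", "B"))
  expect_equal(geneSets(gsc)$P2, "A")

  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\td\tA\tB", "P1\td\tC\tD"), dup)
  expect_error(readGMT(dup), "duplicate set ID")

  short <- withr::local_tempfile(fileext = ".gmt")
  writeLines("P1\tdesc", short)
  expect_error(readGMT(short), "fewer than 3")
})

test_that("typed tables validate schemas and canonicalize SL pairs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "A\tB", "B\tA"), f)
  ref <- readTable(f, "sl_reference")
  expect_equal(nrow(ref), 1L)
  expect_equal(ref$gene_a, "A")

  s <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_line\tmutated_cancer_gene\tdrug\ttarget_gene\tlog_ic50",
               "CL1\tKRAS\tD1\tG1\tNA"), s)
  expect_error(readTable(s, "sensitivity"), "log_ic50")

  l <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tK\tx\tcontext", "G1\t3\t5\tcancer"), l)
  expect_error(readTable(l, "literature_counts"), "x <= K")

  m <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tdrug", "G1\tD1"), m)
  expect_error(readTable(m, "drug_targets"), "target_accession")
})

test_that("writeResults is deterministic and round-trips every schema", {
  b <- smallBundle()
  dir <- withr::local_tempdir()
  tables <- list(drug_targets = b@drugTargets, sl_reference = b@slReference,
                 sensitivity = b@sensitivity, literature_counts = b@literature)
  for (schema in names(tables)) {
    p1 <- file.path(dir, paste0(schema, "_1.tsv"))
    p2 <- file.path(dir, paste0(schema, "_2.tsv"))
    writeResults(tables[[schema]], p1)
    writeResults(tables[[schema]], p2)
    expect_identical(readLines(p1), readLines(p2))
    back <- readTable(p1, schema)
    orig <- readTable(p1, schema)  # already normalized on disk
    expect_identical(back, orig)
    # write -> read -> write is a fixed point
    p3 <- file.path(dir, paste0(schema, "_3.tsv"))
    writeResults(back, p3)
    expect_identical(readTable(p3, schema), back)
  }
  # stability records survive a TSV round trip with full numeric precision
  sc <- stabilityScore(b@network, b@plantedPairs$cancer_gene[1],
                       b@plantedPairs$non_cancer_gene[1])
  p <- file.path(dir, "records.tsv")
  writeResults(sc, p)
  back <- utils::read.delim(p, stringsAsFactors = FALSE)
  expect_equal(back$S, sc$S, tolerance = 1e-15)
  expect_equal(back$Dmn, sc$Dmn, tolerance = 1e-15)
  # empty records yield a header-only file
  writeResults(sc[0, ], file.path(dir, "empty.tsv"))
  expect_length(readLines(file.path(dir, "empty.tsv")), 1L)
})

test_that("symbol normalization is idempotent", {
  x <- c(" tp53", "KRAS ", "myc")
  expect_identical(normalizeSymbols(normalizeSymbols(x)), normalizeSymbols(x))
})
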