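write_toy_contacts <- function(path, extra_score = FALSE, bad_prob = FALSE) {
  header <- c("Gene1", "Chr1", "Start1", "End1", "Gene2", "Chr2",
              "Start2", "End2", "Weight", "Probability")
  if (extra_score) header <- c(header, "score")
  rows <- list(
    c("GA", "chr1", "0", "100", "GB", "chr1", "200", "300", "3", "0.8"),
    c("GA", "chr1", "0", "100", "GC", "chr2", "50", "150", "2",
      if (bad_prob) "1.5" else "0.5"),
    c("GB", "chr1", "200", "300", "GC", "chr2", "50", "150", "1", "0.9"))
  if (extra_score) rows <- lapply(seq_along(rows), function(i)
    c(rows[[i]], sprintf("%.1f", i / 2)))
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

test_that("contact tables parse with extra columns carried as properties", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_toy_contacts(f, extra_score = TRUE)
  rec <- parse_contact_table(f)
  expect_equal(nrow(rec), 3L)
  expect_equal(attr(rec, "extra_cols"), "score")
  expect_equal(rec$score, c(0.5, 1.0, 1.5))
  s <- store_from_records(rec, "e1")
  df <- contact_table(s)
  expect_equal(vapply(df$properties, `[[`, numeric(1), "score"),
               c(0.5, 1.0, 1.5))
})

test_that("contact-table validation reports the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_toy_contacts(f, bad_prob = TRUE)
  expect_error(parse_contact_table(f), "line 3")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  txt <- readLines(write_toy_contacts(f2))
  writeLines(sub("\tProbability", "\tProb", txt), f2)
  expect_error(parse_contact_table(f2), "Probability")
  # a column-mapping rescues the variant dialect
  rec <- parse_contact_table(f2, col_map = c(Probability = "Prob"))
  expect_equal(nrow(rec), 3L)
})

test_that("BED parsing respects 0-based half-open intervals and ignores strand", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t500\tGENE1\t0\t+",
               "chr2\t0\t250\tGENE2\t0\t-"), f)
  genes <- parse_gene_bed(f)
  expect_equal(nrow(genes), 2L)
  expect_equal(genes$start, c(100, 0))
  expect_false("strand" %in% names(genes))
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t500\t100\tBAD", f2)
  expect_error(parse_gene_bed(f2), "line 1")
  f3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t10\tDUP", "chr1\t5\t20\tDUP"), f3)
  expect_error(parse_gene_bed(f3), "DUP")
  f4 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t1\t10", f4)
  expect_error(parse_gene_bed(f4), "BED3\\+1")
})

test_that("binned matrices project onto gene pairs by overlap sums", {
  bins <- data.frame(chromosome = c("chr1", "chr1", "chr1"),
                     start = c(0, 100, 200), end = c(100, 200, 300))
  genes <- data.frame(symbol = c("GA", "GB"), chromosome = "chr1",
                      start = c(10, 210), end = c(90, 290),
                      stringsAsFactors = FALSE)
  X <- matrix(0, 3, 3)
  X[1, 3] <- X[3, 1] <- 5
  rec <- matrix_to_contacts(X, bins, genes)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$Weight, 5)
  expect_equal(rec$Probability, 1.0)
  expect_equal(rec$source, "matrix")
  expect_equal(nrow(matrix_to_contacts(X, bins, genes, min_reads = 6)), 0L)
  # a gene spanning two bins accumulates both bins' counts
  genes2 <- data.frame(symbol = c("GA", "GB"), chromosome = "chr1",
                       start = c(10, 210), end = c(190, 290),
                       stringsAsFactors = FALSE)
  X2 <- matrix(0, 3, 3)
  X2[1, 3] <- X2[3, 1] <- 2
  X2[2, 3] <- X2[3, 2] <- 3
  rec2 <- matrix_to_contacts(X2, bins, genes2)
  expect_equal(rec2$Weight, 5)
  expect_error(matrix_to_contacts(matrix(c(0, 1, 2, 0), 2, 2),
                                  bins[1:2, ], genes), "symmetric")
  far <- data.frame(symbol = "GZ", chromosome = "chr9",
                    start = 0, end = 50, stringsAsFactors = FALSE)
  expect_warning(res <- matrix_to_contacts(X, bins, far), "no gene")
  expect_equal(nrow(res), 0L)
})

test_that("matrix conversion is invariant to bin ordering", {
  bins <- data.frame(chromosome = "chr1",
                     start = c(0, 100, 200, 300),
                     end = c(100, 200, 300, 400))
  genes <- data.frame(symbol = c("GA", "GB", "GC"), chromosome = "chr1",
                      start = c(0, 150, 310), end = c(120, 260, 390),
                      stringsAsFactors = FALSE)
  set.seed(42)
  X <- matrix(sample(0:9, 16, replace = TRUE), 4, 4)
  X <- X + t(X); diag(X) <- 0
  base <- matrix_to_contacts(X, bins, genes)
  perm <- c(3, 1, 4, 2)
  expect_equal(matrix_to_contacts(X[perm, perm], bins[perm, ], genes),
               base)
})

test_that("bulk-import CSV export has the documented headers and relationship type", {
  s <- make_three_experiment_store()
  dir <- withr::local_tempdir()
  paths <- write_neo4j_import(s, "T0_Rep1", dir)
  edges <- readLines(paths[["edges"]])
  expect_equal(edges[1],
               ":START_ID,:END_ID,:TYPE,weight:int,probability:float")
  expect_equal(length(edges), 2L)
  expect_match(edges[2], "^AADACL3,AADACL4,T0_REP1,3,0.8$")
  genes <- readLines(paths[["genes"]])
  expect_equal(genes[1], "symbol:ID,chromosome,start:int,end:int")
  expect_equal(length(genes), 3L)
  expt <- readLines(paths[["experiment"]])
  expect_equal(expt, c("name,n_genes,n_edges", "T0_Rep1,2,1"))
  register_experiment(s, "empty_exp")
  p2 <- write_neo4j_import(s, "empty_exp", dir)
  expect_equal(length(readLines(p2[["edges"]])), 1L)
  expect_error(write_neo4j_import(s, "nope", dir), "unknown experiment")
})

test_that("GraphML export/import round trips graphs with edge properties", {
  g <- random_contact_graph(12, 0.3, seed = 9)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(g, f)
  g2 <- import_graphml(f)
  expect_same_graph(g, g2)
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  f2 <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(empty, f2)
  expect_equal(igraph::vcount(import_graphml(f2)), 0L)
})

test_that("gene-value tables read as named reals, rejecting duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,value", "GA,1.5", "GB,-2.25", "GC,0"), f)
  v <- read_gene_values(f)
  expect_equal(v, c(GA = 1.5, GB = -2.25, GC = 0))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,value", "GA,1", "GA,2"), f2)
  expect_error(read_gene_values(f2), "duplicate gene 'GA'")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,score", "GA,1"), f3)
  expect_error(read_gene_values(f3), "gene.*value")
})

test_that("contact TSV written by the package parses and re-ingests identically", {
  ex <- generate_experiment(synth_config(n_genes = 50, seed = 21))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_table(ex$contacts, f)
  rec <- parse_contact_table(f)
  s1 <- store_from_records(ex$contacts, "e")
  s2 <- store_from_records(rec, "e")
  expect_equal(contact_table(s1)[, 1:5], contact_table(s2)[, 1:5])
})
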