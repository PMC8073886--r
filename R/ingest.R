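#' Parse a gene-pair contact table
#'
#' Reads the package's canonical contact TSV dialect: a header line with
#' the mandatory columns `Gene1 Chr1 Start1 End1 Gene2 Chr2 Start2 End2
#' Weight Probability`, tab-separated, one contact per line. Any extra
#' columns are preserved verbatim as per-edge properties. Variant inputs
#' can be adapted with `col_map`, a named character vector mapping
#' canonical names to the file's actual column names, e.g.
#' `c(Weight = "reads")`.
#'
#' @param path path to the TSV file.
#' @param col_map optional named character vector renaming file columns
#'   to the canonical ones.
#' @return a data.frame of contact records (one per data line, original
#'   line numbers in attribute `line`), canonical columns first, extra
#'   columns after; attribute `extra_cols` lists the extras.
#' @export
parse_contact_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) stopf("contact table '%s' does not exist", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      idx <- match(col_map[[canon]], names(df))
      if (is.na(idx))
        stopf("col_map: column '%s' not found in %s", col_map[[canon]], path)
      names(df)[idx] <- canon
    }
  }
  mandatory <- c("Gene1", "Chr1", "Start1", "End1",
                 "Gene2", "Chr2", "Start2", "End2",
                 "Weight", "Probability")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stopf("contact table '%s' is missing mandatory column(s): %s",
          path, paste(missing, collapse = ", "))
  lines <- seq_len(nrow(df)) + 1L  # +1 for the header
  for (col in c("Start1", "End1", "Start2", "End2", "Weight",
                "Probability")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stopf("non-numeric %s on line %d of %s", col, lines[bad[[1L]]], path)
    df[[col]] <- v
  }
  bad_w <- which(df$Weight < 1 | df$Weight != round(df$Weight))
  if (length(bad_w))
    stopf("invalid Weight %s on line %d of %s (positive integer required)",
          format(df$Weight[bad_w[[1L]]]), lines[bad_w[[1L]]], path)
  bad_p <- which(df$Probability <= 0 | df$Probability > 1)
  if (length(bad_p))
    stopf("invalid Probability %s on line %d of %s (must be in (0,1])",
          format(df$Probability[bad_p[[1L]]]), lines[bad_p[[1L]]], path)
  extra <- setdiff(names(df), mandatory)
  df <- df[, c(mandatory, extra), drop = FALSE]
  attr(df, "line") <- lines
  attr(df, "extra_cols") <- extra
  df
}

#' Parse gene annotation in BED format
#'
#' Accepts BED3+1 or wider (chrom, start, end, name, ...); columns past
#' the fourth — including strand — are ignored: contacts encode spatial
#' proximity, for which strand is irrelevant. Coordinates are 0-based
#' half-open, as in BED.
#'
#' @param path path to a (headerless) BED file.
#' @return data.frame with columns `symbol`, `chromosome`, `start`,
#'   `end`.
#' @export
parse_gene_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file '%s' does not exist", path)
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 4L)
    stopf("'%s': BED3+1 required (chrom, start, end, name)", path)
  out <- data.frame(symbol = as.character(df[[4L]]),
                    chromosome = as.character(df[[1L]]),
                    start = suppressWarnings(as.numeric(df[[2L]])),
                    end = suppressWarnings(as.numeric(df[[3L]])),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad))
    stopf("malformed coordinates on line %d of %s", bad[[1L]], path)
  bad <- which(out$start >= out$end)
  if (length(bad))
    stopf("start >= end on line %d of %s (gene '%s')", bad[[1L]], path,
          out$symbol[bad[[1L]]])
  dup <- duplicated(out$symbol)
  if (any(dup)) {
    full <- !duplicated(out[, c("symbol", "chromosome", "start", "end")])
    if (any(dup & full))
      stopf("duplicate gene name '%s' with a different interval in %s",
            out$symbol[which(dup & full)[[1L]]], path)
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Load parsed contact records into a store
#'
#' Upserts both genes of every record and inserts the contact under the
#' given experiment. Extra columns of the record table become edge
#' properties. Duplicate pairs aggregate per [add_contact()].
#'
#' @param store a [contact_store()].
#' @param records a contact-record data.frame from
#'   [parse_contact_table()], [matrix_to_contacts()] or the synthetic
#'   generators.
#' @param experiment experiment label for every record.
#' @return the store, invisibly.
#' @export
ingest_contacts <- function(store, records, experiment) {
  stopifnot(inherits(store, "contact_store"))
  extra <- attr(records, "extra_cols")
  if (is.null(extra))
    extra <- setdiff(names(records),
                     c("Gene1", "Chr1", "Start1", "End1", "Gene2", "Chr2",
                       "Start2", "End2", "Weight", "Probability"))
  register_experiment(store, experiment)
  for (i in seq_len(nrow(records))) {
    upsert_gene(store, records$Gene1[[i]], records$Chr1[[i]],
                records$Start1[[i]], records$End1[[i]])
    upsert_gene(store, records$Gene2[[i]], records$Chr2[[i]],
                records$Start2[[i]], records$End2[[i]])
    props <- if (length(extra)) as.list(records[i, extra, drop = FALSE])
             else list()
    add_contact(store, experiment, records$Gene1[[i]], records$Gene2[[i]],
                weight = records$Weight[[i]],
                probability = records$Probability[[i]],
                properties = props)
  }
  invisible(store)
}

#' Convert a binned contact matrix to gene-pair contact records
#'
#' Projects a symmetric binned read-count matrix onto a gene universe:
#' for each gene pair (g, h), the contact weight is the sum of matrix
#' entries over unordered bin pairs \{i, j\}, i != j, where bin i
#' overlaps g and bin j overlaps h (each bin pair counted once). Records
#' below `min_reads` are dropped. Matrices carry no edge probability, so
#' every record gets probability 1.0 and the property `source=matrix`,
#' letting probability-weighted analyses degrade gracefully.
#'
#' @param counts square symmetric numeric matrix of read-pair counts.
#' @param bins data.frame (chromosome, start, end), one row per matrix
#'   row/column, 0-based half-open, non-overlapping within a chromosome.
#' @param genes gene annotation data.frame as from [parse_gene_bed()].
#' @param min_reads minimum summed read count to keep a record
#'   (default 1).
#' @return a contact-record data.frame in the canonical dialect with an
#'   extra `source` column.
#' @export
matrix_to_contacts <- function(counts, bins, genes, min_reads = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stopf("contact matrix must be square, got %d x %d",
          nrow(counts), ncol(counts))
  if (nrow(bins) != nrow(counts))
    stopf("bin table has %d rows but matrix is %d x %d",
          nrow(bins), nrow(counts), ncol(counts))
  if (!isTRUE(all.equal(counts, t(counts), check.attributes = FALSE)))
    stopf("contact matrix is not symmetric")
  assert_scalar_number(min_reads, "min_reads", min = 1)
  # bins overlapping each gene (half-open interval intersection)
  gene_bins <- lapply(seq_len(nrow(genes)), function(k) {
    which(bins$chromosome == genes$chromosome[[k]] &
            bins$start < genes$end[[k]] & bins$end > genes$start[[k]])
  })
  covered <- which(lengths(gene_bins) > 0L)
  if (!length(covered)) {
    warning("no gene overlaps any bin; returning zero contact records")
    return(empty_contact_records())
  }
  out <- list()
  for (ai in seq_along(covered)) {
    for (bi in seq_along(covered)) {
      if (bi <= ai) next
      g <- covered[[ai]]; h <- covered[[bi]]
      bg <- gene_bins[[g]]; bh <- gene_bins[[h]]
      # unordered bin pairs with one bin on each gene, i != j, once each
      pairs <- unique(t(apply(expand.grid(bg, bh), 1L, sort)))
      pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
      if (!nrow(pairs)) next
      w <- sum(counts[pairs])
      if (w < min_reads) next
      out[[length(out) + 1L]] <- data.frame(
        Gene1 = genes$symbol[[g]], Chr1 = genes$chromosome[[g]],
        Start1 = genes$start[[g]], End1 = genes$end[[g]],
        Gene2 = genes$symbol[[h]], Chr2 = genes$chromosome[[h]],
        Start2 = genes$start[[h]], End2 = genes$end[[h]],
        Weight = w, Probability = 1.0, source = "matrix",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_contact_records())
  res <- do.call(rbind, out)
  res <- res[order(res$Gene1, res$Gene2), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "extra_cols") <- "source"
  res
}

empty_contact_records <- function() {
  df <- data.frame(Gene1 = character(), Chr1 = character(),
                   Start1 = numeric(), End1 = numeric(),
                   Gene2 = character(), Chr2 = character(),
                   Start2 = numeric(), End2 = numeric(),
                   Weight = numeric(), Probability = numeric(),
                   source = character(), stringsAsFactors = FALSE)
  attr(df, "extra_cols") <- "source"
  df
}

#' Write one experiment as graph-database bulk-import CSV
#'
#' Emits the three-file CSV layout consumed by Neo4j's offline bulk
#' importer (`neo4j-admin import`):
#' \describe{
#'   \item{`<exp>_experiment.csv`}{header `name,n_genes,n_edges`; one
#'     row of experiment statistics.}
#'   \item{`<exp>_genes.csv`}{header
#'     `symbol:ID,chromosome,start:int,end:int`; one row per gene
#'     incident to the experiment's edges, keyed by symbol.}
#'   \item{`<exp>_edges.csv`}{header
#'     `:START_ID,:END_ID,:TYPE,weight:int,probability:float` plus one
#'     column per extra property; the relationship `:TYPE` is the
#'     experiment name uppercased with non-alphanumerics mapped to
#'     underscores (e.g. `T0_Rep1` becomes `T0_REP1`).}
#' }
#'
#' @param store a [contact_store()].
#' @param experiment experiment name.
#' @param outdir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_neo4j_import <- function(store, experiment, outdir) {
  stopifnot(inherits(store, "contact_store"))
  stats <- experiment_stats(store, experiment)  # errors if unknown
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  safe <- gsub("[^A-Za-z0-9]", "_", experiment)
  rel_type <- toupper(safe)
  paths <- c(
    experiment = file.path(outdir, paste0(safe, "_experiment.csv")),
    genes = file.path(outdir, paste0(safe, "_genes.csv")),
    edges = file.path(outdir, paste0(safe, "_edges.csv")))
  writeLines(c("name,n_genes,n_edges",
               paste(experiment, stats$n_genes, stats$n_edges, sep = ",")),
             paths[["experiment"]])
  df <- contact_table(store, experiments = experiment)
  syms <- sort(unique(c(df$gene_a, df$gene_b)))
  gene_rows <- vapply(syms, function(s) {
    gi <- store$genes[[s]]
    paste(gi$symbol, gi$chromosome, format(gi$start, scientific = FALSE),
          format(gi$end, scientific = FALSE), sep = ",")
  }, character(1L))
  writeLines(c("symbol:ID,chromosome,start:int,end:int", gene_rows),
             paths[["genes"]])
  prop_names <- unique(unlist(lapply(df$properties, names)))
  header <- paste(c(":START_ID", ":END_ID", ":TYPE", "weight:int",
                    "probability:float", prop_names), collapse = ",")
  edge_rows <- vapply(seq_len(nrow(df)), function(i) {
    extras <- vapply(prop_names, function(p) {
      v <- df$properties[[i]][[p]]
      if (is.null(v)) "" else as.character(v)
    }, character(1L))
    paste(c(df$gene_a[[i]], df$gene_b[[i]], rel_type,
            format(df$weight[[i]], scientific = FALSE),
            format(df$probability[[i]], scientific = FALSE), extras),
          collapse = ",")
  }, character(1L))
  writeLines(c(header, edge_rows), paths[["edges"]])
  invisible(paths)
}

#' GraphML export / import of a subgraph
#'
#' Thin wrappers over igraph's GraphML reader/writer: gene symbols are
#' stored in the `name` vertex attribute, `weight` and `probability`
#' (and any extra properties) as edge attributes, so
#' `import_graphml(export_graphml(g))` preserves the graph and its edge
#' properties.
#'
#' @param subgraph an igraph object, e.g. from [experiment_subgraph()].
#' @param path file path.
#' @return `export_graphml`: `path`, invisibly. `import_graphml`: an
#'   igraph object.
#' @export
export_graphml <- function(subgraph, path) {
  stopifnot(inherits(subgraph, "igraph"))
  igraph::write_graph(subgraph, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
import_graphml <- function(path) {
  if (!file.exists(path)) stopf("GraphML file '%s' does not exist", path)
  g <- igraph::read_graph(path, format = "graphml")
  igraph::as_undirected(g, mode = "each")
}

#' Read a gene-value overlay table
#'
#' Reads a two-column CSV with header `gene,value` (expression log fold
#' changes, methylation differences, ...). Values are real and may be
#' negative; duplicate genes are an error.
#'
#' @param path CSV path.
#' @return named numeric vector (names are gene symbols).
#' @export
read_gene_values <- function(path) {
  if (!file.exists(path)) stopf("gene-value file '%s' does not exist", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("gene", "value") %in% names(df)))
    stopf("'%s' must have header columns 'gene' and 'value'", path)
  v <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(v) & !is.na(df$value))
  if (length(bad))
    stopf("non-numeric value on line %d of %s", bad[[1L]] + 1L, path)
  dup <- which(duplicated(df$gene))
  if (length(dup))
    stopf("duplicate gene '%s' in %s", df$gene[dup[[1L]]], path)
  stats::setNames(v, df$gene)
}

#' Write a contact-record table in the canonical TSV dialect
#'
#' @param records contact-record data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(records, path) {
  records <- as.data.frame(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
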