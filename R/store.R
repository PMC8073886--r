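#' Create an empty multi-experiment contact store
#'
#' The store is the package's central container: a property graph whose
#' vertices are genes (stored exactly once, keyed by symbol) and whose
#' edges are Hi-C contacts between gene pairs, partitioned by experiment
#' label. It mirrors the data model of a labelled-property graph
#' database: one node per gene regardless of how many experiments touch
#' it, one relationship per (experiment, unordered gene pair).
#'
#' The store has reference semantics: [upsert_gene()] and
#' [add_contact()] mutate it in place and return the inserted record.
#'
#' @param strict logical; when `TRUE`, [add_contact()] refuses contacts
#'   for experiments that have not been registered with
#'   [register_experiment()]. Default `FALSE`: experiments auto-register
#'   on first use, which is convenient during ingestion.
#' @return an object of class `contact_store`.
#' @examples
#' store <- contact_store()
#' upsert_gene(store, "AADACL3", "chr1", 12776118, 12788726)
#' upsert_gene(store, "AADACL4", "chr1", 12704565, 12727097)
#' add_contact(store, "T0_Rep1", "AADACL3", "AADACL4", weight = 3,
#'             probability = 0.8)
#' store
#' @export
contact_store <- function(strict = FALSE) {
  store <- new.env(parent = emptyenv())
  store$genes <- new.env(parent = emptyenv())
  store$edges <- new.env(parent = emptyenv())
  store$experiments <- new.env(parent = emptyenv())
  store$strict <- isTRUE(strict)
  class(store) <- "contact_store"
  store
}

#' @export
print.contact_store <- function(x, ...) {
  cat(sprintf("<contact_store> %d genes, %d contacts, %d experiments\n",
              length(ls(x$genes)), length(ls(x$edges)),
              length(ls(x$experiments))))
  for (e in experiment_names(x)) {
    s <- experiment_stats(x, e)
    cat(sprintf("  %s: %d genes, %d edges\n", e, s$n_genes, s$n_edges))
  }
  invisible(x)
}

#' Insert a gene node, or return the existing one
#'
#' A gene node is created only once: re-upserting an existing symbol
#' with the same coordinates is a no-op that returns the stored record.
#' Re-upserting with *different* coordinates is a hard error (duplicate
#' symbols on different loci are never silently merged). Coordinates are
#' 0-based half-open (BED convention).
#'
#' @param store a [contact_store()].
#' @param symbol gene symbol; the unique node key.
#' @param chromosome chromosome label (any string, e.g. `"chr1"`).
#' @param start,end 0-based half-open interval; `start < end` required.
#' @return the gene record, invisibly: a list with fields `symbol`,
#'   `chromosome`, `start`, `end`.
#' @export
upsert_gene <- function(store, symbol, chromosome, start, end) {
  stopifnot(inherits(store, "contact_store"))
  assert_string(symbol, "symbol")
  assert_string(chromosome, "chromosome")
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end)
    stopf("invalid interval for gene '%s': [%s, %s) requires 0 <= start < end",
          symbol, format(start), format(end))
  existing <- store$genes[[symbol]]
  if (!is.null(existing)) {
    if (existing$chromosome != chromosome ||
        existing$start != start || existing$end != end)
      stopf(paste0("gene '%s' already stored at %s:[%s, %s); conflicting ",
                   "interval %s:[%s, %s) refused"),
            symbol, existing$chromosome, format(existing$start),
            format(existing$end), chromosome, format(start), format(end))
    return(invisible(existing))
  }
  rec <- list(symbol = symbol, chromosome = chromosome,
              start = start, end = end)
  store$genes[[symbol]] <- rec
  invisible(rec)
}

#' Register an experiment label
#'
#' @param store a [contact_store()].
#' @param name experiment name (non-empty, unique).
#' @return the name, invisibly.
#' @export
register_experiment <- function(store, name) {
  stopifnot(inherits(store, "contact_store"))
  assert_string(name, "name")
  store$experiments[[name]] <- TRUE
  invisible(name)
}

#' Add (or aggregate into) a contact edge
#'
#' Inserts an undirected contact between two distinct genes under one
#' experiment. If the unordered pair already has a contact in that
#' experiment, the supporting read counts are summed (reads are additive
#' evidence), the probability is replaced by the maximum of the two, and
#' extra properties are merged with the newer value winning. Input edge
#' direction, if any, is dropped: the store is undirected throughout.
#'
#' @param store a [contact_store()].
#' @param experiment experiment name. Unknown names auto-register unless
#'   the store was created with `strict = TRUE`.
#' @param gene_a,gene_b symbols of two *existing, distinct* genes.
#' @param weight supporting read count, integer `>= 1`.
#' @param probability contact probability in `(0, 1]`.
#' @param properties optional named list of extra scalar edge
#'   properties.
#' @return the stored edge record, invisibly.
#' @export
add_contact <- function(store, experiment, gene_a, gene_b,
                        weight = 1L, probability = 1.0,
                        properties = list()) {
  stopifnot(inherits(store, "contact_store"))
  assert_string(experiment, "experiment")
  assert_string(gene_a, "gene_a")
  assert_string(gene_b, "gene_b")
  if (gene_a == gene_b)
    stopf("self-contact refused: gene '%s' paired with itself", gene_a)
  for (g in c(gene_a, gene_b))
    if (is.null(store$genes[[g]]))
      stopf("unknown gene '%s': upsert_gene() it before adding contacts", g)
  assert_scalar_number(weight, "weight", min = 1)
  if (weight != round(weight))
    stopf("'weight' must be an integer read count, got %s", format(weight))
  assert_scalar_number(probability, "probability", min = 0, max = 1,
                       closed_min = FALSE)
  if (is.null(store$experiments[[experiment]])) {
    if (store$strict)
      stopf("unknown experiment '%s' (strict store; register it first)",
            experiment)
    register_experiment(store, experiment)
  }
  if (length(properties) &&
      (is.null(names(properties)) || any(!nzchar(names(properties)))))
    stopf("'properties' must be a fully named list")
  key <- edge_key(experiment, gene_a, gene_b)
  pair <- sort(c(gene_a, gene_b))
  existing <- store$edges[[key]]
  if (!is.null(existing)) {
    existing$weight <- existing$weight + weight
    existing$probability <- max(existing$probability, probability)
    existing$properties <- utils::modifyList(existing$properties,
                                             as.list(properties))
    store$edges[[key]] <- existing
    return(invisible(existing))
  }
  rec <- list(experiment = experiment, gene_a = pair[[1L]],
              gene_b = pair[[2L]], weight = as.numeric(weight),
              probability = probability, properties = as.list(properties))
  store$edges[[key]] <- rec
  invisible(rec)
}

#' @rdname store_accessors
#' @export
gene_symbols <- function(store) {
  stopifnot(inherits(store, "contact_store"))
  sort(ls(store$genes))
}

#' @rdname store_accessors
#' @export
gene_info <- function(store, symbol) {
  stopifnot(inherits(store, "contact_store"))
  rec <- store$genes[[symbol]]
  if (is.null(rec)) stopf("unknown gene '%s'", symbol)
  rec
}

#' Store accessors
#'
#' Small read-only views of a [contact_store()]: the sorted gene symbol
#' universe, a single gene record, the registered experiment names, and
#' per-experiment statistics recomputed from the store contents (never
#' cached, so they are consistent by construction).
#'
#' @param store a [contact_store()].
#' @param symbol,name gene symbol / experiment name.
#' @name store_accessors
#' @export
experiment_names <- function(store) {
  stopifnot(inherits(store, "contact_store"))
  sort(ls(store$experiments))
}

#' @rdname store_accessors
#' @export
experiment_stats <- function(store, name) {
  stopifnot(inherits(store, "contact_store"))
  if (is.null(store$experiments[[name]]))
    stopf("unknown experiment '%s'; available: %s", name,
          paste(experiment_names(store), collapse = ", "))
  df <- contact_table(store, experiments = name)
  list(name = name, n_genes = length(unique(c(df$gene_a, df$gene_b))),
       n_edges = nrow(df))
}

#' Contacts as a data frame
#'
#' Flattens the store's edges into a deterministic data frame sorted by
#' (experiment, gene_a, gene_b), with one list-column `properties`.
#'
#' @param store a [contact_store()].
#' @param experiments optional character vector restricting to a subset
#'   of experiments (default: all).
#' @return a data.frame with columns `experiment`, `gene_a`, `gene_b`,
#'   `weight`, `probability`, `properties`.
#' @export
contact_table <- function(store, experiments = NULL) {
  stopifnot(inherits(store, "contact_store"))
  keys <- ls(store$edges)
  recs <- lapply(keys, function(k) store$edges[[k]])
  if (!is.null(experiments)) {
    unknown <- setdiff(experiments, experiment_names(store))
    if (length(unknown))
      stopf("unknown experiment '%s'; available: %s", unknown[[1L]],
            paste(experiment_names(store), collapse = ", "))
    recs <- Filter(function(r) r$experiment %in% experiments, recs)
  }
  if (!length(recs)) {
    return(data.frame(experiment = character(), gene_a = character(),
                      gene_b = character(), weight = numeric(),
                      probability = numeric(),
                      properties = I(list()),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    experiment = vapply(recs, `[[`, character(1L), "experiment"),
    gene_a = vapply(recs, `[[`, character(1L), "gene_a"),
    gene_b = vapply(recs, `[[`, character(1L), "gene_b"),
    weight = vapply(recs, `[[`, numeric(1L), "weight"),
    probability = vapply(recs, `[[`, numeric(1L), "probability"),
    stringsAsFactors = FALSE)
  df$properties <- I(lapply(recs, `[[`, "properties"))
  df <- df[order(df$experiment, df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Simple undirected subgraph of one experiment
#'
#' Builds the weighted, undirected igraph view of a single experiment:
#' vertices are the genes incident to at least one of its contacts
#' (registered but isolated genes are excluded), edges carry `weight`
#' and `probability` attributes plus any extra properties. Vertex and
#' edge order is lexicographic by symbol, so all downstream analytics
#' are reproducible.
#'
#' @param store a [contact_store()].
#' @param experiment experiment name.
#' @return an [igraph::graph] with graph attribute `experiment`.
#' @export
experiment_subgraph <- function(store, experiment) {
  stopifnot(inherits(store, "contact_store"))
  if (is.null(store$experiments[[experiment]]))
    stopf("unknown experiment '%s'; available: %s", experiment,
          paste(experiment_names(store), collapse = ", "))
  df <- contact_table(store, experiments = experiment)
  verts <- sort(unique(c(df$gene_a, df$gene_b)))
  g <- igraph::make_empty_graph(n = 0L, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (nrow(df)) {
    g <- igraph::add_edges(g, rbind(match(df$gene_a, verts),
                                    match(df$gene_b, verts)))
    igraph::E(g)$weight <- df$weight
    igraph::E(g)$probability <- df$probability
    prop_names <- unique(unlist(lapply(df$properties, names)))
    for (p in prop_names) {
      vals <- lapply(df$properties, function(x) x[[p]])
      vals[vapply(vals, is.null, logical(1L))] <- NA
      g <- igraph::set_edge_attr(g, p, value = unlist(vals))
    }
  }
  g <- igraph::set_graph_attr(g, "experiment", experiment)
  g
}

#' Threshold-filtered neighbours of a gene
#'
#' Union, over the selected experiments, of the genes that share a
#' contact of weight `>= min_weight` with the query gene. The query
#' gene itself is never returned.
#'
#' @param store a [contact_store()].
#' @param symbol query gene symbol.
#' @param experiments character vector of experiment names
#'   (default: all registered experiments).
#' @param min_weight minimum supporting read count (default 0: keep
#'   every adjacent gene).
#' @return sorted character vector of neighbour symbols.
#' @export
contact_neighbors <- function(store, symbol, experiments = NULL,
                              min_weight = 0) {
  stopifnot(inherits(store, "contact_store"))
  if (is.null(store$genes[[symbol]]))
    stopf("unknown gene '%s'", symbol)
  if (is.null(experiments)) experiments <- experiment_names(store)
  if (!length(experiments)) stopf("'experiments' must be non-empty")
  assert_scalar_number(min_weight, "min_weight", min = 0)
  df <- contact_table(store, experiments = experiments)
  df <- df[df$weight >= min_weight &
             (df$gene_a == symbol | df$gene_b == symbol), , drop = FALSE]
  if (!nrow(df)) return(character(0))
  sort(unique(ifelse(df$gene_a == symbol, df$gene_b, df$gene_a)))
}

#' Persist a store to, or load it from, a directory of TSV files
#'
#' The on-disk format is three UTF-8 tab-separated files with mandatory
#' headers and deterministic row order: `genes.tsv` (symbol, chromosome,
#' start, end), `experiments.tsv` (name, n_genes, n_edges) and
#' `edges.tsv` (experiment, gene_a, gene_b, weight, probability,
#' properties as `key=value;...`). `read_store(write_store(store))` is
#' an exact round trip.
#'
#' @param store a [contact_store()].
#' @param dir directory path (created if needed).
#' @param strict passed to [contact_store()] on load.
#' @return `write_store`: `dir`, invisibly. `read_store`: a new store.
#' @export
write_store <- function(store, dir) {
  stopifnot(inherits(store, "contact_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  syms <- gene_symbols(store)
  genes <- data.frame(
    symbol = syms,
    chromosome = vapply(syms, function(s) store$genes[[s]]$chromosome,
                        character(1L)),
    start = vapply(syms, function(s) store$genes[[s]]$start, numeric(1L)),
    end = vapply(syms, function(s) store$genes[[s]]$end, numeric(1L)),
    stringsAsFactors = FALSE)
  exps <- experiment_names(store)
  stats <- lapply(exps, function(e) experiment_stats(store, e))
  expdf <- data.frame(
    name = exps,
    n_genes = vapply(stats, `[[`, integer(1L), "n_genes"),
    n_edges = vapply(stats, `[[`, integer(1L), "n_edges"),
    stringsAsFactors = FALSE)
  ed <- contact_table(store)
  eddf <- ed[, c("experiment", "gene_a", "gene_b", "weight", "probability")]
  eddf$properties <- vapply(ed$properties, format_properties, character(1L))
  write_tsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  write_tsv(genes, file.path(dir, "genes.tsv"))
  write_tsv(expdf, file.path(dir, "experiments.tsv"))
  write_tsv(eddf, file.path(dir, "edges.tsv"))
  invisible(dir)
}

#' @rdname write_store
#' @export
read_store <- function(dir, strict = FALSE) {
  for (f in c("genes.tsv", "experiments.tsv", "edges.tsv"))
    if (!file.exists(file.path(dir, f)))
      stopf("'%s' is not a store directory: missing %s", dir, f)
  read_tsv <- function(path)
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE, colClasses = NA,
                      fileEncoding = "UTF-8")
  genes <- read_tsv(file.path(dir, "genes.tsv"))
  expdf <- read_tsv(file.path(dir, "experiments.tsv"))
  eddf <- read_tsv(file.path(dir, "edges.tsv"))
  store <- contact_store(strict = FALSE)
  for (i in seq_len(nrow(genes)))
    upsert_gene(store, genes$symbol[[i]], genes$chromosome[[i]],
                genes$start[[i]], genes$end[[i]])
  for (nm in expdf$name) register_experiment(store, nm)
  if (nrow(eddf)) {
    props <- as.character(eddf$properties)
    props[is.na(props)] <- ""
    for (i in seq_len(nrow(eddf)))
      add_contact(store, eddf$experiment[[i]], eddf$gene_a[[i]],
                  eddf$gene_b[[i]], weight = eddf$weight[[i]],
                  probability = eddf$probability[[i]],
                  properties = parse_properties(props[[i]]))
  }
  store$strict <- isTRUE(strict)
  store
}
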