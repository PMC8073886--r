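#' Progressive gene-centric exploration
#'
#' An exploration session is an immutable value: an ordered list of
#' expansion steps, each holding anchor genes, an experiment filter and
#' a weight threshold. The session is the *only* state — resolving the
#' same session against the same store always yields the same display
#' graph, so a session doubles as a reproducible provenance record of a
#' navigation (mirroring a query string that grows by one path pattern
#' per expansion). Navigation functions return new sessions and never
#' modify their input.
#'
#' @param store a [contact_store()].
#' @param gene starting gene symbol.
#' @param experiments character vector of experiment names to explore
#'   (default: all registered).
#' @param min_weight contact weight threshold for neighbours
#'   (default 0).
#' @param require_all_experiments when `TRUE`, only neighbours with at
#'   least one qualifying contact in *each* selected experiment are
#'   shown; default `FALSE` (union semantics).
#' @return an object of class `exploration_session`.
#' @export
explore_start <- function(store, gene, experiments = NULL,
                          min_weight = 0,
                          require_all_experiments = FALSE) {
  stopifnot(inherits(store, "contact_store"))
  if (is.null(store$genes[[gene]])) stopf("unknown gene '%s'", gene)
  if (is.null(experiments)) experiments <- experiment_names(store)
  if (!length(experiments)) stopf("'experiments' must be non-empty")
  unknown <- setdiff(experiments, experiment_names(store))
  if (length(unknown)) stopf("unknown experiment '%s'", unknown[[1L]])
  assert_scalar_number(min_weight, "min_weight", min = 0)
  structure(list(steps = list(list(anchors = gene,
                                   experiments = sort(experiments),
                                   min_weight = min_weight)),
                 require_all = isTRUE(require_all_experiments)),
            class = "exploration_session")
}

#' @rdname explore_start
#' @param session an `exploration_session`.
#' @param genes genes to expand; each must be visible in the current
#'   resolution. Expanding an empty set returns the session unchanged.
#' @export
explore_expand <- function(session, store, genes,
                           min_weight = NULL) {
  stopifnot(inherits(session, "exploration_session"))
  if (!length(genes)) return(session)
  visible <- igraph::V(explore_resolve(session, store))$name
  hidden <- setdiff(genes, visible)
  if (length(hidden))
    stopf("cannot expand '%s': not visible at the current step",
          hidden[[1L]])
  last <- session$steps[[length(session$steps)]]
  step <- list(anchors = sort(unique(genes)),
               experiments = last$experiments,
               min_weight = if (is.null(min_weight)) last$min_weight
                            else min_weight)
  session$steps[[length(session$steps) + 1L]] <- step
  session
}

#' @rdname explore_start
#' @export
explore_back <- function(session) {
  stopifnot(inherits(session, "exploration_session"))
  if (length(session$steps) > 1L)
    session$steps[[length(session$steps)]] <- NULL
  session
}

#' @rdname explore_start
#' @param gene_a,gene_b endpoints of an edge shown at some step; the
#'   session is truncated to the earliest step whose resolution
#'   contains that edge.
#' @export
explore_truncate <- function(session, store, gene_a, gene_b) {
  stopifnot(inherits(session, "exploration_session"))
  for (k in seq_along(session$steps)) {
    partial <- session
    partial$steps <- session$steps[seq_len(k)]
    g <- explore_resolve(partial, store)
    nm <- igraph::V(g)$name
    if (all(c(gene_a, gene_b) %in% nm) &&
        igraph::are_adjacent(g, gene_a, gene_b))
      return(partial)
  }
  stopf("edge %s - %s does not appear on the exploration path",
        gene_a, gene_b)
}

#' @rdname explore_start
#' @param session_wide apply the new threshold to every step instead of
#'   only the latest (default `FALSE`).
#' @export
explore_set_threshold <- function(session, min_weight,
                                  session_wide = FALSE) {
  stopifnot(inherits(session, "exploration_session"))
  assert_scalar_number(min_weight, "min_weight", min = 0)
  idx <- if (session_wide) seq_along(session$steps)
         else length(session$steps)
  for (i in idx) session$steps[[i]]$min_weight <- min_weight
  session
}

#' Resolve a session to its display graph
#'
#' Evaluates every step against the store: each step contributes its
#' anchors plus their threshold-passing neighbours within the step's
#' experiment filter, together with the qualifying anchor-neighbour
#' contacts (one edge per experiment, carrying `experiment`, `weight`
#' and `probability` attributes). Steps are unioned. Resolution is a
#' pure function of (session, store); vertex and edge order is
#' deterministic.
#'
#' @param session an `exploration_session`.
#' @param store a [contact_store()].
#' @return an undirected igraph display graph.
#' @export
explore_resolve <- function(session, store) {
  stopifnot(inherits(session, "exploration_session"),
            inherits(store, "contact_store"))
  edges <- list()
  vert_set <- character()
  for (step in session$steps) {
    unknown <- setdiff(step$experiments, experiment_names(store))
    if (length(unknown))
      stopf("session refers to unknown experiment '%s'", unknown[[1L]])
    vert_set <- union(vert_set, step$anchors)
    df <- contact_table(store, experiments = step$experiments)
    for (anchor in step$anchors) {
      hit <- df[(df$gene_a == anchor | df$gene_b == anchor) &
                  df$weight >= step$min_weight, , drop = FALSE]
      if (!nrow(hit)) next
      other <- ifelse(hit$gene_a == anchor, hit$gene_b, hit$gene_a)
      if (session$require_all) {
        per_exp <- split(other, hit$experiment)
        keep_set <- Reduce(intersect,
                           per_exp[step$experiments],
                           accumulate = FALSE)
        if (is.null(keep_set)) keep_set <- character()
        keep <- other %in% keep_set
        hit <- hit[keep, , drop = FALSE]
        other <- other[keep]
      }
      vert_set <- union(vert_set, other)
      if (nrow(hit)) edges[[length(edges) + 1L]] <- hit
    }
  }
  verts <- sort(vert_set)
  g <- igraph::make_empty_graph(0L, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (length(edges)) {
    ed <- do.call(rbind, edges)
    key <- paste(ed$experiment, pair_key(ed$gene_a, ed$gene_b))
    ed <- ed[!duplicated(key), , drop = FALSE]
    ed <- ed[order(ed$gene_a, ed$gene_b, ed$experiment), , drop = FALSE]
    g <- igraph::add_edges(g, rbind(match(ed$gene_a, verts),
                                    match(ed$gene_b, verts)))
    igraph::E(g)$experiment <- ed$experiment
    igraph::E(g)$weight <- ed$weight
    igraph::E(g)$probability <- ed$probability
  }
  g
}

#' Render a session as a query pattern string
#'
#' Serialises the session in a Cypher-flavoured MATCH pattern, one
#' `(n_x)-[r_x:TYPE]-(n_x+1)` clause per step, for provenance and
#' debugging. The text documents the navigation; it is not executed.
#'
#' @param session an `exploration_session`.
#' @return a single character string.
#' @export
render_pattern <- function(session) {
  stopifnot(inherits(session, "exploration_session"))
  clauses <- vapply(seq_along(session$steps), function(i) {
    step <- session$steps[[i]]
    rel <- paste(toupper(gsub("[^A-Za-z0-9]", "_", step$experiments)),
                 collapse = "|")
    anchors <- paste(sprintf("'%s'", step$anchors), collapse = ", ")
    sprintf("(n%d:Gene {symbol IN [%s]})-[r%d:%s WHERE r%d.weight >= %s]-(n%d)",
            i - 1L, anchors, i - 1L, rel, i - 1L,
            format(step$min_weight), i)
  }, character(1L))
  paste0("MATCH ", paste(clauses, collapse = ",\n      "),
         "\nRETURN *")
}

#' Serialise a session to, or restore it from, JSON
#'
#' The JSON document is the full session state (step list plus the
#' experiment-conjunction flag), so sessions can be stored, shared and
#' replayed.
#'
#' @param session an `exploration_session`.
#' @param path optional file path; when `NULL` the JSON text is
#'   returned.
#' @return `session_to_json`: JSON text or `path`. `session_from_json`:
#'   an `exploration_session`.
#' @export
session_to_json <- function(session, path = NULL) {
  stopifnot(inherits(session, "exploration_session"))
  txt <- jsonlite::toJSON(list(require_all = session$require_all,
                               steps = session$steps),
                          auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' @rdname session_to_json
#' @param json JSON text (ignored when `path` is given).
#' @export
session_from_json <- function(json = NULL, path = NULL) {
  if (!is.null(path)) json <- paste(readLines(path), collapse = "\n")
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  steps <- lapply(obj$steps, function(s)
    list(anchors = as.character(unlist(s$anchors)),
         experiments = as.character(unlist(s$experiments)),
         min_weight = as.numeric(s$min_weight)))
  structure(list(steps = steps, require_all = isTRUE(obj$require_all)),
            class = "exploration_session")
}

#' @export
print.exploration_session <- function(x, ...) {
  cat(sprintf("<exploration_session> %d step(s)\n", length(x$steps)))
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  %d. anchors: %s | experiments: %s | min_weight: %s\n",
                i, paste(s$anchors, collapse = ","),
                paste(s$experiments, collapse = ","),
                format(s$min_weight)))
  }
  invisible(x)
}
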