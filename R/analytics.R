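#' Degree distribution of a subgraph
#'
#' @param subgraph igraph object.
#' @return data.frame with columns `degree` (ascending) and `count`;
#'   counts sum to the vertex count and `sum(degree * count)` equals
#'   twice the edge count.
#' @export
degree_distribution_table <- function(subgraph) {
  stopifnot(inherits(subgraph, "igraph"))
  d <- igraph::degree(subgraph)
  if (!length(d))
    return(data.frame(degree = integer(), count = integer()))
  tab <- table(d)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
}

#' Local clustering attitude: coefficient and triangle counts
#'
#' For each gene v with degree k(v) and T(v) triangles through it, the
#' local clustering coefficient is 2 T(v) / (k(v) (k(v) - 1)), defined
#' as 0 when k(v) < 2. Raw triangle counts are returned alongside
#' because the two scales answer different questions (density of the
#' neighbourhood vs. absolute triangle participation).
#'
#' @param subgraph igraph object.
#' @return list with named numeric vectors `coefficient` (in \[0,1\])
#'   and `triangles`.
#' @export
clustering_attitude <- function(subgraph) {
  stopifnot(inherits(subgraph, "igraph"))
  verts <- igraph::V(subgraph)$name
  if (!length(verts))
    return(list(coefficient = stats::setNames(numeric(), character()),
                triangles = stats::setNames(numeric(), character())))
  coef <- igraph::transitivity(subgraph, type = "local",
                               isolates = "zero",
                               vids = igraph::V(subgraph))
  tri <- igraph::count_triangles(subgraph)
  list(coefficient = stats::setNames(as.numeric(coef), verts),
       triangles = stats::setNames(as.numeric(tri), verts))
}

#' PageRank by power iteration
#'
#' Classic damped random-walk centrality on the undirected graph (each
#' edge treated as two arcs). Iterates
#' `x <- (1 - d)/n + d * (A x / deg + dangling/n)` until the L1 change
#' drops below `tol`; mass of dangling (degree-0) vertices is
#' redistributed uniformly, so the result sums to exactly 1.
#'
#' @param subgraph igraph object with at least one vertex.
#' @param damping damping factor d (default 0.85).
#' @param tol L1 convergence tolerance (default 1e-9).
#' @param max_iter iteration cap; exceeding it is an error that reports
#'   the iteration count.
#' @param weighted when `TRUE`, the walk follows edge weights
#'   proportionally; default `FALSE` (pure topology).
#' @return named numeric vector summing to 1.
#' @export
pagerank_centrality <- function(subgraph, damping = 0.85, tol = 1e-9,
                                max_iter = 200L, weighted = FALSE) {
  stopifnot(inherits(subgraph, "igraph"))
  n <- igraph::vcount(subgraph)
  if (n == 0L) stopf("PageRank requires at least one vertex")
  assert_scalar_number(damping, "damping", min = 0, max = 1,
                       closed_max = FALSE)
  verts <- igraph::V(subgraph)$name
  A <- igraph::as_adjacency_matrix(
    subgraph, sparse = FALSE,
    attr = if (weighted && !is.null(igraph::E(subgraph)$weight)) "weight"
           else NULL)
  s <- rowSums(A)
  dangling <- s == 0
  P <- A
  P[!dangling, ] <- A[!dangling, , drop = FALSE] / s[!dangling]
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- (1 - damping) / n +
      damping * (as.numeric(crossprod(P, x)) + sum(x[dangling]) / n)
    delta <- sum(abs(x_new - x))
    x <- x_new
    if (delta < tol) {
      x <- x / sum(x)
      return(stats::setNames(x, verts))
    }
  }
  stopf("PageRank did not converge within %d iterations (last L1 change %.3g)",
        max_iter, delta)
}

#' Betweenness centrality
#'
#' Brandes' algorithm on the undirected subgraph: for each vertex v,
#' the sum over vertex pairs (s, t), s != v != t, of the fraction of
#' shortest s-t paths passing through v. Each unordered pair is counted
#' once; endpoints are excluded; values are unnormalised by default.
#'
#' @param subgraph igraph object.
#' @param weighted when `TRUE`, shortest paths minimise 1/weight (heavier
#'   contacts are shorter); default `FALSE` (hop counts).
#' @param normalized divide by `(n-1)(n-2)/2` (default `FALSE`).
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(subgraph, weighted = FALSE,
                                   normalized = FALSE) {
  stopifnot(inherits(subgraph, "igraph"))
  if (igraph::vcount(subgraph) == 0L)
    return(stats::setNames(numeric(), character()))
  w <- if (weighted && !is.null(igraph::E(subgraph)$weight))
    1 / igraph::E(subgraph)$weight else NA
  b <- igraph::betweenness(subgraph, directed = FALSE, weights = w,
                           normalized = normalized)
  stats::setNames(as.numeric(b), igraph::V(subgraph)$name)
}

#' Closeness centrality, component-restricted
#'
#' `c(v) = (n_v - 1) / sum of distances from v to the other vertices of
#' its connected component`, where n_v is the component size; an
#' isolated vertex scores 0. Restricting to the component keeps the
#' measure finite on fragmented contact graphs. The harmonic variant
#' (mean of inverse distances over *all* other vertices) is available
#' for cross-component comparability.
#'
#' @param subgraph igraph object.
#' @param harmonic compute harmonic closeness instead (default
#'   `FALSE`).
#' @param weighted minimise 1/weight path lengths instead of hop counts
#'   (default `FALSE`).
#' @return named numeric vector.
#' @export
closeness_centrality <- function(subgraph, harmonic = FALSE,
                                 weighted = FALSE) {
  stopifnot(inherits(subgraph, "igraph"))
  n <- igraph::vcount(subgraph)
  verts <- igraph::V(subgraph)$name
  if (n == 0L) return(stats::setNames(numeric(), character()))
  w <- if (weighted && !is.null(igraph::E(subgraph)$weight))
    1 / igraph::E(subgraph)$weight else NA
  d <- igraph::distances(subgraph, weights = w)
  out <- vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    if (harmonic) {
      if (n == 1L) return(0)
      return(sum(1 / dv[is.finite(dv)]) / (n - 1L))
    }
    reach <- is.finite(dv)
    if (!any(reach)) return(0)
    sum(reach) / sum(dv[reach])
  }, numeric(1L))
  stats::setNames(out, verts)
}

#' Shortest path between two genes
#'
#' In `"hops"` mode the path minimises the number of edges. In
#' `"probability"` mode each edge gets length `-log2(probability)`, so
#' the shortest path maximises the product of edge probabilities; the
#' reported length is that product's negative log2 (bits). Among
#' equally short paths the lexicographically smallest gene sequence is
#' returned, making results deterministic.
#'
#' @param subgraph igraph object whose edges carry `probability`
#'   attributes (required for probability mode).
#' @param from,to gene symbols.
#' @param mode `"hops"` or `"probability"`.
#' @return object of class `path_result`: list with `genes` (character
#'   path, empty when unreachable), `length` (`Inf` when unreachable),
#'   `mode`, `reachable`. An unreachable pair is a result, not an
#'   error.
#' @export
shortest_contact_path <- function(subgraph, from, to,
                                  mode = c("hops", "probability")) {
  stopifnot(inherits(subgraph, "igraph"))
  mode <- match.arg(mode)
  verts <- igraph::V(subgraph)$name
  for (g in c(from, to))
    if (!g %in% verts) stopf("gene '%s' is not in the subgraph", g)
  w <- path_weights(subgraph, mode)
  if (from == to)
    return(structure(list(genes = from, length = 0, mode = mode,
                          reachable = TRUE), class = "path_result"))
  sp <- suppressWarnings(
    igraph::all_shortest_paths(subgraph, from = from, to = to,
                               weights = w))
  paths <- lapply(sp$vpaths, function(p) igraph::V(subgraph)$name[p])
  if (!length(paths))
    return(structure(list(genes = character(), length = Inf, mode = mode,
                          reachable = FALSE), class = "path_result"))
  keys <- vapply(paths, paste, character(1L), collapse = "\r")
  genes <- paths[[order(keys)[[1L]]]]
  len <- if (mode == "hops") length(genes) - 1
  else path_bits(subgraph, genes)
  structure(list(genes = genes, length = len, mode = mode,
                 reachable = TRUE), class = "path_result")
}

path_weights <- function(subgraph, mode) {
  if (mode == "hops") return(NA)
  p <- igraph::E(subgraph)$probability
  if (is.null(p))
    stopf("probability mode requires a 'probability' edge attribute")
  -log2(p)
}

# total path length in bits (-log2 of the probability product)
path_bits <- function(subgraph, genes) {
  if (length(genes) < 2L) return(0)
  ids <- igraph::get_edge_ids(subgraph,
                              rbind(genes[-length(genes)], genes[-1L]))
  sum(-log2(igraph::E(subgraph)$probability[ids]))
}

#' @export
print.path_result <- function(x, ...) {
  if (!x$reachable) cat("<path_result> unreachable\n")
  else cat(sprintf("<path_result> %s (length %.4g, mode %s)\n",
                   paste(x$genes, collapse = " - "), x$length, x$mode))
  invisible(x)
}

#' Single-source shortest path lengths
#'
#' Distances from one gene to every gene of the subgraph, in the same
#' two modes as [shortest_contact_path()]; unreachable genes get `Inf`.
#'
#' @inheritParams shortest_contact_path
#' @param gene source gene symbol.
#' @return named numeric vector of path lengths (hops, or bits in
#'   probability mode).
#' @export
all_shortest_from <- function(subgraph, gene,
                              mode = c("hops", "probability")) {
  stopifnot(inherits(subgraph, "igraph"))
  mode <- match.arg(mode)
  if (!gene %in% igraph::V(subgraph)$name)
    stopf("gene '%s' is not in the subgraph", gene)
  w <- path_weights(subgraph, mode)
  d <- igraph::distances(subgraph, v = gene, weights = w)[1L, ]
  stats::setNames(as.numeric(d), igraph::V(subgraph)$name)
}

#' Per-gene neighbourhood Jaccard between two experiments
#'
#' Similarity of one gene's threshold-passing neighbour sets in two
#' experiments: `|N_a intersect N_b| / |N_a union N_b|`. When both
#' neighbour sets are empty the gene's neighbourhood is identically
#' absent in both experiments and the similarity is defined as 1.
#'
#' @param store a [contact_store()].
#' @param gene gene symbol.
#' @param exp_a,exp_b experiment names.
#' @param min_weight minimum contact weight for a neighbour to count
#'   (default 0).
#' @return a number in \[0, 1\].
#' @export
gene_neighbor_jaccard <- function(store, gene, exp_a, exp_b,
                                  min_weight = 0) {
  for (e in c(exp_a, exp_b))
    if (is.null(store$experiments[[e]]))
      stopf("unknown experiment '%s'; available: %s", e,
            paste(experiment_names(store), collapse = ", "))
  na <- contact_neighbors(store, gene, exp_a, min_weight)
  nb <- contact_neighbors(store, gene, exp_b, min_weight)
  if (!length(na) && !length(nb)) return(1.0)
  length(intersect(na, nb)) / length(union(na, nb))
}

#' Compute a named node-metric map
#'
#' Dispatcher used by the comparison and omics layers: computes one of
#' the supported per-gene metrics on an experiment subgraph.
#'
#' @param subgraph igraph object.
#' @param metric one of `"degree"`, `"pagerank"`, `"betweenness"`,
#'   `"closeness"`, `"clustering_coefficient"`, `"triangles"`.
#' @param seed ignored (accepted for interface symmetry).
#' @param ... passed to the underlying metric function.
#' @return named numeric vector over the subgraph's genes.
#' @export
centrality_map <- function(subgraph, metric, seed = 1L, ...) {
  metrics <- c("degree", "pagerank", "betweenness", "closeness",
               "clustering_coefficient", "triangles")
  if (!metric %in% metrics)
    stopf("unknown metric '%s'; supported: %s", metric,
          paste(metrics, collapse = ", "))
  switch(metric,
         degree = {
           d <- igraph::degree(subgraph)
           stats::setNames(as.numeric(d), igraph::V(subgraph)$name)
         },
         pagerank = pagerank_centrality(subgraph, ...),
         betweenness = betweenness_centrality(subgraph, ...),
         closeness = closeness_centrality(subgraph, ...),
         clustering_coefficient = clustering_attitude(subgraph)$coefficient,
         triangles = clustering_attitude(subgraph)$triangles)
}

#' Write a metric map or partition as two-column CSV
#'
#' @param x named numeric vector (gene metric map) or `gene_partition`.
#' @param path output CSV path.
#' @param value_name header for the value column (default `"value"`, or
#'   `"community"` for partitions).
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(x, path, value_name = NULL) {
  if (inherits(x, "gene_partition")) {
    df <- data.frame(gene = names(x$membership),
                     community = as.integer(x$membership))
    if (!is.null(value_name)) names(df)[2L] <- value_name
  } else {
    df <- data.frame(gene = names(x), value = as.numeric(x))
    names(df)[2L] <- if (is.null(value_name)) "value" else value_name
  }
  df <- df[order(df$gene), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
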