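#' Edge-set Jaccard similarity between two experiments
#'
#' Similarity of the unordered gene-pair edge sets of two experiments:
#' `|E_a intersect E_b| / |E_a union E_b|`, ignoring weights and
#' probabilities. Two empty experiments are identically absent and
#' score 1. (A published table of this statistic is sometimes titled a
#' "distance"; with a unit diagonal it is a similarity, and that is
#' what this function computes. A weight-aware variant — summed
#' min/max weight ratio over the edge union — is available via
#' `weighted = TRUE`.)
#'
#' @param store a [contact_store()].
#' @param exp_a,exp_b experiment names.
#' @param weighted use the min/max weight-ratio variant
#'   (default `FALSE`).
#' @return a number in \[0, 1\].
#' @export
experiment_edge_jaccard <- function(store, exp_a, exp_b,
                                    weighted = FALSE) {
  stopifnot(inherits(store, "contact_store"))
  for (e in c(exp_a, exp_b))
    if (is.null(store$experiments[[e]]))
      stopf("unknown experiment '%s'; available: %s", e,
            paste(experiment_names(store), collapse = ", "))
  da <- contact_table(store, experiments = exp_a)
  db <- contact_table(store, experiments = exp_b)
  ka <- pair_key(da$gene_a, da$gene_b)
  kb <- pair_key(db$gene_a, db$gene_b)
  if (!length(ka) && !length(kb)) return(1.0)
  if (!weighted)
    return(length(intersect(ka, kb)) / length(union(ka, kb)))
  wa <- stats::setNames(da$weight, ka)
  wb <- stats::setNames(db$weight, kb)
  keys <- union(ka, kb)
  lo <- hi <- numeric(length(keys))
  for (i in seq_along(keys)) {
    a <- if (keys[[i]] %in% ka) wa[[keys[[i]]]] else 0
    b <- if (keys[[i]] %in% kb) wb[[keys[[i]]]] else 0
    lo[[i]] <- min(a, b); hi[[i]] <- max(a, b)
  }
  sum(lo) / sum(hi)
}

#' Pairwise Jaccard similarity matrix of experiments
#'
#' @param store a [contact_store()].
#' @param experiments character vector of at least two experiment names
#'   (default: all registered).
#' @param weighted passed to [experiment_edge_jaccard()].
#' @return symmetric numeric matrix with unit diagonal, dimnames set to
#'   the experiment names.
#' @export
jaccard_matrix <- function(store, experiments = NULL, weighted = FALSE) {
  stopifnot(inherits(store, "contact_store"))
  if (is.null(experiments)) experiments <- experiment_names(store)
  if (length(experiments) < 2L)
    stopf("need at least two experiments, got %d", length(experiments))
  k <- length(experiments)
  m <- diag(1, k)
  dimnames(m) <- list(experiments, experiments)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      v <- experiment_edge_jaccard(store, experiments[[i]],
                                   experiments[[j]], weighted = weighted)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Aligned degree-distribution table across experiments
#'
#' Histogram of gene degrees per experiment on shared bin edges, ready
#' for side-by-side bar plotting.
#'
#' @param store a [contact_store()].
#' @param experiments experiment names (default: all registered).
#' @param binwidth integer width of the degree bins (default 1: one
#'   column per exact degree).
#' @return data.frame: `degree` (bin lower edge) plus one count column
#'   per experiment; each experiment column sums to its gene count.
#' @export
degree_table <- function(store, experiments = NULL, binwidth = 1L) {
  stopifnot(inherits(store, "contact_store"))
  if (is.null(experiments)) experiments <- experiment_names(store)
  assert_scalar_number(binwidth, "binwidth", min = 1)
  degs <- lapply(experiments, function(e)
    igraph::degree(experiment_subgraph(store, e)))
  max_d <- max(c(0, unlist(degs)))
  edges <- seq(0L, max_d + binwidth, by = binwidth)
  out <- data.frame(degree = edges[-length(edges)])
  for (i in seq_along(experiments)) {
    bin <- findInterval(degs[[i]], edges)
    counts <- tabulate(bin, nbins = length(edges) - 1L)
    out[[experiments[[i]]]] <- counts
  }
  out
}

#' Louvain community profile of one experiment
#'
#' @param store a [contact_store()].
#' @param experiment experiment name.
#' @param seed RNG seed passed to [louvain_communities()].
#' @param ... further arguments to [louvain_communities()].
#' @return list of class `community_profile`: `experiment`, `sizes`
#'   (descending), `n_communities`, `modularity`, `partition`.
#' @export
community_profile <- function(store, experiment, seed = 1L, ...) {
  part <- louvain_communities(experiment_subgraph(store, experiment),
                              seed = seed, ...)
  structure(list(experiment = experiment,
                 sizes = sort(part$sizes, decreasing = TRUE),
                 n_communities = part$n_communities,
                 modularity = part$modularity,
                 partition = part),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("<community_profile> %s: %d communities (Q = %.4f), sizes %s\n",
              x$experiment, x$n_communities, x$modularity,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Agreement of two community assignments over the same gene set,
#' corrected for chance via the standard hypergeometric contingency
#' formula. Label permutations do not change the value; identical
#' partitions score 1. If the gene sets differ the intersection is used
#' with a warning.
#'
#' @param partition_a,partition_b `gene_partition` objects or named
#'   membership vectors.
#' @return the adjusted Rand index (1 for perfect agreement; about 0
#'   for independent partitions).
#' @export
partition_agreement <- function(partition_a, partition_b) {
  ma <- if (inherits(partition_a, "gene_partition"))
    partition_a$membership else partition_a
  mb <- if (inherits(partition_b, "gene_partition"))
    partition_b$membership else partition_b
  if (is.null(names(ma)) || is.null(names(mb)))
    stopf("memberships must be named by gene symbol")
  shared <- intersect(names(ma), names(mb))
  if (!length(shared)) stopf("partitions share no genes")
  if (length(shared) < length(ma) || length(shared) < length(mb))
    warning(sprintf("partitions differ in gene sets; using %d shared genes",
                    length(shared)))
  a <- ma[shared]; b <- mb[shared]
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps^0.5) return(1.0)
  (sum_ij - expected) / (max_index - expected)
}

#' Per-gene metric change between two experiments
#'
#' Computes one node metric in both experiments, joins on the genes
#' present in both, and reports the change, largest absolute changes
#' first — the screen used to shortlist genes whose local wiring (e.g.
#' clustering attitude) shifts between conditions.
#'
#' @param store a [contact_store()].
#' @param exp_a,exp_b experiment names.
#' @param metric a [centrality_map()] metric tag.
#' @param ... passed to [centrality_map()].
#' @return data.frame with columns `gene`, `value_a`, `value_b`,
#'   `delta` (= `value_b - value_a`), sorted by `abs(delta)`
#'   descending.
#' @export
metric_delta <- function(store, exp_a, exp_b, metric, ...) {
  va <- centrality_map(experiment_subgraph(store, exp_a), metric, ...)
  vb <- centrality_map(experiment_subgraph(store, exp_b), metric, ...)
  shared <- intersect(names(va), names(vb))
  df <- data.frame(gene = shared,
                   value_a = as.numeric(va[shared]),
                   value_b = as.numeric(vb[shared]),
                   stringsAsFactors = FALSE)
  df$delta <- df$value_b - df$value_a
  df <- df[order(-abs(df$delta), df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}
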