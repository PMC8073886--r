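# Fixture builders shared across the suite; everything is generated in
# code so the test tree stays text-only.

# Two genes linked by one contact in each of three experiments: the
# smallest multi-experiment store.
make_three_experiment_store <- function() {
  s <- contact_store()
  upsert_gene(s, "AADACL3", "chr1", 12776118, 12788726)
  upsert_gene(s, "AADACL4", "chr1", 12704565, 12727097)
  for (e in c("T0_Rep1", "T_16_Rep1", "T_32_Rep1"))
    add_contact(s, e, "AADACL3", "AADACL4", weight = 3, probability = 0.8)
  s
}

# A-centred star with weights 1, 2, 3 on A-B, A-C, A-D.
make_star_store <- function(experiment = "exp1") {
  s <- contact_store()
  for (i in seq_along(LETTERS[1:4]))
    upsert_gene(s, LETTERS[i], "chr1", (i - 1) * 1000, (i - 1) * 1000 + 500)
  add_contact(s, experiment, "A", "B", weight = 1, probability = 0.9)
  add_contact(s, experiment, "A", "C", weight = 2, probability = 0.9)
  add_contact(s, experiment, "A", "D", weight = 3, probability = 0.9)
  s
}

# Random G(n, p) with named vertices, optional weight/probability
# attributes, deterministic under seed.
random_contact_graph <- function(n, p, seed, probs = TRUE) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- sprintf("V%02d", seq_len(n))
  if (probs && igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- sample(1:9, igraph::ecount(g), replace = TRUE)
    igraph::E(g)$probability <- stats::runif(igraph::ecount(g), 0.1, 1)
  }
  g
}

adjacency_of <- function(g) {
  igraph::as_adjacency_matrix(g, sparse = FALSE)
}

# all labeled graphs on n vertices as adjacency matrices (n <= 5 keeps
# this affordable: 2^(n(n-1)/2) graphs)
all_labeled_graphs <- function(n) {
  m <- n * (n - 1) / 2
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- bits
    A + t(A)
  })
}

graph_from_adj <- function(A, probs = TRUE, seed = 1) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- sprintf("V%02d", seq_len(nrow(A)))
  if (probs && igraph::ecount(g) > 0) {
    set.seed(seed)
    igraph::E(g)$weight <- sample(1:9, igraph::ecount(g), replace = TRUE)
    igraph::E(g)$probability <- stats::runif(igraph::ecount(g), 0.1, 1)
  }
  g
}

is_connected_adj <- function(A) {
  n <- nrow(A)
  if (n == 1) return(TRUE)
  seen <- c(1L)
  frontier <- c(1L)
  while (length(frontier)) {
    nxt <- setdiff(which(rowSums(A[, frontier, drop = FALSE]) > 0), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == n
}

# build a store from a contact-record data frame under one experiment
store_from_records <- function(records, experiment = "exp1") {
  s <- contact_store()
  ingest_contacts(s, records, experiment)
  s
}

expect_same_graph <- function(g1, g2, attrs = c("weight", "probability")) {
  expect_setequal(igraph::V(g1)$name, igraph::V(g2)$name)
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    k <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    ord <- order(k)
    out <- data.frame(key = k[ord])
    for (a in attrs)
      out[[a]] <- round(igraph::edge_attr(g, a)[ord], 10)
    out
  }
  expect_equal(key(g1), key(g2))
}
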