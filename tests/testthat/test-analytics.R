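triangle_graph <- function() {
  g <- igraph::make_graph(~ A - B, B - C, A - C)
  igraph::E(g)$weight <- 1
  igraph::E(g)$probability <- 0.5
  g
}

test_that("degree distributions count every vertex and satisfy the handshake lemma", {
  tab <- degree_distribution_table(triangle_graph())
  expect_equal(tab, data.frame(degree = 2L, count = 3L))
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(nrow(degree_distribution_table(empty)), 0L)
  for (seed in 1:5) {
    g <- random_contact_graph(25, 0.15, seed = seed)
    tab <- degree_distribution_table(g)
    expect_equal(sum(tab$count), igraph::vcount(g))
    expect_equal(sum(tab$degree * tab$count), 2L * igraph::ecount(g))
    # per-vertex recount
    expect_equal(
      tab$count,
      as.integer(table(igraph::degree(g))[as.character(tab$degree)]))
  }
})

test_that("clustering attitude matches triple enumeration", {
  ca <- clustering_attitude(triangle_graph())
  expect_equal(unname(ca$coefficient), rep(1, 3))
  expect_equal(unname(ca$triangles), rep(1, 3))
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- LETTERS[1:5]
  expect_equal(clustering_attitude(star)$coefficient[["A"]], 0)
  for (seed in 1:8) {
    g <- random_contact_graph(15, 0.3, seed = seed)
    got <- clustering_attitude(g)
    want <- oracle_clustering(adjacency_of(g))
    expect_equal(unname(got$coefficient), want$coefficient)
    expect_equal(unname(got$triangles), want$triangles)
  }
})

test_that("pagerank matches symmetry and a dense linear-solve oracle", {
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- LETTERS[1:6]
  pr <- pagerank_centrality(ring)
  expect_equal(unname(pr), rep(1 / 6, 6), tolerance = 1e-8)
  star <- igraph::make_star(4, mode = "undirected")
  igraph::V(star)$name <- LETTERS[1:4]
  expect_equal(unname(pagerank_centrality(star, tol = 1e-12)),
               oracle_pagerank(adjacency_of(star)), tolerance = 1e-8)
  for (seed in 1:6) {
    g <- random_contact_graph(20, 0.15, seed = seed)
    got <- pagerank_centrality(g, tol = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-10)
    expect_equal(unname(got), oracle_pagerank(adjacency_of(g)),
                 tolerance = 1e-7)
  }
})

test_that("pagerank handles isolated vertices and reports non-convergence", {
  g <- igraph::make_graph(~ A - B) + igraph::vertex("C")
  pr <- pagerank_centrality(g, tol = 1e-12)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_equal(unname(pr), oracle_pagerank(adjacency_of(g)),
               tolerance = 1e-8)
  expect_lt(pr[["C"]], pr[["A"]])
  big <- random_contact_graph(30, 0.2, seed = 1)
  expect_error(pagerank_centrality(big, tol = 1e-15, max_iter = 2L),
               "2 iterations")
})

test_that("betweenness matches the path-counting oracle, endpoints excluded", {
  path3 <- igraph::make_graph(~ A - B, B - C)
  b <- betweenness_centrality(path3)
  expect_equal(b, c(A = 0, B = 1, C = 0))
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- LETTERS[1:5]
  expect_equal(unname(betweenness_centrality(k5)), rep(0, 5))
  for (seed in 1:8) {
    g <- random_contact_graph(18, 0.2, seed = seed)
    expect_equal(unname(betweenness_centrality(g)),
                 oracle_betweenness(adjacency_of(g)),
                 tolerance = 1e-10)
  }
})

test_that("closeness is component-restricted with zero for isolates", {
  path3 <- igraph::make_graph(~ A - B, B - C)
  expect_equal(closeness_centrality(path3),
               c(A = 2 / 3, B = 1, C = 2 / 3))
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- LETTERS[1:4]
  expect_equal(unname(closeness_centrality(k4)), rep(1, 4))
  two_tri <- igraph::make_graph(~ A - B, B - C, A - C, D - E, E - F, D - F)
  expect_equal(unname(closeness_centrality(two_tri)), rep(1, 6))
  iso <- igraph::make_graph(~ A - B) + igraph::vertex("Z")
  expect_equal(closeness_centrality(iso)[["Z"]], 0)
  for (seed in 1:8) {
    g <- random_contact_graph(20, 0.1, seed = seed)
    expect_equal(unname(closeness_centrality(g)),
                 oracle_closeness(adjacency_of(g)), tolerance = 1e-12)
  }
})

test_that("probability mode prefers the most probable path; hops mode the shortest", {
  g <- igraph::make_graph(~ A - B, A - C, C - B)
  igraph::E(g)$probability <- c(0.2, 0.5, 0.5)
  igraph::E(g)$weight <- 1
  p <- shortest_contact_path(g, "A", "B", mode = "probability")
  expect_equal(p$genes, c("A", "C", "B"))
  expect_equal(p$length, 2)              # -log2(0.25) bits
  h <- shortest_contact_path(g, "A", "B", mode = "hops")
  expect_equal(h$genes, c("A", "B"))
  expect_equal(h$length, 1)
  # bits equal -log2 of the product of probabilities along the path
  expect_equal(p$length,
               -log2(prod(c(0.5, 0.5))))
})

test_that("equal-length paths break ties lexicographically and unreachable pairs are results", {
  diamond <- igraph::make_graph(~ A - B, B - D, A - C, C - D)
  igraph::E(diamond)$probability <- 0.5
  for (mode in c("hops", "probability")) {
    p <- shortest_contact_path(diamond, "A", "D", mode = mode)
    expect_equal(p$genes, c("A", "B", "D"))
  }
  two <- igraph::make_graph(~ A - B) + igraph::vertex("Z")
  u <- shortest_contact_path(two, "A", "Z")
  expect_false(u$reachable)
  expect_equal(u$length, Inf)
  expect_error(shortest_contact_path(two, "A", "nope"), "not in the subgraph")
  same <- shortest_contact_path(two, "A", "A")
  expect_equal(same$length, 0)
})

test_that("single-source distances agree with per-pair paths and the oracle", {
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- LETTERS[1:5]
  igraph::E(star)$probability <- 0.5
  d <- all_shortest_from(star, "A")
  expect_equal(unname(d[-1]), rep(1, 4))
  for (seed in 1:5) {
    g <- random_contact_graph(12, 0.2, seed = seed)
    A <- adjacency_of(g)
    D <- oracle_distances(hop_length_matrix(A))
    src <- igraph::V(g)$name[[1]]
    expect_equal(unname(all_shortest_from(g, src)), unname(D[1, ]))
    for (tgt in igraph::V(g)$name[2:4]) {
      pp <- shortest_contact_path(g, src, tgt)
      expect_equal(pp$length,
                   unname(all_shortest_from(g, src)[[tgt]]))
    }
    # probability mode vs weighted Floyd-Warshall
    W <- matrix(Inf, nrow(A), nrow(A)); diag(W) <- 0
    el <- igraph::as_edgelist(g, names = FALSE)
    if (nrow(el)) {
      len <- -log2(igraph::E(g)$probability)
      for (e in seq_len(nrow(el))) {
        W[el[e, 1], el[e, 2]] <- min(W[el[e, 1], el[e, 2]], len[e])
        W[el[e, 2], el[e, 1]] <- W[el[e, 1], el[e, 2]]
      }
    }
    expect_equal(unname(all_shortest_from(g, src, mode = "probability")),
                 unname(oracle_distances(W)[1, ]), tolerance = 1e-12)
  }
})

test_that("per-gene neighbourhood Jaccard follows set arithmetic with the empty-set convention", {
  s <- contact_store()
  for (g in c("A", "B", "C", "D", "E"))
    upsert_gene(s, g, "chr1", match(g, LETTERS) * 100,
                match(g, LETTERS) * 100 + 50)
  add_contact(s, "ea", "A", "B", 1, 0.5)
  add_contact(s, "ea", "A", "C", 1, 0.5)
  add_contact(s, "eb", "A", "B", 1, 0.5)
  add_contact(s, "eb", "A", "D", 1, 0.5)
  expect_equal(gene_neighbor_jaccard(s, "A", "ea", "eb"), 1 / 3)
  expect_equal(gene_neighbor_jaccard(s, "A", "ea", "ea"), 1)
  expect_equal(gene_neighbor_jaccard(s, "E", "ea", "eb"), 1)
  expect_error(gene_neighbor_jaccard(s, "A", "ea", "zz"),
               "unknown experiment")
  # thresholds apply to both neighbour sets
  add_contact(s, "ea", "A", "D", 5, 0.5)
  add_contact(s, "eb", "A", "E", 5, 0.5)
  expect_equal(gene_neighbor_jaccard(s, "A", "ea", "eb", min_weight = 2),
               0)
})

test_that("the metric dispatcher exposes every supported tag and rejects others", {
  g <- random_contact_graph(10, 0.4, seed = 2)
  for (m in c("degree", "pagerank", "betweenness", "closeness",
              "clustering_coefficient", "triangles")) {
    v <- centrality_map(g, m)
    expect_named(v, igraph::V(g)$name)
    expect_true(all(is.finite(v)))
  }
  expect_error(centrality_map(g, "eigenvector"), "unknown metric")
})

test_that("metric maps and partitions export as two-column CSV", {
  g <- triangle_graph()
  f <- withr::local_tempfile(fileext = ".csv")
  write_gene_map(centrality_map(g, "degree"), f, value_name = "degree")
  df <- read.csv(f)
  expect_equal(names(df), c("gene", "degree"))
  expect_equal(df$degree, rep(2, 3))
  part <- louvain_communities(g, seed = 1)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_gene_map(part, f2)
  expect_equal(names(read.csv(f2)), c("gene", "community"))
})
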