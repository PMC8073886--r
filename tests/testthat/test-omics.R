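# store with enough genes per group for the t statistics
make_omics_fixture <- function(seed = 61) {
  pp <- planted_partition_experiment(60, 2, p_in = 0.35, p_out = 0.05,
                                     seed = seed)
  s <- store_from_records(pp$contacts, "expA")
  ingest_contacts(s, perturb_experiment(pp$contacts, 0.3, seed = seed + 1),
                  "expB")
  up <- names(pp$labels)[pp$labels == 1]
  values <- synth_gene_values(names(pp$labels), up_genes = up,
                              shift = 1, sd = 0.5, seed = seed + 2)
  list(store = s, values = stats::setNames(values$value, values$gene))
}

test_that("direction classification splits strictly above/below the threshold", {
  g <- classify_direction(c(A = 1, B = -2, C = 0))
  expect_equal(g$over, "A")
  expect_equal(g$under, "B")
  expect_equal(g$n_excluded, 1L)
  expect_warning(classify_direction(c(A = 1, B = 2)), "one side")
  # shifting the threshold moves genes monotonically out of `over`
  v <- c(A = -1, B = 0.5, C = 1.5, D = 3)
  sizes <- vapply(c(-2, 0, 1, 2),
                  function(t) length(suppressWarnings(
                    classify_direction(v, t))$over), integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(classify_direction(numeric(0)), "non-empty")
})

test_that("welch group comparison matches the textbook computation", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  tt <- t.test(x, y)  # reference route
  groups <- structure(list(over = c("A", "B", "C"),
                           under = c("D", "E", "F"), n_excluded = 0L),
                      class = "gene_groups")
  values <- stats::setNames(c(x, y), c(groups$over, groups$under))
  s <- contact_store()  # metric map supplied directly, store unused
  r <- metric_by_group(s, "e", "degree", groups, metric_map = values)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(r$mean_over, 2)
  expect_equal(r$var_over, 1)   # sample variance
  expect_equal(r$stdev_over^2, r$var_over, tolerance = 1e-9)
})

test_that("the df=1 compatibility convention reproduces its closed form", {
  groups <- structure(list(over = c("A", "B", "C"),
                           under = c("D", "E", "F"), n_excluded = 0L),
                      class = "gene_groups")
  values <- stats::setNames(c(1, 2, 3, 2, 3, 4), c("A", "B", "C",
                                                   "D", "E", "F"))
  s <- contact_store()
  r <- metric_by_group(s, "e", "degree", groups,
                       p_convention = "paper_compat",
                       metric_map = values)
  expect_equal(r$p_value, 2 * (0.5 - atan(abs(r$t)) / pi),
               tolerance = 1e-12)
  expect_equal(r$df, 1)
})

test_that("swapping groups negates t and preserves p; identical groups give t=0, p=1", {
  fx <- make_omics_fixture()
  groups <- classify_direction(fx$values)
  for (conv in c("welch", "paper_compat")) {
    r <- metric_by_group(fx$store, "expA", "clustering_coefficient",
                         groups, p_convention = conv)
    swapped <- structure(list(over = groups$under, under = groups$over,
                              n_excluded = 0L), class = "gene_groups")
    r2 <- metric_by_group(fx$store, "expA", "clustering_coefficient",
                          swapped, p_convention = conv)
    expect_equal(r2$t, -r$t, tolerance = 1e-12)
    expect_equal(r2$p_value, r$p_value, tolerance = 1e-12)
  }
  same <- stats::setNames(rep(2, 8), sprintf("G%04d", 1:8))
  groups_same <- structure(list(over = sprintf("G%04d", 1:4),
                                under = sprintf("G%04d", 5:8),
                                n_excluded = 0L), class = "gene_groups")
  r0 <- metric_by_group(fx$store, "expA", "degree", groups_same,
                        metric_map = same)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)
})

test_that("small groups and absent genes are handled explicitly", {
  fx <- make_omics_fixture()
  tiny <- structure(list(over = "G0001", under = c("G0002", "G0003"),
                         n_excluded = 0L), class = "gene_groups")
  expect_error(metric_by_group(fx$store, "expA", "degree", tiny),
               ">= 2 genes")
  groups <- classify_direction(fx$values)
  groups$over <- c(groups$over, "NOT_A_GENE")
  r <- metric_by_group(fx$store, "expA", "degree", groups)
  expect_equal(r$n_dropped, 1L)
})

test_that("comparison tables have one internally consistent row per experiment", {
  fx <- make_omics_fixture()
  groups <- classify_direction(fx$values)
  tab <- comparison_table(fx$store, metric = "clustering_coefficient",
                          groups = groups, p_convention = "paper_compat")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$Experiment, c("expA", "expB"))
  expect_equal(tab$Stdev_Over^2, tab$Variance_Over, tolerance = 1e-9)
  expect_equal(tab$Stdev_Under^2, tab$Variance_Under, tolerance = 1e-9)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  one <- comparison_table(fx$store, "expA", metric = "closeness",
                          groups = groups)
  expect_equal(nrow(one), 1L)
})

test_that("the metric is computed once when a precomputed map is reused", {
  fx <- make_omics_fixture()
  groups <- classify_direction(fx$values)
  g <- experiment_subgraph(fx$store, "expA")
  map <- centrality_map(g, "closeness")
  r1 <- metric_by_group(fx$store, "expA", "closeness", groups)
  r2 <- metric_by_group(fx$store, "expA", "closeness", groups,
                        metric_map = map)
  expect_equal(r1$t, r2$t, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("gene lists export one symbol per line and round trip", {
  groups <- structure(list(over = c("GC", "GA", "GB"), under = "GD",
                           n_excluded = 0L), class = "gene_groups")
  stem <- file.path(withr::local_tempdir(), "lists.txt")
  paths <- export_gene_lists(groups, stem)
  expect_length(paths, 2L)
  expect_equal(readLines(paths[[1]]), c("GA", "GB", "GC"))
  expect_equal(readLines(paths[[2]]), "GD")
  g <- igraph::make_graph(~ A - B, B - C, A - C, D - E, E - F, D - F)
  part <- louvain_communities(g, seed = 1)
  pp <- export_gene_lists(part, file.path(withr::local_tempdir(),
                                          "comm.txt"))
  expect_length(pp, 2L)
  expect_setequal(unlist(lapply(pp, readLines)), LETTERS[1:6])
  expect_warning(export_gene_lists(character(0),
                                   file.path(withr::local_tempdir(),
                                             "empty.txt")),
                 "empty")
})
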