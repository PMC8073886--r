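#' Split genes into up- and down-regulated groups
#'
#' Partitions an overlay value map (log fold changes, methylation
#' differences, ...) at a threshold: `over` holds genes strictly above
#' it, `under` genes strictly below; genes exactly at the threshold are
#' excluded and counted. A one-sided result (all genes on the same
#' side) is a warning, not an error.
#'
#' @param values named numeric vector (gene -> value), e.g. from
#'   [read_gene_values()].
#' @param threshold split point (default 0).
#' @return object of class `gene_groups`: list with character vectors
#'   `over` and `under` and the integer `n_excluded`.
#' @export
classify_direction <- function(values, threshold = 0.0) {
  if (!length(values) || is.null(names(values)))
    stopf("'values' must be a non-empty named numeric vector")
  over <- sort(names(values)[values > threshold])
  under <- sort(names(values)[values < threshold])
  n_excluded <- sum(values == threshold)
  if (!length(over) || !length(under))
    warning("all genes fall on one side of the threshold")
  structure(list(over = over, under = under,
                 n_excluded = as.integer(n_excluded)),
            class = "gene_groups")
}

#' @export
print.gene_groups <- function(x, ...) {
  cat(sprintf("<gene_groups> %d over, %d under (%d at threshold)\n",
              length(x$over), length(x$under), x$n_excluded))
  invisible(x)
}

# Two-sided p-value conventions for the group-comparison t statistic.
# "welch": classical Welch-Satterthwaite degrees of freedom.
# "paper_compat": two-sided tail of a t distribution with ONE degree of
# freedom (equivalently a standard Cauchy), i.e.
# p = 2 * (0.5 - atan(|t|)/pi) — a convention kept for compatibility
# with published tables produced by an earlier implementation.
pvalue_from_t <- function(t_stat, df, convention = c("welch",
                                                     "paper_compat")) {
  convention <- match.arg(convention)
  if (convention == "paper_compat") df <- 1
  2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
}

#' Compare a node metric between up- and down-regulated genes
#'
#' Computes one graph metric on the experiment subgraph, restricts it
#' to the two overlay groups (genes absent from the experiment are
#' dropped and counted), and summarises each group (mean, sample
#' variance, standard deviation) together with the Welch two-sample t
#' statistic `t = (mean_over - mean_under) / se`. Two p-value
#' conventions are offered: `"welch"` (two-sided,
#' Welch-Satterthwaite df; the statistically standard choice and the
#' default) and `"paper_compat"` (two-sided under df = 1, i.e. a
#' standard Cauchy reference — reproduces the p-values of earlier
#' published tables and is flagged as a compatibility quirk, not a
#' recommendation).
#'
#' @param store a [contact_store()].
#' @param experiment experiment name.
#' @param metric a [centrality_map()] tag: `"clustering_coefficient"`,
#'   `"triangles"`, `"closeness"`, `"degree"`, `"pagerank"` or
#'   `"betweenness"`.
#' @param groups a `gene_groups` object from [classify_direction()].
#' @param p_convention `"welch"` (default) or `"paper_compat"`.
#' @param metric_map optional precomputed metric map (named numeric) to
#'   reuse across calls; when supplied the metric is not recomputed.
#' @param ... passed to [centrality_map()].
#' @return object of class `group_comparison`: experiment, metric,
#'   per-group n/mean/variance/stdev, `t`, `df`, `p_value`,
#'   `p_convention`, and counts of dropped genes.
#' @export
metric_by_group <- function(store, experiment, metric, groups,
                            p_convention = c("welch", "paper_compat"),
                            metric_map = NULL, ...) {
  stopifnot(inherits(groups, "gene_groups"))
  p_convention <- match.arg(p_convention)
  values <- if (is.null(metric_map))
    centrality_map(experiment_subgraph(store, experiment), metric, ...)
  else metric_map
  x <- values[intersect(groups$over, names(values))]
  y <- values[intersect(groups$under, names(values))]
  dropped <- (length(groups$over) - length(x)) +
    (length(groups$under) - length(y))
  if (length(x) < 2L || length(y) < 2L)
    stopf("each group needs >= 2 genes present in experiment '%s' (got %d over, %d under)",
          experiment, length(x), length(y))
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / length(x) + vy / length(y)
  if (se2 == 0) {
    t_stat <- 0
    df <- length(x) + length(y) - 2
  } else {
    t_stat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                     (vy / length(y))^2 / (length(y) - 1))
  }
  p <- if (se2 == 0) 1.0 else pvalue_from_t(t_stat, df, p_convention)
  structure(list(experiment = experiment, metric = metric,
                 n_over = length(x), n_under = length(y),
                 mean_over = mean(x), mean_under = mean(y),
                 var_over = vx, var_under = vy,
                 stdev_over = sqrt(vx), stdev_under = sqrt(vy),
                 t = t_stat,
                 df = if (p_convention == "paper_compat") 1 else df,
                 p_value = p, p_convention = p_convention,
                 n_dropped = as.integer(dropped)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s / %s: over %.4g (n=%d), under %.4g (n=%d), t = %.3f, p = %.3f [%s]\n",
    x$experiment, x$metric, x$mean_over, x$n_over, x$mean_under,
    x$n_under, x$t, x$p_value, x$p_convention))
  invisible(x)
}

#' Group-comparison table across experiments
#'
#' One [metric_by_group()] row per experiment, in the layout of the
#' published comparison tables: per-group Mean, Variance and Stdev
#' columns followed by the t statistic and p-value.
#'
#' @inheritParams metric_by_group
#' @param experiments character vector of experiment names (default:
#'   all registered).
#' @return data.frame with columns `Experiment`, `Metric`,
#'   `Mean_Over`, `Mean_Under`, `Variance_Over`, `Variance_Under`,
#'   `Stdev_Over`, `Stdev_Under`, `t`, `p_value`, `n_over`, `n_under`.
#' @export
comparison_table <- function(store, experiments = NULL, metric, groups,
                             p_convention = c("welch", "paper_compat"),
                             ...) {
  stopifnot(inherits(store, "contact_store"))
  p_convention <- match.arg(p_convention)
  if (is.null(experiments)) experiments <- experiment_names(store)
  rows <- lapply(experiments, function(e) {
    r <- metric_by_group(store, e, metric, groups,
                         p_convention = p_convention, ...)
    data.frame(Experiment = e, Metric = metric,
               Mean_Over = r$mean_over, Mean_Under = r$mean_under,
               Variance_Over = r$var_over, Variance_Under = r$var_under,
               Stdev_Over = r$stdev_over, Stdev_Under = r$stdev_under,
               t = r$t, p_value = r$p_value,
               n_over = r$n_over, n_under = r$n_under,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export gene lists for external enrichment tools
#'
#' Writes plain-text gene lists (one symbol per line) suitable for
#' upload to enrichment services; the package exports lists only and
#' never calls a web service. Accepts a `gene_groups` (two files, one
#' per group), a `gene_partition` (one file per community) or a plain
#' character vector / named metric map (one file).
#'
#' @param x `gene_groups`, `gene_partition`, named numeric map or
#'   character vector.
#' @param path output file path; for multi-file exports it is used as a
#'   stem (`<stem>_over.txt`, `<stem>_community3.txt`, ...).
#' @return character vector of the file paths written, invisibly.
#' @export
export_gene_lists <- function(x, path) {
  write_list <- function(genes, p) {
    if (!length(genes)) warning(sprintf("empty gene list written to %s", p))
    writeLines(sort(unique(genes)), p)
    p
  }
  stem <- sub("\\.[A-Za-z0-9]+$", "", path)
  ext <- if (grepl("\\.[A-Za-z0-9]+$", path))
    sub(".*(\\.[A-Za-z0-9]+)$", "\\1", path) else ".txt"
  paths <- if (inherits(x, "gene_groups")) {
    c(write_list(x$over, paste0(stem, "_over", ext)),
      write_list(x$under, paste0(stem, "_under", ext)))
  } else if (inherits(x, "gene_partition")) {
    vapply(sort(unique(x$membership)), function(cm)
      write_list(names(x$membership)[x$membership == cm],
                 paste0(stem, "_community", cm, ext)),
      character(1L))
  } else if (is.character(x)) {
    write_list(x, path)
  } else if (is.numeric(x) && !is.null(names(x))) {
    write_list(names(x), path)
  } else stopf("unsupported input type for export_gene_lists()")
  invisible(paths)
}
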