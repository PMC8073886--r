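#' Configuration for the synthetic contact-network generator
#'
#' Defines a synthetic gene universe and a Hi-C-like contact process:
#' genes laid out sequentially along chromosomes, an intra-chromosomal
#' contact probability decaying with linear (gene-index) distance d as
#' `intra_base * (1 + d)^(-decay_alpha)`, a constant inter-chromosomal
#' base rate, geometric read-count weights (mode 1, long tail — the
#' shape of read-support counts) and uniform edge probabilities on
#' \[0.05, 1\]. The seed is mandatory: the generator has no hidden
#' entropy and identical configs give byte-identical output.
#'
#' Defaults give a few-hundred-gene genome whose subgraphs have the
#' qualitative features of gene-centric Hi-C networks (dense
#' near-diagonal neighbourhoods, sparse trans contacts, heavy-tailed
#' degree) at a size every test can afford.
#'
#' @param n_genes number of genes (default 300).
#' @param n_chromosomes number of chromosomes; genes are split evenly
#'   (default 3).
#' @param gene_length_mean mean synthetic gene length in bp
#'   (exponential; default 20000).
#' @param gene_gap_mean mean intergenic gap in bp (default 5000).
#' @param decay_alpha distance-decay exponent alpha >= 0 (default 1.0).
#' @param intra_base intra-chromosomal contact probability at distance
#'   0 (default 0.5).
#' @param inter_rate constant inter-chromosomal contact probability
#'   (default 0.002).
#' @param weight_geom_prob success probability of the geometric weight
#'   distribution (default 0.5).
#' @param seed integer RNG seed (mandatory).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 300L, n_chromosomes = 3L,
                         gene_length_mean = 20000, gene_gap_mean = 5000,
                         decay_alpha = 1.0, intra_base = 0.5,
                         inter_rate = 0.002, weight_geom_prob = 0.5,
                         seed) {
  if (missing(seed)) stopf("'seed' is mandatory: no hidden entropy")
  assert_scalar_number(n_genes, "n_genes", min = 2)
  assert_scalar_number(n_chromosomes, "n_chromosomes", min = 1)
  assert_scalar_number(decay_alpha, "decay_alpha", min = 0)
  assert_scalar_number(intra_base, "intra_base", min = 0, max = 1)
  assert_scalar_number(inter_rate, "inter_rate", min = 0, max = 1)
  assert_scalar_number(weight_geom_prob, "weight_geom_prob", min = 0,
                       max = 1, closed_min = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 gene_length_mean = gene_length_mean,
                 gene_gap_mean = gene_gap_mean,
                 decay_alpha = decay_alpha, intra_base = intra_base,
                 inter_rate = inter_rate,
                 weight_geom_prob = weight_geom_prob,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# deterministic synthetic gene layout for a config
synth_genes <- function(config) {
  n <- config$n_genes
  chrom_of <- rep(seq_len(config$n_chromosomes),
                  each = ceiling(n / config$n_chromosomes))[seq_len(n)]
  lens <- pmax(200, round(stats::rexp(n, 1 / config$gene_length_mean)))
  gaps <- pmax(1, round(stats::rexp(n, 1 / config$gene_gap_mean)))
  starts <- ends <- numeric(n)
  for (c in seq_len(config$n_chromosomes)) {
    idx <- which(chrom_of == c)
    pos <- 0
    for (i in idx) {
      starts[[i]] <- pos
      ends[[i]] <- pos + lens[[i]]
      pos <- ends[[i]] + gaps[[i]]
    }
  }
  data.frame(symbol = sprintf("G%04d", seq_len(n)),
             chromosome = paste0("chr", chrom_of),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Generate one synthetic Hi-C experiment
#'
#' Draws contacts over the config's gene universe: every same-chromosome
#' gene pair at index distance d contacts with probability
#' `intra_base * (1 + d)^(-decay_alpha)`; every cross-chromosome pair
#' with probability `inter_rate`. Contact weights are geometric
#' (shifted to be >= 1), edge probabilities uniform on \[0.05, 1\].
#' Fully deterministic under the config seed.
#'
#' @param config a [synth_config()].
#' @return list with `contacts` (canonical contact-record data.frame)
#'   and `genes` (symbol/chromosome/start/end data.frame).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    genes <- synth_genes(config)
    n <- nrow(genes)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pairs[, 1L]; j <- pairs[, 2L]
    same <- genes$chromosome[i] == genes$chromosome[j]
    p <- ifelse(same,
                config$intra_base * (1 + abs(i - j))^(-config$decay_alpha),
                config$inter_rate)
    keep <- stats::runif(length(p)) < p
    i <- i[keep]; j <- j[keep]
    w <- stats::rgeom(sum(keep), config$weight_geom_prob) + 1
    pr <- stats::runif(sum(keep), 0.05, 1.0)
    contacts <- data.frame(
      Gene1 = genes$symbol[i], Chr1 = genes$chromosome[i],
      Start1 = genes$start[i], End1 = genes$end[i],
      Gene2 = genes$symbol[j], Chr2 = genes$chromosome[j],
      Start2 = genes$start[j], End2 = genes$end[j],
      Weight = w, Probability = pr, stringsAsFactors = FALSE)
    contacts <- contacts[order(contacts$Gene1, contacts$Gene2), ,
                         drop = FALSE]
    rownames(contacts) <- NULL
    list(contacts = contacts, genes = genes)
  })
}

#' Rewire a fraction of an experiment's contacts
#'
#' Produces a pseudo-replicate: removes `floor(f * E)` edges uniformly
#' at random and adds the same number of fresh gene pairs (not present
#' in the base edge set), drawing weights and probabilities from the
#' generator's distributions. The expected edge-set Jaccard similarity
#' against the base experiment is `(1 - f) / (1 + f)` — the knob used
#' to emulate time-series replicates with a controlled similarity
#' matrix.
#'
#' @param records base contact-record data.frame.
#' @param fraction rewiring fraction f in \[0, 1\].
#' @param seed integer RNG seed.
#' @param weight_geom_prob geometric parameter for replacement weights
#'   (default 0.5).
#' @return a contact-record data.frame of the same size.
#' @export
perturb_experiment <- function(records, fraction, seed,
                               weight_geom_prob = 0.5) {
  assert_scalar_number(fraction, "fraction", min = 0, max = 1)
  if (missing(seed)) stopf("'seed' is mandatory")
  e_total <- nrow(records)
  n_rewire <- floor(fraction * e_total)
  if (n_rewire == 0L) return(records)
  gene_cols <- unique(rbind(
    stats::setNames(records[, c("Gene1", "Chr1", "Start1", "End1")],
                    c("symbol", "chromosome", "start", "end")),
    stats::setNames(records[, c("Gene2", "Chr2", "Start2", "End2")],
                    c("symbol", "chromosome", "start", "end"))))
  gene_cols <- gene_cols[!duplicated(gene_cols$symbol), , drop = FALSE]
  gene_cols <- gene_cols[order(gene_cols$symbol), , drop = FALSE]
  n_genes <- nrow(gene_cols)
  if (choose(n_genes, 2) - e_total < n_rewire)
    stopf("graph too dense to add %d fresh pairs over %d genes",
          n_rewire, n_genes)
  base_keys <- pair_key(records$Gene1, records$Gene2)
  with_seed(seed, {
    drop_idx <- sample.int(e_total, n_rewire)
    kept <- records[-drop_idx, , drop = FALSE]
    new_keys <- character(0)
    new_i <- new_j <- integer(0)
    while (length(new_keys) < n_rewire) {
      need <- n_rewire - length(new_keys)
      ci <- sample.int(n_genes, 2 * need, replace = TRUE)
      cj <- sample.int(n_genes, 2 * need, replace = TRUE)
      ok <- ci != cj
      ci <- ci[ok]; cj <- cj[ok]
      keys <- pair_key(gene_cols$symbol[ci], gene_cols$symbol[cj])
      fresh <- !(keys %in% base_keys) & !(keys %in% new_keys) &
        !duplicated(keys)
      take <- which(fresh)[seq_len(min(need, sum(fresh)))]
      new_keys <- c(new_keys, keys[take])
      new_i <- c(new_i, ci[take]); new_j <- c(new_j, cj[take])
    }
    added <- data.frame(
      Gene1 = gene_cols$symbol[new_i], Chr1 = gene_cols$chromosome[new_i],
      Start1 = gene_cols$start[new_i], End1 = gene_cols$end[new_i],
      Gene2 = gene_cols$symbol[new_j], Chr2 = gene_cols$chromosome[new_j],
      Start2 = gene_cols$start[new_j], End2 = gene_cols$end[new_j],
      Weight = stats::rgeom(n_rewire, weight_geom_prob) + 1,
      Probability = stats::runif(n_rewire, 0.05, 1.0),
      stringsAsFactors = FALSE)
    swap <- added$Gene1 > added$Gene2
    if (any(swap)) {
      tmp <- added[swap, c("Gene1", "Chr1", "Start1", "End1")]
      added[swap, c("Gene1", "Chr1", "Start1", "End1")] <-
        added[swap, c("Gene2", "Chr2", "Start2", "End2")]
      added[swap, c("Gene2", "Chr2", "Start2", "End2")] <- tmp
    }
    out <- rbind(kept[, names(added)], added)
    out <- out[order(out$Gene1, out$Gene2), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Planted-partition contact network with known communities
#'
#' Ground truth for community-recovery checks: genes are split into k
#' equal communities; same-community pairs contact with probability
#' `p_in`, cross-community pairs with `p_out < p_in`. Weights and
#' probabilities are drawn as in [generate_experiment()].
#'
#' @param n_genes number of genes.
#' @param k_communities number of planted communities.
#' @param p_in,p_out within/between contact probabilities;
#'   `p_in > p_out` required.
#' @param seed integer RNG seed.
#' @return list with `contacts`, `genes` and `labels` (named integer
#'   vector of planted community ids).
#' @export
planted_partition_experiment <- function(n_genes, k_communities,
                                         p_in, p_out, seed) {
  assert_scalar_number(p_in, "p_in", min = 0, max = 1)
  assert_scalar_number(p_out, "p_out", min = 0, max = 1)
  if (p_in <= p_out) stopf("p_in (%s) must exceed p_out (%s)",
                           format(p_in), format(p_out))
  if (missing(seed)) stopf("'seed' is mandatory")
  with_seed(seed, {
    labels <- rep(seq_len(k_communities),
                  length.out = n_genes)[order(rep(seq_len(k_communities),
                                                  length.out = n_genes))]
    genes <- data.frame(
      symbol = sprintf("G%04d", seq_len(n_genes)),
      chromosome = "chr1",
      start = (seq_len(n_genes) - 1) * 25000,
      end = (seq_len(n_genes) - 1) * 25000 + 20000,
      stringsAsFactors = FALSE)
    names(labels) <- genes$symbol
    pairs <- which(upper.tri(matrix(0, n_genes, n_genes)),
                   arr.ind = TRUE)
    i <- pairs[, 1L]; j <- pairs[, 2L]
    p <- ifelse(labels[i] == labels[j], p_in, p_out)
    keep <- stats::runif(length(p)) < p
    i <- i[keep]; j <- j[keep]
    contacts <- data.frame(
      Gene1 = genes$symbol[i], Chr1 = genes$chromosome[i],
      Start1 = genes$start[i], End1 = genes$end[i],
      Gene2 = genes$symbol[j], Chr2 = genes$chromosome[j],
      Start2 = genes$start[j], End2 = genes$end[j],
      Weight = stats::rgeom(sum(keep), 0.5) + 1,
      Probability = stats::runif(sum(keep), 0.05, 1.0),
      stringsAsFactors = FALSE)
    contacts <- contacts[order(contacts$Gene1, contacts$Gene2), ,
                         drop = FALSE]
    rownames(contacts) <- NULL
    list(contacts = contacts, genes = genes, labels = labels)
  })
}

#' Synthetic overlay values with a group mean shift
#'
#' Draws a gene-value table (the shape read by [read_gene_values()])
#' with normal values per gene; genes in `up_genes` get mean `+shift`,
#' the rest mean `-shift`. Used to exercise the omics-overlay layer
#' with a known effect size.
#'
#' @param symbols character vector of gene symbols.
#' @param up_genes subset of `symbols` forming the shifted group.
#' @param shift half-distance between group means (default 1).
#' @param sd within-group standard deviation (default 1).
#' @param seed integer RNG seed.
#' @return data.frame with columns `gene` and `value`.
#' @export
synth_gene_values <- function(symbols, up_genes = character(),
                              shift = 1, sd = 1, seed) {
  if (missing(seed)) stopf("'seed' is mandatory")
  with_seed(seed, {
    mu <- ifelse(symbols %in% up_genes, shift, -shift)
    data.frame(gene = symbols,
               value = stats::rnorm(length(symbols), mean = mu, sd = sd),
               stringsAsFactors = FALSE)
  })
}
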