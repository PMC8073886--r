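# Brute-force oracles, independent of the package's implementation
# paths: dense matrix algorithms written directly from the definitions.

# Floyd-Warshall shortest-path distances. `W`: matrix with edge lengths
# (Inf where no edge), 0 on the diagonal.
oracle_distances <- function(W) {
  n <- nrow(W)
  D <- W
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

hop_length_matrix <- function(A) {
  W <- ifelse(A > 0, 1, Inf)
  diag(W) <- 0
  W
}

# number of shortest s->t paths, by DP in order of increasing distance
oracle_path_counts <- function(A) {
  D <- oracle_distances(hop_length_matrix(A))
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    finite <- which(is.finite(D[s, ]) & D[s, ] > 0)
    for (t in finite[order(D[s, finite])]) {
      preds <- which(A[, t] > 0 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  list(D = D, sigma = sigma)
}

# betweenness from the definition: sum over pairs s < t (both != v) of
# the fraction of shortest s-t paths through v
oracle_betweenness <- function(A) {
  pc <- oracle_path_counts(A)
  D <- pc$D; sigma <- pc$sigma
  n <- nrow(A)
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        if (s == v || t == v || !is.finite(D[s, t])) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t])
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  b
}

oracle_closeness <- function(A) {
  D <- oracle_distances(hop_length_matrix(A))
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    dv <- D[v, -v]
    reach <- is.finite(dv)
    if (!any(reach)) return(0)
    sum(reach) / sum(dv[reach])
  }, numeric(1))
}

# local clustering coefficient and triangle count by triple enumeration
oracle_clustering <- function(A) {
  n <- nrow(A)
  tri <- numeric(n)
  coef <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k >= 2) {
      cnt <- 0
      for (a in seq_len(k - 1))
        for (b in seq(a + 1, k))
          if (A[nb[a], nb[b]] > 0) cnt <- cnt + 1
      tri[v] <- cnt
      coef[v] <- 2 * cnt / (k * (k - 1))
    }
  }
  list(coefficient = coef, triangles = tri)
}

# PageRank by dense linear solve, same dangling convention as the
# package (dangling mass redistributed uniformly)
oracle_pagerank <- function(A, damping = 0.85) {
  n <- nrow(A)
  s <- rowSums(A)
  P <- matrix(0, n, n)
  nz <- s > 0
  P[nz, ] <- A[nz, , drop = FALSE] / s[nz]
  Pt <- t(P)
  dang <- matrix(0, n, n)
  dang[, !nz] <- 1 / n
  x <- solve(diag(n) - damping * (Pt + dang), rep((1 - damping) / n, n))
  x / sum(x)
}

# hand-computed adjusted Rand index from the contingency table
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  exp_idx <- sa * sb / choose(n, 2)
  max_idx <- (sa + sb) / 2
  if (max_idx == exp_idx) return(1)
  (sij - exp_idx) / (max_idx - exp_idx)
}
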