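# Shared fixtures and independent numerical oracles.

# Unit-weight triangle.
triangle_graph <- function() {
  cell_graph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
                    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
}

# Unit-weight path a - c - b (c in the middle), node order a, b, c so that
# degrees are (1, 1, 2).
path_graph <- function() {
  A <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  A["a", "c"] <- A["c", "a"] <- 1
  A["b", "c"] <- A["c", "b"] <- 1
  cell_graph(A)
}

# Dense random weighted graph (always connected).
random_graph <- function(n, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  cell_graph(W)
}

# Matrix exponential by scaling-and-squaring of the Taylor series —
# independent of the package's eigendecomposition route.
expm_ref <- function(M, terms = 30, squarings = 20) {
  M <- M / 2^squarings
  S <- diag(nrow(M))
  P <- diag(nrow(M))
  for (k in seq_len(terms)) {
    P <- P %*% M / k
    S <- S + P
  }
  for (k in seq_len(squarings)) S <- S %*% S
  S
}

# Continuous Markov stability straight from its definition: stationary
# distribution, series matrix exponential, explicit double sum.
stability_ref <- function(G, partition, t) {
  A <- as.matrix(G$adjacency)
  d <- rowSums(A)
  Lrw <- diag(nrow(A)) - A / d
  P <- expm_ref(-t * Lrw)
  pi_ <- d / sum(d)
  s <- 0
  for (u in seq_along(d)) for (v in seq_along(d))
    if (partition[u] == partition[v])
      s <- s + pi_[u] * P[u, v] - pi_[u] * pi_[v]
  unname(s)
}

# Random partition of n nodes into at most k groups (all groups occupied
# labels need not be contiguous; VI and stability are label-invariant).
random_partition <- function(n, k, seed) {
  set.seed(seed)
  sample.int(k, n, replace = TRUE)
}
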