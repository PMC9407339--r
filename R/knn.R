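#' Build a weighted k-nearest-neighbour cell graph
#'
#' Computes pairwise distances between cells (rows of `points`), links every
#' cell to its `k` nearest neighbours, symmetrises by union (an edge is kept
#' if either endpoint lists the other), and weights edges by the chosen
#' scheme:
#'
#' * `"fuzzy-local-kernel"` (default): a locally scaled exponential kernel in
#'   the spirit of UMAP's fuzzy simplicial set. Each cell `u` gets a
#'   connectivity radius `rho_u` (distance to its nearest neighbour) and a
#'   bandwidth `sigma_u` calibrated by bisection so that
#'   `sum_v exp(-max(0, d_uv - rho_u)/sigma_u) = log2(k)` over its `k`
#'   neighbours; directed weights are combined by the fuzzy union
#'   `w = w_uv + w_vu - w_uv * w_vu`.
#' * `"gaussian-kernel"`: locally scaled heat kernel
#'   `w = exp(-d^2 / (s_u s_v))` with `s_u` the distance of `u` to its k-th
#'   neighbour.
#' * `"unit"`: all kept edges get weight 1.
#'
#' @param points numeric matrix, cells in rows, features in columns.
#' @param k number of neighbours, `1 <= k < nrow(points)`.
#' @param metric `"euclidean"`, `"cosine"` or `"pearson-correlation-distance"`
#'   (1 minus the Pearson correlation of feature profiles).
#' @param weighting edge-weight scheme, see above.
#' @return a [cell_graph] whose node ids are the rownames of `points`.
#' @examples
#' pts <- matrix(c(0, 1, 3), ncol = 1)
#' build_knn_graph(pts, k = 1, metric = "euclidean", weighting = "unit")
#' @export
build_knn_graph <- function(points, k,
                            metric = c("euclidean", "cosine",
                                       "pearson-correlation-distance"),
                            weighting = c("fuzzy-local-kernel",
                                          "gaussian-kernel", "unit")) {
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 cells to build a graph")
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k >= n)
    stop("k must satisfy 1 <= k < number of cells (got k=", k, ", n=", n, ")")
  k <- as.integer(k)
  ids <- rownames(points) %||% paste0("cell_", seq_len(n))

  D <- pairwise_distances(points, metric)
  diag(D) <- Inf
  # k nearest neighbours per node, ties broken by index
  nn_idx <- t(apply(D, 1L, function(row) order(row)[seq_len(k)]))
  nn_dist <- matrix(D[cbind(rep(seq_len(n), k), as.vector(nn_idx))], n, k)

  i <- rep(seq_len(n), k)
  j <- as.vector(nn_idx)
  w <- switch(weighting,
    "unit" = rep(1, length(i)),
    "gaussian-kernel" = {
      s <- pmax(nn_dist[, k], .Machine$double.eps)
      exp(-as.vector(nn_dist)^2 / (s[i] * s[j]))
    },
    "fuzzy-local-kernel" = fuzzy_weights(nn_dist, k)
  )
  W <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  Wt <- Matrix::t(W)
  A <- if (weighting == "fuzzy-local-kernel") {
    W + Wt - W * Wt            # fuzzy union of directed memberships
  } else {
    pmax_sparse(W, Wt)         # union; symmetric schemes give equal values
  }
  dimnames(A) <- list(ids, ids)
  cell_graph(A, node_ids = ids)
}

# Directed fuzzy membership weights, rows of nn_dist = distances to the k
# nearest neighbours of each node (ascending).
fuzzy_weights <- function(nn_dist, k) {
  n <- nrow(nn_dist)
  target <- log2(max(k, 2))
  w <- matrix(1, n, k)
  for (u in seq_len(n)) {
    d <- nn_dist[u, ]
    rho <- d[1]
    adj <- pmax(d - rho, 0)
    if (all(adj == 0)) { w[u, ] <- 1; next }
    lo <- 1e-12; hi <- max(adj)
    while (sum(exp(-adj / hi)) < target) hi <- hi * 2
    for (it in 1:64) {
      mid <- (lo + hi) / 2
      if (sum(exp(-adj / mid)) > target) hi <- mid else lo <- mid
    }
    w[u, ] <- exp(-adj / ((lo + hi) / 2))
  }
  as.vector(w)
}

# Entry-wise maximum of two sparse non-negative matrices.
pmax_sparse <- function(X, Y) {
  U <- X + Y
  V <- methods::as(methods::as(U, "generalMatrix"), "TsparseMatrix")
  xi <- X[cbind(V@i + 1L, V@j + 1L)]
  yi <- Y[cbind(V@i + 1L, V@j + 1L)]
  V@x <- pmax(xi, yi)
  methods::as(V, "CsparseMatrix")
}

pairwise_distances <- function(points, metric) {
  n <- nrow(points)
  switch(metric,
    "euclidean" = as.matrix(stats::dist(points)),
    "cosine" = {
      nrm <- sqrt(rowSums(points^2))
      if (any(nrm == 0))
        stop("cosine metric undefined for all-zero cells: ",
             paste(utils::head(which(nrm == 0), 5), collapse = ", "))
      S <- tcrossprod(points / nrm)
      D <- 1 - pmin(pmax(S, -1), 1)
      D[D < 0] <- 0
      D
    },
    "pearson-correlation-distance" = {
      v <- apply(points, 1L, stats::var)
      if (any(v == 0))
        stop("pearson-correlation-distance undefined for zero-variance cells: ",
             paste(utils::head(which(v == 0), 5), collapse = ", "))
      D <- 1 - stats::cor(t(points))
      D[D < 0] <- 0
      D
    })
}
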