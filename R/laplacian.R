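#' Graph Laplacians
#'
#' Returns one of the three standard Laplacians of a weighted graph with
#' adjacency `A` and degree matrix `D = diag(d)`:
#' combinatorial `L = D - A`, symmetrically normalised
#' `Lsym = D^{-1/2} L D^{-1/2}`, or random-walk `Lrw = D^{-1} L`.
#'
#' @param G a [cell_graph].
#' @param kind `"combinatorial"`, `"normalized"` or `"random-walk"`.
#' @return a sparse square matrix over the nodes of `G`.
#' @examples
#' g <- cell_graph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
#' laplacian(g, "combinatorial")
#' @export
laplacian <- function(G, kind = c("combinatorial", "normalized", "random-walk")) {
  kind <- match.arg(kind)
  A <- G$adjacency
  d <- G$degrees
  L <- Matrix::Diagonal(x = d) - A
  out <- switch(kind,
    "combinatorial" = L,
    "normalized"    = {
      s <- 1 / sqrt(d)
      Matrix::Diagonal(x = s) %*% L %*% Matrix::Diagonal(x = s)
    },
    "random-walk"   = Matrix::Diagonal(x = 1 / d) %*% L)
  dimnames(out) <- list(G$node_ids, G$node_ids)
  out
}

#' Degree-weighted mean and variance of a graph signal
#'
#' The graph mean is `mu_G(g) = sum_v d_v g(v) / sum_v d_v`; the graph
#' variance is `Var_G(g) = sum_v d_v (g(v) - mu_G(g))^2`. These are the
#' moments of the signal under the stationary distribution of the random
#' walk (up to the total-degree normalisation of the variance).
#'
#' @param g numeric signal, one value per node.
#' @param G a [cell_graph].
#' @return list with `mean` and `variance`.
#' @export
signal_moments <- function(g, G) {
  g <- drop(signal_matrix(g, G))
  d <- G$degrees
  mu <- sum(g * d) / sum(d)
  list(mean = mu, variance = sum(d * (g - mu)^2))
}

#' Rayleigh quotient of a graph signal
#'
#' For the combinatorial form,
#' `R(g) = sum_{u~v} A_uv (g(u)-g(v))^2 / sum_u g(u)^2`; the normalised form
#' divides instead by the degree-weighted norm `sum_u g(u)^2 d_u` (the
#' quotient of the normalised Laplacian applied to `D^{1/2} g`). Zero for
#' constant signals; large for signals that vary wildly across edges. The
#' normalised form lies in `[0, 2]`.
#'
#' @param g numeric signal over the nodes (must be non-zero).
#' @param G a [cell_graph].
#' @param normalized use the degree-normalised denominator?
#' @return non-negative scalar.
#' @export
rayleigh_quotient <- function(g, G, normalized = FALSE) {
  g <- drop(signal_matrix(g, G))
  if (all(g == 0)) stop("Rayleigh quotient undefined for the zero signal")
  L <- laplacian(G, "combinatorial")
  num <- as.numeric(g %*% (L %*% g))
  den <- if (normalized) sum(g^2 * G$degrees) else sum(g^2)
  max(num, 0) / den
}

#' Laplacian score of graph signals
#'
#' The Laplacian score of a signal `g` is the normalised Rayleigh quotient of
#' the graph-mean-centred signal:
#' `LS(g) = sum_{u~v} A_uv (g(u)-g(v))^2 / Var_G(g)`.
#' It is invariant under affine maps `g -> a g + b` (`a != 0`) and undefined
#' for constant signals. Low scores flag signals that are locally smooth but
#' globally varying, i.e. consistent with the graph structure.
#'
#' @param g numeric signal or a [gene_signals] set (scored row-wise).
#' @param G a [cell_graph].
#' @return scalar for a single signal, otherwise a named vector.
#' @export
laplacian_score <- function(g, G) {
  X <- signal_matrix(g, G)
  d <- G$degrees
  mu <- as.numeric(X %*% d) / sum(d)
  Xc <- X - mu
  v <- as.numeric((Xc^2) %*% d)
  bad <- v <= 0
  if (any(bad))
    stop("Laplacian score undefined for constant signals: ",
         paste(utils::head(rownames(X)[bad] %||% which(bad), 5), collapse = ", "))
  L <- laplacian(G, "combinatorial")
  num <- Matrix::rowSums((Xc %*% L) * Xc)
  out <- pmax(as.numeric(num), 0) / v
  if (nrow(X) == 1 && is.null(rownames(X))) out else stats::setNames(out, rownames(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
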