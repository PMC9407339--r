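#' Low-frequency eigenbasis of the normalised Laplacian
#'
#' Computes the ascending eigenpairs `(lambda_i, e_i)` of the symmetrically
#' normalised Laplacian. For a connected graph `lambda_0 = 0` with
#' eigenvector proportional to `D^{1/2} 1`. Each eigenvector's sign is fixed
#' so that its largest-magnitude entry is positive, making outputs
#' reproducible (eigenscores are intrinsically sign-ambiguous).
#'
#' Eigenvalues below `trivial_tol` are flagged as trivial: for a graph with
#' `c` connected components the zero eigenvalue has multiplicity `c`, and
#' the corresponding eigenvectors carry no signal-ranking information.
#'
#' @param G a [cell_graph].
#' @param count number of smallest eigenpairs to keep (mutually exclusive
#'   with `max_eigenvalue`).
#' @param max_eigenvalue keep all eigenpairs with `lambda_i < max_eigenvalue`
#'   plus the trivial pair(s); the default 0.1 targets the low-frequency
#'   regime used for gene-space embeddings.
#' @param trivial_tol eigenvalues below this count as zero.
#' @return object of class `spectral_basis`: `eigenvalues`, `eigenvectors`
#'   (orthonormal columns), `degree_sqrt`, `trivial` (logical per pair).
#' @export
spectral_basis <- function(G, count = NULL, max_eigenvalue = NULL,
                           trivial_tol = 1e-10) {
  n <- n_nodes(G)
  if (is.null(count) && is.null(max_eigenvalue)) max_eigenvalue <- 0.1
  if (!is.null(count) && !is.null(max_eigenvalue))
    stop("give either count or max_eigenvalue, not both")
  if (!is.null(count) && (count < 1 || count > n))
    stop("count must be in [1, ", n, "]")
  if (!is.null(max_eigenvalue) && max_eigenvalue <= 0)
    stop("max_eigenvalue must be positive")

  Lsym <- as.matrix(laplacian(G, "normalized"))
  es <- eigen(Lsym, symmetric = TRUE)
  ord <- order(es$values)             # ascending
  lam <- pmax(es$values[ord], 0)
  vec <- es$vectors[, ord, drop = FALSE]

  keep <- if (!is.null(count)) seq_len(count)
          else which(lam < max_eigenvalue | lam < trivial_tol)
  lam <- lam[keep]
  vec <- vec[, keep, drop = FALSE]

  # sign convention: largest-magnitude entry positive
  for (i in seq_along(lam)) {
    piv <- which.max(abs(vec[, i]))
    if (vec[piv, i] < 0) vec[, i] <- -vec[, i]
  }
  ncomp <- sum(lam < trivial_tol)
  if (ncomp > 1)
    warning("graph is disconnected: eigenvalue 0 has multiplicity ", ncomp)
  rownames(vec) <- G$node_ids
  structure(list(eigenvalues = lam, eigenvectors = vec,
                 degree_sqrt = sqrt(G$degrees),
                 trivial = lam < trivial_tol),
            class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat("spectral_basis: ", length(x$eigenvalues), " eigenpairs, lambda in [",
      format(min(x$eigenvalues), digits = 4), ", ",
      format(max(x$eigenvalues), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Eigenscores of gene signals
#'
#' The i-th eigenscore of a signal `g` is the cosine between the
#' degree-lifted signal `D^{1/2} g` and the i-th eigenvector of the
#' normalised Laplacian: `eig_i(g) = <D^{1/2} g, e_i> / ||D^{1/2} g||`.
#' Values lie in `[-1, 1]`; with a complete basis the squared eigenscores
#' sum to 1 and `R(D^{1/2} g) = sum_i lambda_i eig_i(g)^2`, so eigenscores
#' decompose the Rayleigh quotient by graph frequency.
#'
#' @param signals a [gene_signals] set (or numeric matrix/vector).
#' @param basis a [spectral_basis].
#' @return object of class `eigenscore_matrix`: `gene_ids`, `scores`
#'   (genes x basis dimension), `eigenvalues`, `trivial`.
#' @export
eigenscores <- function(signals, basis) {
  X <- if (inherits(signals, "gene_signals")) signals$values else {
    if (is.vector(signals)) matrix(signals, nrow = 1) else as.matrix(signals)
  }
  if (ncol(X) != nrow(basis$eigenvectors))
    stop("signals have ", ncol(X), " cells but basis has ",
         nrow(basis$eigenvectors))
  lifted <- X * rep(basis$degree_sqrt, each = nrow(X))
  nrm <- sqrt(rowSums(lifted^2))
  if (any(nrm == 0))
    stop("eigenscore undefined for all-zero signals: ",
         paste(utils::head((rownames(X) %||% seq_len(nrow(X)))[nrm == 0], 5),
               collapse = ", "))
  S <- (lifted %*% basis$eigenvectors) / nrm
  colnames(S) <- paste0("eig_", seq_len(ncol(S)) - 1L)
  structure(list(gene_ids = rownames(X) %||% paste0("gene_", seq_len(nrow(X))),
                 scores = S, eigenvalues = basis$eigenvalues,
                 trivial = basis$trivial),
            class = "eigenscore_matrix")
}

#' @export
print.eigenscore_matrix <- function(x, ...) {
  cat("eigenscore_matrix: ", length(x$gene_ids), " genes x ",
      ncol(x$scores), " eigenscores\n", sep = "")
  invisible(x)
}

default_dims <- function(E) which(!E$trivial)

#' Rank genes by eigenscore norm
#'
#' Sorts genes by the descending Euclidean norm of their eigenscores over
#' the selected (non-trivial) coordinates. Signals aligned with
#' low-frequency structure score near 1; noise signals plot near the
#' origin. Ties are broken by lexicographic gene id.
#'
#' @param E an [eigenscores] result.
#' @param dims integer indices into the basis (1-based positions in the
#'   score matrix, excluding trivial coordinates by default).
#' @return data.frame with `gene_id`, `norm`, `rank`.
#' @export
rank_by_eigenscore_norm <- function(E, dims = default_dims(E)) {
  if (length(dims) == 0) stop("dims must be non-empty")
  if (any(dims < 1 | dims > ncol(E$scores))) stop("dims out of basis range")
  nrm <- sqrt(rowSums(E$scores[, dims, drop = FALSE]^2))
  ord <- order(-nrm, E$gene_ids)
  data.frame(gene_id = E$gene_ids[ord], norm = nrm[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Eigenscore coordinates for embedding
#'
#' Returns the selected eigenscore columns as a plain matrix, ready for any
#' downstream 2-D embedding or plotting tool; no transformation is applied.
#'
#' @inheritParams rank_by_eigenscore_norm
#' @return numeric matrix, genes x `length(dims)`.
#' @export
eigenscore_embedding_matrix <- function(E, dims = default_dims(E)) {
  if (length(dims) && any(dims < 1 | dims > ncol(E$scores)))
    stop("dims out of basis range")
  M <- E$scores[, dims, drop = FALSE]
  if (nrow(M) == length(E$gene_ids)) rownames(M) <- E$gene_ids
  M
}

#' Write eigenscores as TSV with basis metadata JSON
#'
#' @param E an [eigenscores] result.
#' @param path output TSV (columns `gene_id`, `eig_*`, `norm`).
#' @param meta_path optional JSON path for eigenvalues and selector info.
#' @param selector free-form description stored in the metadata.
#' @export
write_eigenscores <- function(E, path, meta_path = NULL, selector = NULL) {
  nrm <- sqrt(rowSums(E$scores[, default_dims(E), drop = FALSE]^2))
  df <- data.frame(gene_id = E$gene_ids,
                   format(E$scores, digits = 10, trim = TRUE),
                   norm = format(nrm, digits = 10, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    jsonlite::write_json(list(eigenvalues = E$eigenvalues,
                              trivial = E$trivial,
                              selector = selector %||% "unspecified"),
                         meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
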