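#' Weighted cell-similarity graph
#'
#' A `cell_graph` is an undirected, weighted graph whose nodes are cells and
#' whose edge weights encode transcriptional similarity. It is the substrate
#' for every score in the package. The adjacency matrix must be symmetric,
#' non-negative, with a zero diagonal, and every node must have positive
#' degree (isolated nodes carry no information for any Laplacian-based score
#' and are rejected).
#'
#' @param adjacency square symmetric non-negative matrix (base or
#'   [Matrix::Matrix]) with zero diagonal; `dimnames` supply node ids.
#' @param node_ids optional character vector of cell identifiers; defaults to
#'   the adjacency dimnames or `"cell_1" ...`.
#' @param tol relative tolerance for the symmetry check.
#' @return An object of class `cell_graph` with elements `node_ids`,
#'   `adjacency` (a sparse `dgCMatrix`) and `degrees`.
#' @examples
#' A <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
#' g <- cell_graph(A)
#' g$degrees
#' @export
cell_graph <- function(adjacency, node_ids = NULL, tol = 1e-8) {
  A <- methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  n <- nrow(A)
  if (n != ncol(A)) stop("adjacency must be square")
  if (is.null(node_ids)) {
    node_ids <- rownames(adjacency)
    if (is.null(node_ids)) node_ids <- paste0("cell_", seq_len(n))
  }
  if (length(node_ids) != n) stop("node_ids length does not match adjacency")
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  if (any(A@x < 0)) stop("adjacency weights must be non-negative")
  scale <- max(abs(A@x), 1)
  if (max(abs(A - Matrix::t(A))) > tol * scale)
    stop("adjacency must be symmetric (relative tolerance ", tol, ")")
  A <- (A + Matrix::t(A)) / 2     # exact symmetry
  if (any(Matrix::diag(A) != 0)) {
    if (max(Matrix::diag(A)) > tol * scale)
      stop("adjacency must have a zero diagonal (no self-loops)")
    Matrix::diag(A) <- 0
    A <- Matrix::drop0(A)
  }
  d <- Matrix::rowSums(A)
  if (any(d <= 0))
    stop("isolated nodes (zero degree): ",
         paste(utils::head(node_ids[d <= 0], 5), collapse = ", "))
  dimnames(A) <- list(node_ids, node_ids)
  structure(list(node_ids = node_ids, adjacency = A, degrees = stats::setNames(d, node_ids)),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  m <- Matrix::nnzero(x$adjacency) / 2
  cat("cell_graph: ", length(x$node_ids), " nodes, ", m, " edges, ",
      "total weight ", format(sum(x$degrees) / 2, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Number of nodes of a cell graph
#' @param G a [cell_graph].
#' @return integer node count.
#' @export
n_nodes <- function(G) length(G$node_ids)

#' Named set of gene signals over a graph
#'
#' Wraps a genes-by-cells real matrix: one row per gene, one column per node
#' of the companion graph. A gene's expression across cells is a graph
#' signal, i.e. a real-valued function on the nodes.
#'
#' @param values numeric matrix, genes in rows, cells in columns.
#' @param gene_ids optional character vector of gene names (defaults to
#'   rownames).
#' @return An object of class `gene_signals`.
#' @export
gene_signals <- function(values, gene_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  }
  if (length(gene_ids) != nrow(values)) stop("gene_ids length does not match values")
  if (anyDuplicated(gene_ids)) {
    gene_ids <- make.unique(gene_ids, sep = "-")
    warning("duplicate gene ids disambiguated by suffixing")
  }
  if (!all(is.finite(values))) stop("signal values must be finite")
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  structure(list(gene_ids = gene_ids, values = values), class = "gene_signals")
}

#' @export
print.gene_signals <- function(x, ...) {
  cat("gene_signals: ", nrow(x$values), " genes x ", ncol(x$values), " cells\n", sep = "")
  invisible(x)
}

# Check a signal set against a graph; returns the matrix.
signal_matrix <- function(signals, G) {
  if (inherits(signals, "gene_signals")) signals <- signals$values
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  if (ncol(signals) != n_nodes(G))
    stop("signal has ", ncol(signals), " columns but graph has ", n_nodes(G), " nodes")
  signals
}

#' Write a graph as an undirected TSV edge list
#'
#' One line per unordered pair: `node_u<TAB>node_v<TAB>weight`.
#'
#' @param G a [cell_graph].
#' @param path output file.
#' @export
write_edge_list <- function(G, path) {
  A <- methods::as(Matrix::triu(G$adjacency), "TsparseMatrix")
  ord <- order(A@i, A@j)
  df <- data.frame(u = G$node_ids[A@i[ord] + 1L],
                   v = G$node_ids[A@j[ord] + 1L],
                   w = format(A@x[ord], digits = 10, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a graph from an undirected TSV edge list
#'
#' @param path file with lines `node_u<TAB>node_v<TAB>weight`.
#' @return a [cell_graph].
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("u", "v", "w"),
                          colClasses = c("character", "character", "numeric"))
  ids <- sort(unique(c(df$u, df$v)))
  i <- match(df$u, ids); j <- match(df$v, ids)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(df$w, df$w),
                            dims = c(length(ids), length(ids)),
                            dimnames = list(ids, ids))
  cell_graph(A, node_ids = ids)
}
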