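#' Integer filtration of a cell graph
#'
#' A filtration assigns an integer `f(v)` to every node; the sublevel set
#' `alpha(i) = {v : f(v) <= i}` induces a nested sequence of subgraphs.
#' For developmental time the interesting direction is usually "reverse
#' time": see [filtration_from_time()].
#'
#' @param values integer filtration value per node.
#' @param node_ids optional node identifiers (defaults to names of
#'   `values`).
#' @return object of class `filtration`.
#' @export
filtration <- function(values, node_ids = NULL) {
  if (is.null(node_ids)) node_ids <- names(values)
  v <- as.integer(round(values))
  if (any(abs(values - v) > 1e-8)) stop("filtration values must be integers")
  if (!is.null(node_ids) && length(node_ids) != length(v))
    stop("node_ids length does not match values")
  structure(list(values = v, node_ids = node_ids), class = "filtration")
}

#' Reverse-time filtration from a time column
#'
#' Converts per-cell (developmental) times into the reverse-time filtration
#' `f = max(t) - t`, so that the latest cells enter first and sublevel sets
#' grow backwards in time — the direction in which a bifurcation appears as
#' components merging.
#'
#' @param times numeric per-cell times (coerced to integers).
#' @param node_ids optional node identifiers.
#' @return a [filtration].
#' @export
filtration_from_time <- function(times, node_ids = NULL) {
  filtration(max(times) - times, node_ids = node_ids %||% names(times))
}

check_filtration <- function(f, G) {
  if (inherits(f, "filtration")) {
    if (!is.null(f$node_ids)) {
      m <- match(G$node_ids, f$node_ids)
      if (anyNA(m)) stop("filtration is missing values for some graph nodes")
      return(f$values[m])
    }
    f <- f$values
  }
  f <- as.integer(f)
  if (length(f) != n_nodes(G))
    stop("filtration has ", length(f), " values but graph has ", n_nodes(G),
         " nodes")
  f
}

#' Sublevel node set and induced subgraph
#'
#' Returns `alpha(i) = {v : f(v) <= i}` and the subgraph of `G` induced on
#' those nodes (every edge with both endpoints in the sublevel set).
#' Induced subgraphs may be disconnected and may contain isolated nodes;
#' degrees are reported as-is.
#'
#' @param G a [cell_graph].
#' @param f a [filtration] (or integer vector over nodes).
#' @param i filtration index.
#' @return list with `nodes` (character ids), `index` (positions in `G`),
#'   `adjacency` (induced weight matrix).
#' @export
filtered_subgraph <- function(G, f, i) {
  fv <- check_filtration(f, G)
  idx <- which(fv <= i)
  if (length(idx) == 0)
    stop("sublevel set alpha(", i, ") is empty (min filtration value is ",
         min(fv), ")")
  list(nodes = G$node_ids[idx], index = idx,
       adjacency = G$adjacency[idx, idx, drop = FALSE])
}

#' Kron reduction (0-degree persistent Laplacian) of a Laplacian matrix
#'
#' The Kron reduction of `L` onto a node subset `alpha` is the Schur
#' complement `L_alpha = L[a,a] - L[a,ac] L[ac,ac]^{-1} L[ac,a]` with
#' `ac` the complement. It is again a Laplacian: symmetric, annihilating
#' the ones vector, with non-positive off-diagonals — the Laplacian of a
#' reduced graph on `alpha` that preserves effective connectivity through
#' the eliminated nodes. Requires every connected component of the graph
#' to contain at least one node of `alpha` (otherwise `L[ac,ac]` is
#' singular).
#'
#' @param L square Laplacian matrix (combinatorial or normalised).
#' @param alpha integer indices (or logical mask) of the retained nodes.
#' @return object of class `reduced_laplacian`: `matrix`, `kept_nodes`,
#'   and `degrees` (diagonal of the reduced combinatorial Laplacian).
#' @export
kron_reduce <- function(L, alpha) {
  L <- as.matrix(L)
  n <- nrow(L)
  if (is.logical(alpha)) alpha <- which(alpha)
  alpha <- sort(unique(as.integer(alpha)))
  if (length(alpha) == 0) stop("alpha must be non-empty")
  if (any(alpha < 1 | alpha > n)) stop("alpha indices out of range")
  comp <- graph_components(abs(L) * (1 - diag(n)))
  orphan <- setdiff(unique(comp), unique(comp[alpha]))
  if (length(orphan))
    stop("connected component(s) ", paste(orphan, collapse = ", "),
         " lie entirely outside alpha; L[ac,ac] is singular")
  ac <- setdiff(seq_len(n), alpha)
  R <- if (length(ac) == 0) {
    L[alpha, alpha, drop = FALSE]
  } else {
    L[alpha, alpha, drop = FALSE] -
      L[alpha, ac, drop = FALSE] %*%
        solve(L[ac, ac, drop = FALSE], L[ac, alpha, drop = FALSE])
  }
  R <- (R + t(R)) / 2
  # clip floating-point positives off the diagonal (valid Laplacian has
  # non-positive off-diagonals)
  off <- R - diag(diag(R), nrow(R))
  slack <- 1e-10 * max(abs(R), 1)
  if (any(off > slack))
    warning("Kron reduction produced positive off-diagonals above slack; worst = ",
            max(off))
  pos <- off > 0
  if (any(pos)) {
    zero_rowsums <- all(abs(rowSums(L)) <= slack)  # combinatorial input
    R[pos & row(R) != col(R)] <- 0
    if (zero_rowsums) diag(R) <- -(rowSums(R) - diag(R))
  }
  kept <- rownames(L)[alpha] %||% alpha
  dimnames(R) <- if (is.character(kept)) list(kept, kept) else NULL
  structure(list(matrix = R, kept_nodes = kept,
                 degrees = diag(R), source = NULL),
            class = "reduced_laplacian")
}

#' @export
print.reduced_laplacian <- function(x, ...) {
  cat("reduced_laplacian: ", nrow(x$matrix), " kept nodes",
      if (!is.null(x$source)) paste0(" (persistent pair i=", x$source[1],
                                     ", j=", x$source[2], ")"), "\n", sep = "")
  invisible(x)
}

#' (i, j)-persistent Laplacian of a filtered graph
#'
#' Builds the Laplacian (combinatorial or symmetrically normalised) of the
#' induced subgraph `G[alpha(j)]` and Kron-reduces it onto the earlier
#' sublevel set `alpha(i)` (`i <= j`). For `i = j` this is the plain
#' Laplacian of `G[alpha(i)]`. Its nullity equals the persistent Betti-0
#' number of the inclusion `G[alpha(i)] <= G[alpha(j)]`.
#'
#' @param G a [cell_graph].
#' @param f a [filtration].
#' @param i,j filtration indices with `i <= j`.
#' @param normalized reduce the normalised rather than combinatorial
#'   Laplacian?
#' @return a [kron_reduce()] result with `source = c(i, j)`.
#' @export
persistent_laplacian <- function(G, f, i, j, normalized = FALSE) {
  if (i > j) stop("need i <= j (got i=", i, ", j=", j, ")")
  fv <- check_filtration(f, G)
  sub_j <- filtered_subgraph(G, fv, j)
  Aj <- sub_j$adjacency
  dj <- Matrix::rowSums(Aj)
  Lj <- Matrix::Diagonal(x = dj) - Aj
  if (normalized) {
    s <- ifelse(dj > 0, 1 / sqrt(dj), 0)   # isolated nodes stay zero rows
    Lj <- Matrix::Diagonal(x = s) %*% Lj %*% Matrix::Diagonal(x = s)
  }
  Lj <- as.matrix(Lj)
  dimnames(Lj) <- list(sub_j$nodes, sub_j$nodes)
  keep <- which(fv[sub_j$index] <= i)
  if (length(keep) == 0)
    stop("sublevel set alpha(", i, ") is empty")
  out <- kron_reduce(Lj, keep)
  out$source <- c(i, j)
  out
}

#' Persistent Betti-0 number of a filtered graph
#'
#' The number of connected components of `G[alpha(i)]` that remain
#' disconnected from each other in `G[alpha(j)]`, computed by union-find
#' (equivalently: the number of components of `G[alpha(j)]` containing at
#' least one node of `alpha(i)`). Equals the nullity of the
#' `(i,j)`-persistent Laplacian.
#'
#' @inheritParams persistent_laplacian
#' @return non-negative integer.
#' @export
persistent_betti0 <- function(G, f, i, j) {
  if (i > j) stop("need i <= j")
  fv <- check_filtration(f, G)
  sub_j <- filtered_subgraph(G, fv, j)
  parent <- seq_along(sub_j$index)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  A <- methods::as(methods::as(sub_j$adjacency, "generalMatrix"), "TsparseMatrix")
  for (e in seq_along(A@x)) {
    ru <- find(A@i[e] + 1L); rv <- find(A@j[e] + 1L)
    if (ru != rv) parent[ru] <- rv
  }
  roots <- vapply(seq_along(parent), find, 1L)
  length(unique(roots[fv[sub_j$index] <= i]))
}

#' Persistent Rayleigh quotient of gene signals
#'
#' For a graph with filtration `f` and `i <= j`, the persistent Rayleigh
#' quotient of a signal `g` (implicitly restricted to `alpha(i)`) is
#' `PRQ(g) = <g, L_ij g> / <g, g>` with `L_ij` the combinatorial
#' `(i,j)`-persistent Laplacian; the normalised form divides by
#' `<g, D_ij g>` instead, where `D_ij` holds the degrees of the
#' Kron-reduced graph. Comparing persistent (`i < j`) with full (`i = j`)
#' quotients separates signals by their role in a bifurcation:
#' parent-plus-one-daughter genes land above the persistent-vs-full
#' diagonal, both-daughters-only genes below it, single-daughter genes on
#' it.
#'
#' @param signals a [gene_signals] set (or matrix/vector over all graph
#'   nodes).
#' @param G a [cell_graph].
#' @param f a [filtration].
#' @param i,j filtration indices with `i <= j`.
#' @param normalized use the degree-normalised denominator?
#' @return named numeric vector, one non-negative value per gene.
#' @export
prq <- function(signals, G, f, i, j, normalized = TRUE) {
  X <- signal_matrix(signals, G)
  fv <- check_filtration(f, G)
  red <- persistent_laplacian(G, fv, i, j, normalized = FALSE)
  idx <- which(fv <= i)
  Xr <- X[, idx, drop = FALSE]
  L <- red$matrix
  den <- if (normalized) as.numeric((Xr^2) %*% red$degrees) else rowSums(Xr^2)
  bad <- den <= 0
  if (any(bad))
    stop("persistent Rayleigh quotient undefined (zero restricted signal",
         if (normalized) " or support only on zero-degree reduced nodes", "): ",
         paste(utils::head((rownames(X) %||% seq_len(nrow(X)))[bad], 5),
               collapse = ", "))
  num <- pmax(rowSums((Xr %*% L) * Xr), 0)
  stats::setNames(num / den, rownames(X))
}

#' Batch persistent Rayleigh quotients over filtration pairs
#'
#' Evaluates [prq()] for every `(i, j)` pair, e.g. for birth-death-style
#' scatter plots of persistent vs full quotients. Genes for which a pair is
#' undefined (zero restricted signal) get `NA` in that column and are
#' listed in the `failures` attribute rather than dropped.
#'
#' @param signals a [gene_signals] set.
#' @param G a [cell_graph].
#' @param f a [filtration].
#' @param pairs list of `c(i, j)` integer pairs (or a 2-column matrix).
#' @param normalized use the degree-normalised form?
#' @return data.frame with `gene_id` and one `prq_i_j` column per pair;
#'   attribute `failures` is a data.frame of gene/pair/message records.
#' @export
prq_map <- function(signals, G, f, pairs, normalized = TRUE) {
  X <- signal_matrix(signals, G)
  gene_ids <- rownames(X) %||% paste0("gene_", seq_len(nrow(X)))
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  cols <- list(gene_id = gene_ids)
  failures <- list()
  fv <- check_filtration(f, G)
  for (p in pairs) {
    cn <- paste0("prq_", p[1], "_", p[2])
    col <- rep(NA_real_, nrow(X))
    res <- tryCatch(prq(X, G, fv, p[1], p[2], normalized = normalized),
                    error = function(e) e)
    if (inherits(res, "error")) {
      # per-gene retry so one bad gene does not void the column
      for (g in seq_len(nrow(X))) {
        r <- tryCatch(prq(X[g, , drop = FALSE], G, fv, p[1], p[2],
                          normalized = normalized),
                      error = function(e) e)
        if (inherits(r, "error")) {
          failures[[length(failures) + 1]] <-
            data.frame(gene_id = gene_ids[g], pair = cn,
                       message = conditionMessage(r),
                       stringsAsFactors = FALSE)
        } else col[g] <- r
      }
    } else col <- as.numeric(res)
    cols[[length(cols) + 1]] <- col
    names(cols)[length(cols)] <- cn
  }
  out <- data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures)
                           else data.frame(gene_id = character(), pair = character(),
                                           message = character())
  out
}

#' Read a filtration from TSV
#'
#' Expected format: two tab-separated columns `cell_id<TAB>integer_value`,
#' no header.
#'
#' @param path input file.
#' @return a [filtration].
#' @export
read_filtration <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("cell_id", "value"),
                          colClasses = c("character", "integer"))
  filtration(df$value, node_ids = df$cell_id)
}

#' Write a filtration to TSV
#' @param f a [filtration] with node ids.
#' @param path output file.
#' @export
write_filtration <- function(f, path) {
  if (is.null(f$node_ids)) stop("filtration has no node ids to write")
  utils::write.table(data.frame(f$node_ids, f$values), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
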