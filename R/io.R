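#' Read an expression matrix
#'
#' Supported formats:
#' * `"mtx-dir"`: a directory in the CellRanger convention containing
#'   `matrix.mtx` (Matrix Market triplet, genes x cells), `genes.tsv` (or
#'   `features.tsv`) and `barcodes.tsv`.
#' * `"dense-csv"` / `"dense-tsv"`: a dense table with a header row of cell
#'   ids and gene ids in the first column.
#'
#' Genes are rows and cells are columns throughout. Duplicate gene ids are
#' disambiguated by suffixing; all-zero genes or cells are reported via a
#' message but kept.
#'
#' @param path directory (for `mtx-dir`) or file path.
#' @param format one of `"mtx-dir"`, `"dense-csv"`, `"dense-tsv"`; guessed
#'   from the path when omitted.
#' @return a [gene_signals] object with cell ids as column names.
#' @export
read_expression <- function(path, format = c("auto", "mtx-dir", "dense-csv",
                                             "dense-tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx-dir"
              else if (grepl("\\.csv$", path)) "dense-csv" else "dense-tsv"
  }
  if (format == "mtx-dir") {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx in ", path)
    genes_f <- file.path(path, "genes.tsv")
    if (!file.exists(genes_f)) genes_f <- file.path(path, "features.tsv")
    bc_f <- file.path(path, "barcodes.tsv")
    if (!file.exists(genes_f) || !file.exists(bc_f))
      stop("mtx-dir needs genes.tsv (or features.tsv) and barcodes.tsv")
    M <- as.matrix(Matrix::readMM(mtx))
    genes <- utils::read.table(genes_f, sep = "\t", header = FALSE,
                               colClasses = "character")[[1]]
    cells <- utils::read.table(bc_f, sep = "\t", header = FALSE,
                               colClasses = "character")[[1]]
    if (length(genes) != nrow(M))
      stop("genes.tsv has ", length(genes), " entries but matrix has ",
           nrow(M), " rows")
    if (length(cells) != ncol(M))
      stop("barcodes.tsv has ", length(cells), " entries but matrix has ",
           ncol(M), " columns")
    rownames(M) <- genes; colnames(M) <- cells
  } else {
    sep <- if (format == "dense-csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                            check.names = FALSE)
    bad <- !vapply(df, is.numeric, TRUE)
    if (any(bad))
      stop("non-numeric entries in columns: ",
           paste(utils::head(colnames(df)[bad], 5), collapse = ", "))
    M <- as.matrix(df)
  }
  empty_genes <- sum(rowSums(abs(M)) == 0)
  empty_cells <- sum(colSums(abs(M)) == 0)
  if (empty_genes || empty_cells)
    message(empty_genes, " all-zero genes and ", empty_cells,
            " all-zero cells in ", path)
  gene_signals(M)
}

#' Write an expression matrix as a Matrix Market directory
#'
#' Inverse of [read_expression()] for the `mtx-dir` format.
#'
#' @param signals a [gene_signals] object.
#' @param dir output directory (created if needed).
#' @export
write_expression_mtx <- function(signals, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  M <- methods::as(methods::as(Matrix::Matrix(signals$values, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(M, file.path(dir, "matrix.mtx"))
  writeLines(signals$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(colnames(signals$values) %||%
               paste0("cell_", seq_len(ncol(signals$values))),
             file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Normalise, select highly variable genes, and reduce dimension
#'
#' Applies the chosen normalisation (`"none"`, `"log1p"` for
#' `log(x + 1)`, or `"tpm-log1p"` which rescales each cell to a fixed
#' total before the log transform), ranks genes by dispersion
#' (variance / (mean + 1e-8) of the normalised values) and keeps the
#' `n_hvg` most variable, and optionally projects cells onto the first
#' `n_pcs` principal components for graph building. The signals returned
#' for scoring are the retained normalised genes, not the principal
#' components.
#'
#' @param raw a [gene_signals] object of raw counts/expression.
#' @param normalization `"none"`, `"log1p"` or `"tpm-log1p"`.
#' @param n_hvg number of highly variable genes to keep (clipped with a
#'   warning if it exceeds the gene count); `Inf` keeps all.
#' @param n_pcs number of principal components for the feature matrix; 0
#'   uses the genes directly.
#' @param scale_total target per-cell total for `"tpm-log1p"`
#'   (default 1e4).
#' @return list with `features` (cells x features matrix for
#'   [build_knn_graph()]) and `signals` (retained [gene_signals] for
#'   scoring).
#' @export
preprocess <- function(raw, normalization = c("none", "log1p", "tpm-log1p"),
                       n_hvg = Inf, n_pcs = 0, scale_total = 1e4) {
  normalization <- match.arg(normalization)
  M <- raw$values
  if (normalization == "tpm-log1p") {
    tot <- colSums(M)
    if (any(tot == 0)) stop("all-zero cells cannot be total-count normalised")
    M <- log1p(t(t(M) / tot * scale_total))
  } else if (normalization == "log1p") {
    M <- log1p(M)
  }
  if (is.finite(n_hvg)) {
    if (n_hvg > nrow(M)) {
      warning("n_hvg = ", n_hvg, " exceeds gene count ", nrow(M), "; clipped")
      n_hvg <- nrow(M)
    }
    mu <- rowMeans(M)
    disp <- apply(M, 1, stats::var) / (mu + 1e-8)
    keep <- order(-disp, rownames(M))[seq_len(n_hvg)]
    M <- M[sort(keep), , drop = FALSE]
  }
  features <- t(M)
  if (n_pcs > 0) {
    n_pcs <- min(n_pcs, ncol(features) - 1, nrow(features) - 1)
    features <- stats::prcomp(features, center = TRUE,
                              rank. = n_pcs)$x
  }
  list(features = features, signals = gene_signals(M))
}

#' Pipeline run configuration
#'
#' Collects every tunable of the standard pipeline with serialisable
#' defaults: input paths, normalisation, gene selection, graph
#' construction, and the method-specific blocks (eigenscore selector,
#' Markov-time grid, filtration pairs). A config round-trips through
#' [write_run_config()] / [read_run_config()] unchanged.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    expression = "",
    graph = "",
    filtration = "",
    output_dir = ".",
    normalization = "log1p",
    n_hvg = 10000,
    n_pcs = 30,
    subsample_cells = 0,
    knn_k = 15,
    metric = "euclidean",
    weighting = "fuzzy-local-kernel",
    eigen_max_eigenvalue = 0.1,
    eigen_count = 0,
    t_min = 1e-2,
    t_max = 1e2,
    n_times = 100,
    runs = 20,
    seed = 1,
    prq_pairs = "",
    prq_normalized = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Checks that every non-empty input path exists and that numeric fields
#' are in range.
#'
#' @param cfg a [run_config].
#' @return the config, invisibly; errors on problems.
#' @export
validate_run_config <- function(cfg) {
  for (key in c("expression", "graph", "filtration")) {
    p <- cfg[[key]]
    if (nzchar(p) && !file.exists(p))
      stop("config path does not exist: ", key, " = ", p)
  }
  if (cfg$knn_k < 1) stop("knn_k must be >= 1")
  if (cfg$runs < 2) stop("runs must be >= 2")
  if (cfg$t_min <= 0 || cfg$t_max <= cfg$t_min)
    stop("need 0 < t_min < t_max")
  invisible(cfg)
}

#' Write a run configuration as TOML
#'
#' Flat `key = value` TOML (strings quoted, booleans lowercase).
#'
#' @param cfg a [run_config].
#' @param path output file.
#' @export
write_run_config <- function(cfg, path) {
  fmt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    val <- if (is.character(v)) paste0('"', v, '"')
           else if (is.logical(v)) tolower(as.character(v))
           else format(v, digits = 15)
    paste0(k, " = ", val)
  }, "")
  writeLines(fmt, path)
  invisible(path)
}

#' Read a run configuration from TOML
#'
#' Parses the flat `key = value` subset of TOML written by
#' [write_run_config()] (strings, numbers, booleans; `#` comments).
#'
#' @param path input file.
#' @return a [run_config].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    out[[key]] <-
      if (grepl('^".*"$', val)) sub('^"(.*)"$', "\\1", val)
      else if (val %in% c("true", "false")) val == "true"
      else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) stop("cannot parse config value: ", ln)
        num
      }
  }
  do.call(run_config, out)
}
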