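#' Stationary distribution of the random walk on a cell graph
#'
#' The continuous-time random walk generated by the random-walk Laplacian
#' has stationary distribution `pi_v = d_v / sum_u d_u`. It is unique only
#' on connected graphs; request `per_component = TRUE` to obtain one
#' distribution per connected component.
#'
#' @param G a [cell_graph].
#' @param per_component return a list of per-component distributions?
#' @return probability vector over nodes (or a list of them).
#' @export
stationary_distribution <- function(G, per_component = FALSE) {
  comp <- graph_components(G$adjacency)
  d <- G$degrees
  if (max(comp) > 1L) {
    if (!per_component)
      stop("graph is disconnected (", max(comp),
           " components); stationary distribution is not unique. ",
           "Use per_component = TRUE.")
    return(lapply(seq_len(max(comp)), function(c) {
      idx <- comp == c
      stats::setNames(d[idx] / sum(d[idx]), G$node_ids[idx])
    }))
  }
  stats::setNames(d / sum(d), G$node_ids)
}

# Connected components of a sparsity pattern; integer labels 1..c.
graph_components <- function(A) {
  n <- nrow(A)
  Ap <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- Ap@i[seq.int(Ap@p[v] + 1L, length.out = Ap@p[v + 1L] - Ap@p[v])] + 1L
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Symmetric spectral factorisation of the random-walk generator, reused
# across Markov times: Lrw = D^{-1/2} (U diag(lam) U') D^{1/2}.
rw_spectrum <- function(G) {
  es <- eigen(as.matrix(laplacian(G, "normalized")), symmetric = TRUE)
  list(U = es$vectors, lambda = pmax(es$values, 0),
       d = G$degrees, sqrt_d = sqrt(G$degrees))
}

#' Continuous-time transition kernel (heat kernel) of a cell graph
#'
#' Computes `P(t) = exp(-t Lrw)` via the symmetric conjugate
#' eigendecomposition of the random-walk Laplacian. `P(t)` is
#' row-stochastic, satisfies the semigroup property
#' `P(t) P(s) = P(t + s)`, obeys detailed balance
#' `d_u P(t)_{uv} = d_v P(t)_{vu}`, and converges to `1 pi^T` as
#' `t -> Inf`. Entries that come out slightly negative from floating-point
#' round-off (above `-1e-12`) are clipped to zero.
#'
#' @param G a [cell_graph].
#' @param t Markov time, `t >= 0`.
#' @param spectrum optional precomputed spectrum (internal reuse).
#' @return object of class `transition_kernel` with fields `time` and
#'   `matrix`.
#' @export
heat_kernel <- function(G, t, spectrum = NULL) {
  if (!is.numeric(t) || length(t) != 1 || t < 0)
    stop("Markov time t must be a single non-negative number")
  sp <- spectrum %||% rw_spectrum(G)
  E <- sp$U %*% (exp(-t * sp$lambda) * t(sp$U))
  P <- (1 / sp$sqrt_d) * E * rep(sp$sqrt_d, each = length(sp$sqrt_d))
  if (min(P) < -1e-12 * max(abs(P)))
    warning("heat kernel entries below clipping slack; worst = ", min(P))
  P[P < 0] <- 0
  dimnames(P) <- list(G$node_ids, G$node_ids)
  structure(list(time = t, matrix = P), class = "transition_kernel")
}

#' @export
print.transition_kernel <- function(x, ...) {
  cat("transition_kernel: t = ", x$time, ", ", nrow(x$matrix), " nodes\n", sep = "")
  invisible(x)
}

# Symmetrised Markov-stability quality matrix
# B(t) = Pi P(t) - pi pi^T  with Pi = diag(pi).
quality_matrix <- function(G, t, spectrum = NULL) {
  sp <- spectrum %||% rw_spectrum(G)
  half <- sp$U * rep(exp(-t * sp$lambda / 2), each = nrow(sp$U))
  E <- tcrossprod(half)                       # U exp(-t lam) U'
  sd <- sp$sqrt_d / sqrt(sum(sp$d))
  B <- sd * E * rep(sd, each = length(sd))    # = Pi P(t), symmetric
  pi_ <- sp$d / sum(sp$d)
  B <- B - tcrossprod(pi_)
  (B + t(B)) / 2
}

#' Markov stability of a partition
#'
#' The continuous Markov stability of a partition at time `t` is
#' `sum_{u,v} (pi_u P(t)_{uv} - pi_u pi_v) delta(c_u, c_v)`: the
#' probability that a stationary random walker stays within its community
#' over time `t`, minus the chance that two independent stationary walkers
#' occupy the same community. Values lie in `(-1/2, 1]`; the one-community
#' partition always scores 0.
#'
#' @param G a [cell_graph].
#' @param partition integer community labels, one per node (all communities
#'   non-empty; labels are permutation-invariant).
#' @param t Markov time.
#' @param spectrum optional precomputed spectrum.
#' @return scalar stability value.
#' @export
markov_stability <- function(G, partition, t, spectrum = NULL) {
  partition <- check_partition(partition, n_nodes(G))
  B <- quality_matrix(G, t, spectrum)
  s <- 0
  for (c in unique(partition)) {
    idx <- partition == c
    s <- s + sum(B[idx, idx])
  }
  s
}

check_partition <- function(partition, n) {
  if (length(partition) != n)
    stop("partition has ", length(partition), " labels but graph has ", n, " nodes")
  as.integer(factor(partition))
}

#' Maximise Markov stability with repeated seeded Louvain runs
#'
#' Each run performs greedy single-node moves plus aggregation (the Louvain
#' scheme) on the generalized quality matrix
#' `B(t) = Pi P(t) - pi pi^T` from a seeded random node order, followed by
#' a node-level refinement pass, so every returned partition is a local
#' maximum of stability under single-node moves. Output is deterministic
#' for a fixed seed.
#'
#' @param G a [cell_graph].
#' @param t Markov time.
#' @param runs number of restarts (`>= 1`).
#' @param seed integer seed controlling all restarts.
#' @param spectrum optional precomputed spectrum.
#' @return list with `partitions` (list of integer label vectors),
#'   `stability` (vector), and `best` (index of the best run).
#' @export
optimize_partition <- function(G, t, runs = 20, seed = 1, spectrum = NULL) {
  if (runs < 1) stop("runs must be >= 1")
  B <- quality_matrix(G, t, spectrum)
  run_seeds <- derive_seeds(seed, runs)
  parts <- vector("list", runs)
  stab <- numeric(runs)
  for (r in seq_len(runs)) {
    res <- louvain_quality(B, run_seeds[r])
    parts[[r]] <- stats::setNames(res$labels, G$node_ids)
    stab[r] <- res$stability
  }
  list(partitions = parts, stability = stab, best = which.max(stab))
}

# Deterministic integer sub-seeds < 2^31 from one integer seed.
derive_seeds <- function(seed, n) {
  s <- as.double(seed %% 2147483647L)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647   # Lehmer / MINSTD step
    out[i] <- s
  }
  as.integer(out)
}

#' Variation of information between two partitions
#'
#' `VI(P, Q) = 2 H(P, Q) - H(P) - H(Q)` in bits (base-2 entropies). It is a
#' metric on partitions: symmetric, zero iff the partitions are equal up to
#' relabelling, and satisfying the triangle inequality.
#'
#' @param p,q integer community labels over the same node set.
#' @return non-negative scalar (bits).
#' @export
variation_of_information <- function(p, q) {
  if (length(p) != length(q))
    stop("partitions are over different node sets (", length(p), " vs ",
         length(q), " nodes)")
  n <- length(p)
  joint <- table(p, q) / n
  hj <- entropy_bits(as.vector(joint))
  2 * hj - entropy_bits(rowSums(joint)) - entropy_bits(colSums(joint))
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Default logarithmic Markov-time grid
#'
#' 100 logarithmically spaced times spanning `[1e-2, 1e2]`.
#'
#' @param from,to grid end points.
#' @param length number of times.
#' @return ascending numeric vector.
#' @export
default_time_grid <- function(from = 1e-2, to = 1e2, length = 100) {
  exp(seq(log(from), log(to), length.out = length))
}

#' Scan Markov times for robust partition scales
#'
#' At each Markov time the stability optimiser is restarted `runs` times;
#' the best-stability partition is retained and the mean pairwise variation
#' of information (VI) across the runs measures how reproducible the
#' optimum is. Times where the VI curve attains a local minimum (robust,
#' well-defined community structure) are selected as scales. Plateaus of
#' equal VI collapse to their midpoint time; a candidate must also lie
#' below `(1 - min_drop)` times the global VI maximum, so that a flat VI
#' curve with no structure yields no spurious interior scales.
#'
#' @param G a [cell_graph].
#' @param times ascending Markov-time grid (default [default_time_grid()]).
#' @param runs Louvain restarts per time (`>= 2`; pairwise VI needs 2).
#' @param seed integer seed.
#' @param min_drop relative VI drop below the global maximum required for
#'   selection (default 0.01).
#' @return object of class `stability_profile`: `times`, `stability`,
#'   `n_communities`, `mean_vi`, `partitions` (best per time),
#'   `selected_scales`, `selected_idx`.
#' @export
scan_scales <- function(G, times = default_time_grid(), runs = 20, seed = 1,
                        min_drop = 0.01) {
  if (runs < 2) stop("runs must be >= 2 (pairwise VI is undefined otherwise)")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly ascending")
  sp <- rw_spectrum(G)
  nt <- length(times)
  time_seeds <- derive_seeds(seed, nt)
  stability <- mean_vi <- numeric(nt)
  ncomm <- integer(nt)
  partitions <- vector("list", nt)
  for (i in seq_len(nt)) {
    opt <- optimize_partition(G, times[i], runs = runs, seed = time_seeds[i],
                              spectrum = sp)
    partitions[[i]] <- opt$partitions[[opt$best]]
    stability[i] <- opt$stability[opt$best]
    ncomm[i] <- length(unique(partitions[[i]]))
    pairs <- utils::combn(runs, 2)
    mean_vi[i] <- mean(apply(pairs, 2, function(pr)
      variation_of_information(opt$partitions[[pr[1]]], opt$partitions[[pr[2]]])))
  }
  sel <- vi_local_minima(mean_vi, ncomm, min_drop = min_drop)
  structure(list(times = times, stability = stability, n_communities = ncomm,
                 mean_vi = mean_vi, partitions = partitions,
                 selected_idx = sel, selected_scales = times[sel]),
            class = "stability_profile")
}

# Indices of local minima of a VI curve. A "plateau" is a maximal stretch
# of times with (numerically) equal VI and an unchanged community count of
# the best partition; each plateau collapses to its midpoint index. A
# plateau qualifies as a scale if its VI does not exceed that of either
# adjacent plateau (plateaus touching the grid boundary compare only
# against their single interior neighbour — stable coarse partitions
# persist to the end of any finite grid) and lies below
# (1 - min_drop) * max(vi). If the curve is globally flat with a single
# community count, the midpoint of the whole grid is returned.
vi_local_minima <- function(vi, n_communities, min_drop = 0.01, tol = 1e-9) {
  n <- length(vi)
  brk <- abs(diff(vi)) > tol | diff(n_communities) != 0L
  run_id <- cumsum(c(1, brk))
  nruns <- max(run_id)
  run_val <- vapply(seq_len(nruns), function(r) vi[run_id == r][1], 0)
  if (nruns == 1) return(floor((1 + n) / 2))
  run_len <- tabulate(run_id, nruns)
  keep <- vapply(seq_len(nruns), function(r) {
    left_ok <- r == 1 || run_val[r] <= run_val[r - 1] + tol
    right_ok <- r == nruns || run_val[r] <= run_val[r + 1] + tol
    # a robust scale persists over an interval of Markov times: a
    # single-grid-point run only qualifies if strictly below a neighbour
    # (transition partitions between two plateaus do not)
    strict <- (r > 1 && run_val[r] < run_val[r - 1] - tol) ||
              (r < nruns && run_val[r] < run_val[r + 1] - tol)
    left_ok && right_ok && (run_len[r] >= 2 || strict)
  }, TRUE)
  keep <- keep & (run_val <= max(vi) * (1 - min_drop) + tol)
  idx <- vapply(which(keep), function(r) {
    pos <- which(run_id == r)
    pos[ceiling(length(pos) / 2)]
  }, 0L)
  sort(idx)
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("stability_profile: ", length(x$times), " Markov times, ",
      length(x$selected_idx), " selected scales\n", sep = "")
  if (length(x$selected_idx)) {
    cat(sprintf("  t = %-10.4g  communities = %d\n",
                x$times[x$selected_idx], x$n_communities[x$selected_idx]), sep = "")
  }
  invisible(x)
}

#' Multiscale Laplacian score
#'
#' `MLS(g, t) = sum_{u,v} d_u P(t)_{uv} (g(u) - g(v))^2 / (2 Var_G(g))`:
#' the expected squared change in `g` seen by a stationary random walker
#' over time `t`, normalised by the graph variance. `MLS(g, 0) = 0` and
#' `MLS(g, t) -> 1` as `t -> Inf`; replacing `P(t)` by the one-step matrix
#' `D^{-1} A` recovers the classic Laplacian score. Low values at a scale
#' `t` mark signals coherent with the graph structure at that scale.
#'
#' @param signals a [gene_signals] set (or matrix/vector); every signal
#'   must be non-constant.
#' @param G a [cell_graph].
#' @param times Markov times, typically the `selected_scales` of a
#'   [scan_scales()] profile.
#' @return object of class `mls_matrix`: `gene_ids`, `times`, `scores`
#'   (genes x times).
#' @export
mls <- function(signals, G, times) {
  X <- signal_matrix(signals, G)
  if (any(times < 0)) stop("Markov times must be non-negative")
  d <- G$degrees
  mu <- as.numeric(X %*% d) / sum(d)
  Xc <- X - mu
  v <- as.numeric((Xc^2) %*% d)
  bad <- v <= 0
  if (any(bad))
    stop("MLS undefined for constant signals (zero graph variance): ",
         paste(utils::head((rownames(X) %||% seq_len(nrow(X)))[bad], 5),
               collapse = ", "))
  sp <- rw_spectrum(G)
  S <- matrix(0, nrow(X), length(times),
              dimnames = list(rownames(X), paste0("mls_t", seq_along(times))))
  for (j in seq_along(times)) {
    P <- heat_kernel(G, times[j], spectrum = sp)$matrix
    DP <- d * P                       # symmetric by detailed balance
    num <- as.numeric((Xc^2) %*% d) - rowSums((Xc %*% DP) * Xc)
    S[, j] <- pmax(num, 0) / v
  }
  structure(list(gene_ids = rownames(X) %||% paste0("gene_", seq_len(nrow(X))),
                 times = times, scores = S),
            class = "mls_matrix")
}

#' @export
print.mls_matrix <- function(x, ...) {
  cat("mls_matrix: ", nrow(x$scores), " genes x ", length(x$times),
      " Markov times\n", sep = "")
  invisible(x)
}

#' Enumerate all partitions of n items
#'
#' Generates every set partition (as restricted-growth label vectors).
#' Intended for exhaustive verification on small graphs; the count is the
#' Bell number (e.g. 203 for n = 6, 877 for n = 7).
#'
#' @param n number of items (capped at 10).
#' @return list of integer label vectors.
#' @export
enumerate_partitions <- function(n) {
  if (n > 10) stop("exhaustive enumeration capped at n = 10")
  out <- list()
  labels <- integer(n)
  recurse <- function(i, maxl) {
    if (i > n) { out[[length(out) + 1]] <<- labels[seq_len(n)]; return() }
    for (l in seq_len(maxl + 1L)) {
      labels[i] <<- l
      recurse(i + 1L, max(maxl, l))
    }
  }
  recurse(1L, 0L)
  out
}

#' Export a stability profile as JSON plus per-scale partition TSVs
#'
#' @param profile a [scan_scales()] result.
#' @param json_path output JSON (times, stability, community counts, VI,
#'   selected scales).
#' @param partition_dir optional directory for one
#'   `partition_scale_<k>.tsv` (`cell_id<TAB>community`) per selected scale.
#' @export
write_stability_profile <- function(profile, json_path, partition_dir = NULL) {
  jsonlite::write_json(list(times = profile$times,
                            stability = profile$stability,
                            n_communities = profile$n_communities,
                            mean_vi = profile$mean_vi,
                            selected_scales = profile$selected_scales),
                       json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(partition_dir)) {
    dir.create(partition_dir, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(profile$selected_idx)) {
      p <- profile$partitions[[profile$selected_idx[k]]]
      utils::write.table(data.frame(cell_id = names(p), community = as.integer(p)),
                         file.path(partition_dir, paste0("partition_scale_", k, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(json_path)
}

#' Write MLS scores as TSV
#'
#' Columns: `gene_id`, one `mls_t*` column per Markov time, and the classic
#' Laplacian score for comparison.
#'
#' @param M an [mls()] result.
#' @param G the graph the scores were computed on.
#' @param signals the scored signals (for the Laplacian-score column).
#' @param path output TSV.
#' @export
write_mls <- function(M, G, signals, path) {
  ls_col <- laplacian_score(signals, G)
  df <- data.frame(gene_id = M$gene_ids,
                   format(M$scores, digits = 10, trim = TRUE),
                   laplacian_score = format(as.numeric(ls_col), digits = 10,
                                            trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
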