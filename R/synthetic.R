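#' @name synthetic
#' @title Seeded synthetic benchmark generators
#' @description Deterministic generators for the toy constructions used to
#'   validate the scoring methods: Gaussian-ball point clouds, hierarchical
#'   planted-partition graphs, a three-community graph with test signals,
#'   the three-node bifurcation graph, and a Y-shaped bifurcating
#'   expression simulator. Every generator is reproducible from its seed
#'   and returns a `synthetic_bundle` whose `truth` element records the
#'   planted structure.
NULL

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  code
}

new_bundle <- function(...) structure(list(...), class = "synthetic_bundle")

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Four touching Gaussian balls in high dimension
#'
#' Samples `points_per_ball` points from each of four isotropic Gaussian
#' clusters (`sd = 0.4`, i.e. clusters of radius ~1 at 2.5 sigma) centred
#' on the vertices of a planar square of side 2 embedded in `dim`
#' dimensions, so that adjacent clusters touch. Bundled signals: one 0/1
#' indicator per ball, signed (+1/-1) indicators of the left/right and
#' bottom/top ball pairs, and an i.i.d. standard-normal noise signal. A
#' 15-nearest-neighbour graph on these points is connected with
#' low-frequency eigenvectors that separate the ball pairs (up to
#' rotation within the nearly degenerate leading eigenspace).
#'
#' @param points_per_ball points per ball (default 100).
#' @param dim ambient dimension (default 30).
#' @param sd cluster standard deviation (default 0.4).
#' @param seed integer seed.
#' @return `synthetic_bundle` with `points` (cells x dim), `signals`
#'   ([gene_signals]) and `truth$ball` labels.
#' @export
four_balls <- function(points_per_ball = 100, dim = 30, sd = 0.4, seed = 1) {
  stopifnot(points_per_ball >= 2, dim >= 2)
  with_seed(seed, {
    centers <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
    n <- 4 * points_per_ball
    pts <- matrix(0, n, dim)
    ball <- rep(1:4, each = points_per_ball)
    for (b in 1:4) {
      p <- matrix(stats::rnorm(points_per_ball * dim, sd = sd),
                  points_per_ball, dim)
      p[, 1:2] <- p[, 1:2] + rep(centers[b, ], each = points_per_ball)
      pts[ball == b, ] <- p
    }
    rownames(pts) <- paste0("cell_", seq_len(n))
    sig <- rbind(ball_1 = as.numeric(ball == 1),
                 ball_2 = as.numeric(ball == 2),
                 ball_3 = as.numeric(ball == 3),
                 ball_4 = as.numeric(ball == 4),
                 pair_left  = ifelse(ball %in% c(1, 3), 1, -1),
                 pair_bottom = ifelse(ball %in% c(1, 2), 1, -1),
                 noise = stats::rnorm(n))
    colnames(sig) <- rownames(pts)
    new_bundle(points = pts, signals = gene_signals(sig),
               truth = list(ball = ball,
                            pair_left = ball %in% c(1, 3),
                            pair_bottom = ball %in% c(1, 2)))
  })
}

#' Balanced hierarchical planted-partition graph
#'
#' A fully connected weighted graph on `leaf_size * branching^depth` nodes
#' arranged in a balanced `branching`-ary hierarchy of `depth` levels above
#' the leaf groups. The weight between two nodes decays geometrically with
#' how far up the hierarchy their lowest common ancestor sits:
#' `w = weight_decay^(depth - shared_levels)` (same leaf group: 1), with
#' mild multiplicative jitter so that realisations differ by seed. The
#' planted partition at level `l` has `branching^l` communities; with the
#' defaults the partitions have 4, 16, 64 and 256 communities on 1024
#' nodes, which is the multiscale benchmark for Markov-stability scale
#' selection.
#'
#' @param branching children per internal node (default 4).
#' @param depth hierarchy levels (default 4).
#' @param leaf_size nodes per leaf group (default 4).
#' @param weight_decay geometric decay per level (default 0.1).
#' @param jitter half-width of the multiplicative weight jitter
#'   (default 0.1, i.e. factors in `[0.9, 1.1]`).
#' @param seed integer seed.
#' @return `synthetic_bundle` with `graph` ([cell_graph]) and
#'   `truth$partitions` (named list `level_1` ... `level_depth`).
#' @export
hierarchical_graph <- function(branching = 4, depth = 4, leaf_size = 4,
                               weight_decay = 0.1, jitter = 0.1, seed = 1) {
  stopifnot(branching >= 2, depth >= 2, leaf_size >= 1,
            weight_decay > 0, weight_decay < 1)
  n <- leaf_size * branching^depth
  with_seed(seed, {
    shared <- matrix(0L, n, n)
    partitions <- list()
    for (l in seq_len(depth)) {
      block <- leaf_size * branching^(depth - l)
      grp <- ceiling(seq_len(n) / block)
      partitions[[paste0("level_", l)]] <- grp
      shared <- shared + outer(grp, grp, "==")
    }
    W <- weight_decay^(depth - shared)
    jit <- matrix(stats::runif(n * n, 1 - jitter, 1 + jitter), n, n)
    jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
    W <- W * jit
    diag(W) <- 0
    rownames(W) <- colnames(W) <- paste0("cell_", seq_len(n))
    new_bundle(graph = cell_graph(W),
               truth = list(partitions = partitions))
  })
}

#' Three-community weighted graph with test signals
#'
#' A planted-partition graph with three communities of distinct sizes:
#' within-community weight `w_in`, between-community weight `w_out`
#' (`w_in > w_out`), with mild multiplicative jitter. Bundled signals: for
#' each community, a signal equal to 1 on that community and uniformly
#' random on `[0, 1]` elsewhere, plus one fully random signal. Truth holds
#' the three-way partition and the coarse two-way partition in which the
#' two smallest communities merge (the grouping the slowest diffusion mode
#' of the graph induces).
#'
#' @param sizes three distinct community sizes (default `c(60, 30, 15)`).
#' @param w_in within-community weight (default 1).
#' @param w_out between-community weight (default 0.02).
#' @param jitter multiplicative jitter half-width (default 0.1).
#' @param seed integer seed.
#' @return `synthetic_bundle` with `graph`, `signals` and
#'   `truth$partition3` / `truth$partition2` / `truth$signal_community`.
#' @export
three_community_graph <- function(sizes = c(60, 30, 15), w_in = 1,
                                  w_out = 0.02, jitter = 0.1, seed = 1) {
  if (length(sizes) != 3 || anyDuplicated(sizes))
    stop("sizes must be three distinct community sizes")
  if (!(w_in > w_out && w_out >= 0)) stop("need w_in > w_out >= 0")
  n <- sum(sizes)
  comm <- rep(1:3, times = sizes)
  with_seed(seed, {
    W <- matrix(w_out, n, n)
    for (c in 1:3) W[comm == c, comm == c] <- w_in
    jit <- matrix(stats::runif(n * n, 1 - jitter, 1 + jitter), n, n)
    jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
    W <- W * jit
    diag(W) <- 0
    rownames(W) <- colnames(W) <- paste0("cell_", seq_len(n))
    ord <- order(sizes, decreasing = TRUE)   # communities by size
    sig <- matrix(stats::runif(4 * n), 4, n)
    for (k in 1:3) sig[k, comm == ord[k]] <- 1
    rownames(sig) <- c("ind_largest", "ind_middle", "ind_smallest", "random")
    colnames(sig) <- rownames(W)
    two <- ifelse(comm == ord[1], 1L, 2L)    # two smallest merge
    new_bundle(graph = cell_graph(W),
               signals = gene_signals(sig),
               truth = list(partition3 = comm, partition2 = two,
                            signal_community = stats::setNames(ord, rownames(sig)[1:3])))
  })
}

#' The three-node toy bifurcation
#'
#' The unit-weight graph on nodes `a`, `b`, `c` with edges `(a,c)` and
#' `(b,c)`: `c` is a parent cell type, `a` and `b` its daughters. Bundled
#' binary signals: `g1 = (1,1,1)` (housekeeper), `g2 = (1,0,1)`
#' (parent + one daughter), `g3 = (1,1,0)` (both daughters only),
#' `g4 = (0,1,0)` (one daughter only); reverse-time filtration
#' `f(a) = f(b) = 0`, `f(c) = 1`. Deterministic — no seed.
#'
#' @return `synthetic_bundle` with `graph`, `signals`, `filtration` and
#'   `truth$archetype`.
#' @export
toy_bifurcation <- function() {
  A <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  A["a", "c"] <- A["c", "a"] <- 1
  A["b", "c"] <- A["c", "b"] <- 1
  sig <- rbind(g1 = c(1, 1, 1), g2 = c(1, 0, 1),
               g3 = c(1, 1, 0), g4 = c(0, 1, 0))
  colnames(sig) <- c("a", "b", "c")
  new_bundle(graph = cell_graph(A),
             signals = gene_signals(sig),
             filtration = filtration(c(a = 0, b = 0, c = 1),
                                     node_ids = c("a", "b", "c")),
             truth = list(archetype = c(g1 = "constant",
                                        g2 = "parent_daughter",
                                        g3 = "both_daughters",
                                        g4 = "single_daughter")))
}

#' Y-shaped bifurcating expression simulator
#'
#' Places cells along a Y-shaped trajectory over 7 integer developmental
#' stages: a parent trunk (stages 1-3) that splits into two daughter
#' branches (stages 4-7), with `n_cells_per_branch` cells per stage per
#' lineage. Genes are drawn from
#' five archetypes — `constant` (housekeeper), `parent_daughter1` /
#' `parent_daughter2` (rises in the trunk, stays on in one daughter,
#' ramps off along the other), `both_daughters` (off in the trunk, ramps
#' on in both branches) and `daughter1_only` (a terminal marker of the
#' first daughter fate, switching on at the final stage) — as stagewise
#' ramps of amplitude `amplitude` plus i.i.d. Gaussian noise. The
#' reverse-time filtration `f = 7 - stage` makes the final-stage branch
#' tips the first sublevel set, so persistent-vs-full Rayleigh quotients
#' on a k-NN graph of the cells separate the archetypes as in the
#' three-node toy: `parent_daughter*` above the diagonal,
#' `both_daughters` below, `daughter1_only` on it, `constant` near the
#' origin.
#'
#' The default of one cell per branch and stage emulates a
#' metacell-resolution trajectory, where each branch tip is a single
#' node; this is the regime in which the normalised persistent quotient
#' contrasts are sharpest (thicker tips dilute the tip-to-tip contrast by
#' their internal degree).
#'
#' @param n_cells_per_branch cells per stage per branch (default 1).
#' @param n_genes_per_archetype genes per archetype (default 8).
#' @param noise_sd Gaussian noise standard deviation (default 0.1).
#' @param amplitude peak expression of the ramps (default 4).
#' @param seed integer seed.
#' @return `synthetic_bundle` with `points` (cells x genes expression),
#'   `signals` (genes x cells), `filtration`, and
#'   `truth$stage` / `truth$branch` / `truth$archetype`.
#' @export
bifurcating_expression <- function(n_cells_per_branch = 1,
                                   n_genes_per_archetype = 8,
                                   noise_sd = 0.1, amplitude = 4, seed = 1) {
  stopifnot(n_cells_per_branch >= 1, n_genes_per_archetype >= 1, noise_sd >= 0)
  n <- n_cells_per_branch
  stage <- c(rep(1:3, each = n), rep(4:7, each = n), rep(4:7, each = n))
  branch <- c(rep("P", 3 * n), rep("D1", 4 * n), rep("D2", 4 * n))
  ncells <- length(stage)
  cell_ids <- paste0("cell_", seq_len(ncells))

  # archetype mean profiles as functions of (stage, branch)
  ramp_on <- function(s) pmin(0.25 + 0.25 * (s - 3), 1) # 0.5, 0.75, 1, 1
  ramp_off <- function(s) pmax(1 - (s - 3) / 3, 0)      # 2/3, 1/3, 0, 0
  trunk <- function(s) s / 3                            # 1/3, 2/3, 1
  terminal <- function(s) pmax(s - 6, 0)                # on only at stage 7
  profile <- function(arch) {
    vapply(seq_len(ncells), function(i) {
      s <- stage[i]; b <- branch[i]
      switch(arch,
        constant = 1,
        parent_daughter1 = if (b == "P") trunk(s) else if (b == "D1") 1 else ramp_off(s),
        parent_daughter2 = if (b == "P") trunk(s) else if (b == "D2") 1 else ramp_off(s),
        both_daughters = if (b == "P") 0 else ramp_on(s),
        daughter1_only = if (b == "D1") terminal(s) else 0)
    }, 0)
  }
  archetypes <- c("constant", "parent_daughter1", "parent_daughter2",
                  "both_daughters", "daughter1_only")
  with_seed(seed, {
    rows <- list()
    arch_of <- character(0)
    for (a in archetypes) {
      mu <- amplitude * profile(a)
      for (g in seq_len(n_genes_per_archetype)) {
        rows[[length(rows) + 1]] <- mu + stats::rnorm(ncells, sd = noise_sd)
        arch_of <- c(arch_of, a)
      }
    }
    expr <- do.call(rbind, rows)
    rownames(expr) <- paste0(arch_of, "_", stats::ave(seq_along(arch_of),
                                                      arch_of, FUN = seq_along))
    colnames(expr) <- cell_ids
    new_bundle(points = t(expr),
               signals = gene_signals(expr),
               filtration = filtration_from_time(stats::setNames(stage, cell_ids)),
               truth = list(stage = stage, branch = branch,
                            archetype = stats::setNames(arch_of, rownames(expr))))
  })
}

#' Classify genes from persistent-vs-full Rayleigh quotients
#'
#' Given full (`i = j`) and persistent (`i < j`) normalised Rayleigh
#' quotients, assigns each gene to a region of the persistent-vs-full
#' plane: `"near-zero"` (both quotients below `low`; constant-like
#' housekeepers), `"above"` (persistent exceeds full by more than `band`;
#' parent-plus-one-daughter pattern), `"below"` (full exceeds persistent;
#' both-daughters pattern) or `"on-diagonal"` (single-daughter pattern).
#'
#' @param full numeric vector of full quotients.
#' @param persistent numeric vector of persistent quotients.
#' @param band half-width of the diagonal band (default 0.05).
#' @param low near-zero threshold (default 0.2).
#' @return character vector of region labels.
#' @export
classify_prq <- function(full, persistent, band = 0.05, low = 0.2) {
  delta <- persistent - full
  ifelse(pmax(full, persistent) < low, "near-zero",
         ifelse(delta > band, "above",
                ifelse(delta < -band, "below", "on-diagonal")))
}

#' Export a synthetic bundle to plain-text files
#'
#' Writes whichever parts the bundle has: `points.tsv` (dense matrix,
#' cells x features), `expression.tsv` (genes x cells), `graph.tsv` (edge
#' list), `filtration.tsv`, and `truth_<name>.tsv` label tables.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$points))
    utils::write.table(data.frame(cell_id = rownames(bundle$points),
                                  bundle$points, check.names = FALSE),
                       file.path(dir, "points.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bundle$signals))
    utils::write.table(data.frame(gene_id = bundle$signals$gene_ids,
                                  bundle$signals$values, check.names = FALSE),
                       file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$graph))
    write_edge_list(bundle$graph, file.path(dir, "graph.tsv"))
  if (!is.null(bundle$filtration))
    write_filtration(bundle$filtration, file.path(dir, "filtration.tsv"))
  if (!is.null(bundle$truth)) {
    for (nm in names(bundle$truth)) {
      tr <- bundle$truth[[nm]]
      if (is.atomic(tr))
        utils::write.table(data.frame(item = seq_along(tr), label = as.vector(tr)),
                           file.path(dir, paste0("truth_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
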