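# Random graph + random integer filtration for property checks.
random_filtered <- function(n, seed, fmax = 3) {
  G <- random_graph(n, seed = seed)
  set.seed(seed + 1000)
  f <- filtration(sample(0:fmax, n, replace = TRUE))
  list(G = G, f = f)
}

test_that("filtrations validate and convert from time", {
  expect_error(filtration(c(0.5, 1)), "integers")
  f <- filtration_from_time(c(c1 = 10, c2 = 13, c3 = 17))
  expect_equal(f$values, c(7, 4, 0))
  expect_equal(f$node_ids, c("c1", "c2", "c3"))
})

test_that("sublevel subgraphs nest and match the toy example", {
  tb <- toy_bifurcation()
  s0 <- filtered_subgraph(tb$graph, tb$filtration, 0)
  expect_setequal(s0$nodes, c("a", "b"))
  expect_equal(sum(s0$adjacency), 0)   # edgeless: two components
  s1 <- filtered_subgraph(tb$graph, tb$filtration, 5)  # i >= max f
  expect_setequal(s1$nodes, c("a", "b", "c"))
  expect_equal(as.matrix(s1$adjacency), as.matrix(tb$graph$adjacency))
  expect_error(filtered_subgraph(tb$graph, tb$filtration, -1), "empty")
  rf <- random_filtered(10, seed = 2)
  prev <- character(0)
  for (i in 0:3) {
    cur <- filtered_subgraph(rf$G, rf$f, i)$nodes
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("Kron reduction reproduces the printed two-node reduction", {
  P <- path_graph()   # a - c - b, unit weights
  L <- as.matrix(laplacian(P, "combinatorial"))
  red <- kron_reduce(L, which(P$node_ids %in% c("a", "b")))
  expect_equal(red$matrix,
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2,
                      dimnames = list(c("a", "b"), c("a", "b"))))
  # alpha = all nodes leaves L unchanged
  expect_equal(kron_reduce(L, 1:3)$matrix, L)
  # a component entirely eliminated is a hard error
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  L2 <- diag(rowSums(W)) - W
  expect_error(kron_reduce(L2, c(1, 2)), "singular")
})

test_that("Kron reductions are Laplacians (symmetry, L1=0, signs)", {
  for (seed in 1:50) {
    n <- sample(5:12, 1)
    G <- random_graph(n, seed = 300 + seed)
    L <- as.matrix(laplacian(G, "combinatorial"))
    keep <- sort(sample(n, sample(2:(n - 1), 1)))
    red <- kron_reduce(L, keep)$matrix
    expect_equal(red, t(red), tolerance = 1e-10)
    expect_lt(max(abs(rowSums(red))), 1e-9)
    off <- red - diag(diag(red))
    expect_true(all(off <= 1e-10))
  }
})

test_that("Schur reduction is transitive", {
  G <- random_graph(10, seed = 77)
  L <- as.matrix(laplacian(G, "combinatorial"))
  alpha <- c(1, 2, 4, 6, 7, 9)
  beta_in_alpha <- c(1, 3, 5)       # positions within alpha
  R1 <- kron_reduce(kron_reduce(L, alpha)$matrix, beta_in_alpha)$matrix
  R2 <- kron_reduce(L, alpha[beta_in_alpha])$matrix
  expect_equal(R1, R2, tolerance = 1e-9)
})

test_that("persistent Laplacian interpolates between sublevel Laplacians", {
  tb <- toy_bifurcation()
  red <- persistent_laplacian(tb$graph, tb$filtration, 0, 1)
  expect_equal(unname(red$matrix),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  expect_equal(red$source, c(0, 1))
  # (max, max) is the plain Laplacian of the full graph
  full <- persistent_laplacian(tb$graph, tb$filtration, 1, 1)
  expect_equal(full$matrix,
               as.matrix(laplacian(tb$graph, "combinatorial")))
  # nullity of the (0,1) reduction is 1: the two components merge into one
  expect_equal(sum(abs(eigen(red$matrix)$values) < 1e-8), 1)
  expect_error(persistent_laplacian(tb$graph, tb$filtration, 1, 0), "i <= j")
  # normalized variant is the Schur complement of the normalized Laplacian
  rf <- random_filtered(9, seed = 5)
  rn <- persistent_laplacian(rf$G, rf$f, 1, 2, normalized = TRUE)
  sub <- filtered_subgraph(rf$G, rf$f, 2)
  A <- as.matrix(sub$adjacency); d <- rowSums(A)
  Ln <- diag(length(d)) - (1 / sqrt(d)) * A * rep(1 / sqrt(d), each = length(d))
  fv <- graphsel:::check_filtration(rf$f, rf$G)
  keep <- which(fv[sub$index] <= 1)
  ac <- setdiff(seq_along(d), keep)
  ref <- if (length(ac) == 0) Ln[keep, keep]
         else Ln[keep, keep] -
           Ln[keep, ac, drop = FALSE] %*%
             solve(Ln[ac, ac, drop = FALSE], Ln[ac, keep, drop = FALSE])
  expect_equal(unname(rn$matrix), unname((ref + t(ref)) / 2),
               tolerance = 1e-9)
})

test_that("persistent Betti-0 equals the nullity of the reduced Laplacian", {
  tb <- toy_bifurcation()
  expect_equal(persistent_betti0(tb$graph, tb$filtration, 0, 1), 1)
  expect_equal(persistent_betti0(tb$graph, tb$filtration, 0, 0), 2)
  # two cliques joined only at a late filtration value stay separate
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  G2 <- cell_graph(W + diag(0, 6))
  f2 <- filtration(c(0, 1, 1, 0, 1, 1))
  expect_equal(persistent_betti0(G2, f2, 0, 1), 2)
  for (seed in 1:30) {
    n <- sample(6:15, 1)
    G <- random_graph(n, seed = 400 + seed)
    # sparsify so components can actually appear
    A <- as.matrix(G$adjacency)
    A[A < stats::quantile(A[A > 0], 0.75)] <- 0
    A <- A + t(A)
    deg <- rowSums(A)
    if (any(deg == 0)) next
    G <- cell_graph(A)
    set.seed(seed)
    f <- filtration(sample(0:3, n, replace = TRUE))
    for (i in 0:2) for (j in i:3) {
      if (length(which(f$values <= i)) == 0) next
      b0 <- persistent_betti0(G, f, i, j)
      red <- tryCatch(persistent_laplacian(G, f, i, j), error = function(e) NULL)
      if (is.null(red)) next   # a component of G[alpha(j)] misses alpha(i)
      lam <- abs(eigen(red$matrix, symmetric = TRUE, only.values = TRUE)$values)
      nullity <- sum(lam < 1e-8 * max(lam, 1))
      expect_equal(nullity, b0)
    }
  }
})

test_that("toy bifurcation PRQ values and sign pattern match the worked example", {
  tb <- toy_bifurcation()
  pers <- prq(tb$signals, tb$graph, tb$filtration, 0, 1)
  full <- prq(tb$signals, tb$graph, tb$filtration, 1, 1)
  expect_equal(unname(pers), c(0, 1, 0, 1))
  expect_equal(unname(full), c(0, 1 / 3, 1, 1))
  # above/below/on-diagonal narrative: signs of (persistent - full)
  expect_equal(sign(round(unname(pers - full), 10)), c(0, 1, -1, 0))
  # i = j = max f reduces to the plain normalized Rayleigh quotient
  for (g in seq_len(4)) {
    expect_equal(unname(full[g]),
                 rayleigh_quotient(tb$signals$values[g, ], tb$graph,
                                   normalized = TRUE))
  }
  # unnormalised form divides by <g, g> instead
  raw <- prq(tb$signals, tb$graph, tb$filtration, 1, 1, normalized = FALSE)
  for (g in seq_len(4)) {
    expect_equal(unname(raw[g]),
                 rayleigh_quotient(tb$signals$values[g, ], tb$graph))
  }
  expect_error(prq(rbind(z = c(0, 0, 1)), tb$graph, tb$filtration, 0, 1),
               "undefined")
})

test_that("prq_map collects pairs and flags undefined genes", {
  tb <- toy_bifurcation()
  tab <- prq_map(tb$signals, tb$graph, tb$filtration,
                 list(c(0, 1), c(1, 1), c(0, 1)))
  expect_equal(names(tab), c("gene_id", "prq_0_1", "prq_1_1", "prq_0_1"))
  expect_equal(tab[[2]], tab[[4]])          # duplicate pairs identical
  expect_equal(tab$prq_1_1, c(0, 1 / 3, 1, 1))
  sig2 <- gene_signals(rbind(ok = c(1, 0, 1), dead = c(0, 0, 1)))
  tab2 <- prq_map(sig2, tb$graph, tb$filtration, list(c(0, 1)))
  expect_true(is.na(tab2$prq_0_1[2]))
  expect_equal(tab2$prq_0_1[1], 1)
  fails <- attr(tab2, "failures")
  expect_equal(fails$gene_id, "dead")
})

test_that("bifurcating fixture: archetypes recovered from the PRQ plane", {
  b <- bifurcating_expression(seed = 1)
  G <- build_knn_graph(b$points, k = 3, metric = "euclidean",
                       weighting = "unit")
  full <- prq(b$signals, G, b$filtration, 6, 6)
  pers <- prq(b$signals, G, b$filtration, 0, 6)
  cls <- classify_prq(full, pers, band = 0.05, low = 0.1)
  expected <- c(constant = "near-zero", parent_daughter1 = "above",
                parent_daughter2 = "above", both_daughters = "below",
                daughter1_only = "on-diagonal")
  acc <- mean(cls == expected[b$truth$archetype])
  expect_gte(acc, 0.9)
  # parent-plus-one-daughter genes sit above the diagonal almost surely
  pd <- b$truth$archetype %in% c("parent_daughter1", "parent_daughter2")
  expect_gte(mean(pers[pd] > full[pd]), 0.9)
})
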