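test_that("stationary distribution is the degree distribution", {
  G2 <- cell_graph(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(unname(stationary_distribution(G2)), c(1 / 2, 1 / 2))
  expect_equal(unname(stationary_distribution(path_graph())),
               c(1 / 4, 1 / 4, 1 / 2))
  G <- random_graph(8, seed = 1)
  pi_ <- stationary_distribution(G)
  expect_equal(sum(pi_), 1)
  P <- heat_kernel(G, 0.7)$matrix
  expect_equal(drop(pi_ %*% P), pi_, tolerance = 1e-10)
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 2
  D <- cell_graph(W)
  expect_error(stationary_distribution(D), "disconnected")
  pcs <- stationary_distribution(D, per_component = TRUE)
  expect_length(pcs, 2)
  expect_equal(unname(pcs[[1]]), c(1 / 2, 1 / 2))
})

test_that("heat kernel: closed form, semigroup, detailed balance, oracle", {
  G2 <- cell_graph(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(heat_kernel(G2, 0)$matrix, diag(2), ignore_attr = TRUE)
  t <- 0.37
  ref <- matrix(c(1 + exp(-2 * t), 1 - exp(-2 * t),
                  1 - exp(-2 * t), 1 + exp(-2 * t)) / 2, 2, 2)
  expect_equal(heat_kernel(G2, t)$matrix, ref, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(heat_kernel(G2, -1), "non-negative")

  G <- random_graph(6, seed = 4)
  P3 <- heat_kernel(G, 0.3)$matrix
  P5 <- heat_kernel(G, 0.5)$matrix
  P8 <- heat_kernel(G, 0.8)$matrix
  expect_equal(P3 %*% P5, P8, tolerance = 1e-8)
  expect_equal(unname(rowSums(P8)), rep(1, 6), tolerance = 1e-10)
  # detailed balance d_u P_uv = d_v P_vu
  DP <- G$degrees * P8
  expect_equal(DP, t(DP), tolerance = 1e-8)
  # independent series-expansion oracle
  A <- as.matrix(G$adjacency)
  Lrw <- diag(6) - A / rowSums(A)
  expect_equal(P8, expm_ref(-0.8 * Lrw), tolerance = 1e-8,
               ignore_attr = TRUE)
  # long-time limit 1 pi^T
  Pinf <- heat_kernel(G, 500)$matrix
  expect_equal(Pinf, matrix(stationary_distribution(G), 6, 6, byrow = TRUE),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Markov stability matches its definition and bounds", {
  G <- random_graph(5, seed = 6)
  pi_ <- stationary_distribution(G)
  # all-in-one partition scores exactly 0 at any time
  expect_equal(markov_stability(G, rep(1, 5), 1.3), 0, tolerance = 1e-12)
  # singleton partition at t = 0
  expect_equal(markov_stability(G, 1:5, 0), 1 - sum(pi_^2),
               tolerance = 1e-10)
  # quality-matrix evaluation equals the defining double sum via an
  # independent matrix-exponential route
  for (t in c(0.1, 1, 10)) {
    for (s in 1:5) {
      p <- random_partition(5, 3, seed = 40 + s)
      expect_lt(abs(markov_stability(G, p, t) - stability_ref(G, p, t)),
                1e-8)
    }
  }
  # range over exhaustive partitions
  vals <- vapply(enumerate_partitions(5),
                 function(p) markov_stability(G, p, 0.5), 0)
  expect_true(all(vals > -0.5))
  expect_true(all(vals <= 1 + 1e-12))
})

test_that("Louvain optimiser attains the exhaustive optimum on small graphs", {
  hits <- 0; total <- 0
  for (seed in 1:6) {
    G <- random_graph(6, seed = 200 + seed)
    parts <- enumerate_partitions(6)
    for (t in c(0.1, 1, 10)) {
      best <- max(vapply(parts, function(p) markov_stability(G, p, t), 0))
      opt <- optimize_partition(G, t, runs = 5, seed = seed)
      total <- total + 1
      if (max(opt$stability) >= best - 1e-9) hits <- hits + 1
      # every returned partition is a local maximum under single moves
      expect_true(all(opt$stability <= best + 1e-9))
    }
  }
  expect_gte(hits / total, 0.9)   # Louvain is a heuristic; allow rare misses
})

test_that("optimiser is deterministic for a fixed seed", {
  G <- random_graph(10, seed = 31)
  a <- optimize_partition(G, 0.8, runs = 6, seed = 42)
  b <- optimize_partition(G, 0.8, runs = 6, seed = 42)
  expect_identical(a, b)
  expect_length(a$partitions, 6)
  expect_true(all(vapply(a$partitions, function(p)
    all(tabulate(p) > 0), TRUE)))          # communities all non-empty
})

test_that("complete regular graphs keep the all-singletons optimum", {
  # every off-diagonal quality entry is negative at finite t, so the exact
  # optimum is the finest partition and all restarts agree
  n <- 6
  K <- cell_graph(matrix(1, n, n) - diag(n))
  for (t in c(0.5, 5, 50)) {
    opt <- optimize_partition(K, t, runs = 4, seed = 1)
    expect_equal(length(unique(opt$partitions[[opt$best]])), n)
    best <- max(vapply(enumerate_partitions(n),
                       function(p) markov_stability(K, p, t), 0))
    expect_equal(max(opt$stability), best, tolerance = 1e-10)
  }
})

test_that("planted three-community structure is recovered at mid scales", {
  b <- three_community_graph(seed = 3)
  opt <- optimize_partition(b$graph, t = 3, runs = 5, seed = 9)
  for (p in opt$partitions)
    expect_equal(variation_of_information(p, b$truth$partition3), 0)
})

test_that("variation of information is a metric in bits", {
  p <- random_partition(30, 4, seed = 1)
  q <- random_partition(30, 5, seed = 2)
  r <- random_partition(30, 3, seed = 3)
  expect_equal(variation_of_information(p, p), 0)
  # relabeling leaves VI at zero
  expect_equal(variation_of_information(p, max(p) + 1 - p), 0)
  expect_equal(variation_of_information(p, q), variation_of_information(q, p))
  expect_gte(variation_of_information(p, q) + variation_of_information(q, r),
             variation_of_information(p, r) - 1e-12)
  # n singletons vs all-in-one: VI = log2 n
  expect_equal(variation_of_information(1:16, rep(1, 16)), 4)
  expect_error(variation_of_information(1:4, 1:5), "different node sets")
})

test_that("scale scan finds the three- and two-community regimes", {
  b <- three_community_graph(seed = 1)
  prof <- scan_scales(b$graph, runs = 8, seed = 2)
  expect_error(scan_scales(b$graph, runs = 1), "runs must be >= 2")
  expect_true(all(prof$selected_scales %in% prof$times))
  expect_true(all(prof$stability > -0.5 & prof$stability <= 1))
  expect_true(all(prof$mean_vi >= 0))
  k_sel <- prof$n_communities[prof$selected_idx]
  nsel <- length(k_sel)
  expect_gte(nsel, 2)
  expect_equal(k_sel[nsel], 2)       # coarsest: two communities
  expect_equal(k_sel[nsel - 1], 3)   # then: the three planted communities
  p2 <- prof$partitions[[prof$selected_idx[nsel]]]
  p3 <- prof$partitions[[prof$selected_idx[nsel - 1]]]
  expect_equal(variation_of_information(p3, b$truth$partition3), 0)
  expect_equal(variation_of_information(p2, b$truth$partition2), 0)
})

test_that("MLS endpoints, one-step identity, and community ordering", {
  G <- random_graph(7, seed = 8)
  set.seed(8)
  X <- rbind(g1 = rnorm(7), g2 = rnorm(7))
  M <- mls(X, G, times = c(0, 1000))
  expect_equal(unname(M$scores[, 1]), c(0, 0))
  expect_equal(unname(M$scores[, 2]), c(1, 1), tolerance = 1e-8)
  expect_error(mls(rbind(k = rep(2, 7)), G, 1), "constant")
  expect_error(mls(X, G, c(-1, 2)), "non-negative")

  # replacing P(t) by the one-step matrix D^{-1}A recovers the classic
  # Laplacian score (computed here from its own definition)
  A <- as.matrix(G$adjacency)
  d <- rowSums(A)
  Pstep <- A / d
  for (i in 1:2) {
    g <- X[i, ]
    mu <- sum(g * d) / sum(d)
    varg <- sum(d * (g - mu)^2)
    one_step <- sum(d * Pstep * outer(g, g, "-")^2) / (2 * varg)
    expect_equal(one_step, unname(laplacian_score(g, G)), tolerance = 1e-10)
  }

  # community indicators: low at matched scales, random high
  b <- three_community_graph(seed = 1)
  prof <- scan_scales(b$graph, runs = 6, seed = 5)
  k_sel <- prof$n_communities[prof$selected_idx]
  two_coarsest <- rev(prof$selected_scales)[2:1]
  S <- mls(b$signals, b$graph, two_coarsest)$scores
  for (j in 1:2) {
    expect_lt(S["ind_largest", j], min(S[c("ind_middle", "ind_smallest"), j]))
    expect_gt(S["random", j], max(S[1:3, j]))
  }
})

test_that("MLS of a community indicator rises monotonically past mixing", {
  b <- three_community_graph(seed = 4)
  ts <- default_time_grid(from = 2, to = 80, length = 12)
  g <- ifelse(b$truth$partition3 == 1, 1, 0)
  s <- mls(rbind(ind = g), b$graph, ts)$scores[1, ]
  expect_true(all(diff(s) > -1e-6))
})

test_that("stability profile exports round-trip as JSON and TSV", {
  b <- three_community_graph(seed = 2)
  prof <- scan_scales(b$graph, times = default_time_grid(0.5, 50, 12),
                      runs = 4, seed = 1)
  json <- withr::local_tempfile(fileext = ".json")
  pdir <- withr::local_tempdir()
  write_stability_profile(prof, json, partition_dir = pdir)
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(back$times, prof$times)
  expect_equal(back$selected_scales, prof$selected_scales)
  tsvs <- list.files(pdir, pattern = "partition_scale_.*tsv")
  expect_length(tsvs, length(prof$selected_idx))
  first <- utils::read.table(file.path(pdir, tsvs[1]), header = TRUE,
                             sep = "\t")
  expect_equal(nrow(first), n_nodes(b$graph))
})
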