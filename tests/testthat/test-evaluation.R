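test_that("edge splits have the right sizes and are deterministic per seed", {
  g <- toy_graph()
  s <- split_edges(g, 0.5, 1)
  expect_equal(nrow(s$training_edges), 3)
  expect_equal(nrow(s$probe_edges), 3)
  s2 <- split_edges(g, 0.5, 1)
  expect_identical(s$probe_edges, s2$probe_edges)
  expect_false(identical(split_edges(g, 0.5, 2)$probe_edges,
                         s$probe_edges) &&
                 identical(split_edges(g, 0.5, 3)$probe_edges,
                           s$probe_edges))
  # partition contract: E^T u E^P = E, disjoint
  both <- rbind(s$training_edges, s$probe_edges)
  expect_equal(both[order(both[, 1], both[, 2]), ], g$edges,
               ignore_attr = TRUE)
  expect_error(split_edges(g, 0.01, 1), "empty")
  expect_error(split_edges(g, 1.2, 1), "in \\(0, 1\\)")
})

test_that("probe membership is uniform across many splits", {
  g <- er_graph(5, n = 40, p = 0.13)  # ~100 edges
  m <- n_edges(g)
  counts <- numeric(m)
  n_rep <- 1000
  for (r in 1:n_rep) {
    s <- split_edges(g, 0.9, 1000 + r)
    idx <- match(paste(s$probe_edges[, 1], s$probe_edges[, 2]),
                 paste(g$edges[, 1], g$edges[, 2]))
    counts[idx] <- counts[idx] + 1
  }
  p_hat <- counts / n_rep
  p0 <- (m - round(0.9 * m)) / m
  expect_equal(mean(p_hat), p0)  # exact: every split has |E^P| probes
  # max over m correlated binomials: 4-sigma (Bonferroni-sized) band
  expect_true(all(abs(p_hat - p0) <= 4 * sqrt(p0 * (1 - p0) / n_rep)))
})

test_that("AUC is 1 for a perfect ranking and 0.5 under constant scores", {
  g <- er_graph(2, n = 20, p = 0.2)
  s <- split_edges(g, 0.8, 3)
  n <- g$n_nodes
  perfect <- matrix(0, n, n)
  perfect[s$probe_edges] <- 1
  perfect[s$probe_edges[, 2:1]] <- 1
  expect_equal(auc_score(perfect, s, g), 1)
  flat <- matrix(1, n, n); diag(flat) <- 0
  expect_equal(auc_score(flat, s, g), 0.5)
})

test_that("exact AUC matches the exhaustive comparison oracle and its symmetries", {
  for (seed in 1:6) {
    g <- er_graph(seed, n = 22, p = 0.18)
    s <- split_edges(g, 0.85, seed + 50)
    gt <- training_graph(g, s)
    sc <- score_matrix(gt, "ra")
    expect_equal(auc_score(sc, s, g), o_auc(sc, s, g))
    # invariance under strictly monotone transforms
    expect_equal(auc_score(exp(3 * sc), s, g), auc_score(sc, s, g))
    # jittered scores have no ties: AUC(s) + AUC(-s) = 1
    jit <- sc + matrix(seq_len(length(sc)) * 1e-9, nrow(sc))
    jit <- (jit + t(jit)) / 2
    expect_equal(auc_score(jit, s, g) + auc_score(-jit, s, g), 1)
  }
})

test_that("sampled AUC converges to the exact value", {
  g <- er_graph(9, n = 25, p = 0.2)
  s <- split_edges(g, 0.85, 4)
  sc <- score_matrix(training_graph(g, s), "cn")
  exact <- auc_score(sc, s, g)
  n <- 1e5
  sampled <- auc_score(sc, s, g, mode = "sampled", n = n, seed = 99)
  expect_lt(abs(sampled - exact), 3 * sqrt(0.25 / n))
  expect_identical(sampled, auc_score(sc, s, g, mode = "sampled", n = n,
                                      seed = 99))
})

test_that("precision@L matches the sort-and-count oracle and is deterministic under ties", {
  for (seed in 1:4) {
    g <- er_graph(seed + 20, n = 30, p = 0.15)
    s <- split_edges(g, 0.85, seed)
    sc <- score_matrix(training_graph(g, s), "ra")
    expect_equal(precision_at_l(sc, s, g, L = 20),
                 o_precision(sc, s, g, L = 20))
  }
  g <- er_graph(1, n = 15, p = 0.3)
  s <- split_edges(g, 0.8, 2)
  zeros <- matrix(0, 15, 15)
  expect_identical(precision_at_l(zeros, s, g, L = 10),
                   precision_at_l(zeros, s, g, L = 10))
  expect_error(precision_at_l(zeros, s, g, L = 10000), "fewer than L")
})

test_that("precision counts all probe edges recovered when they top the list", {
  g <- er_graph(4, n = 20, p = 0.2)
  s <- split_edges(g, 0.8, 7)
  m <- nrow(s$probe_edges)
  sc <- matrix(0, 20, 20)
  sc[s$probe_edges] <- 1
  sc[s$probe_edges[, 2:1]] <- 1
  L <- m + 5
  expect_equal(precision_at_l(sc, s, g, L = L), m / L)
})

test_that("replicated experiments are reproducible and compose with manual calls", {
  g <- er_graph(6, n = 30, p = 0.15)
  oracle <- function(g_train, split, g_full) {
    n <- g_full$n_nodes
    m <- matrix(0, n, n)
    m[split$probe_edges] <- 1
    m[split$probe_edges[, 2:1]] <- 1
    m
  }
  res <- run_experiment(g, oracle, ratio = 0.8, L = 5, n_replicates = 3,
                        base_seed = 10)
  expect_equal(res$mean_auc, 1)
  expect_equal(res$mean_auc, mean(res$auc))
  expect_equal(res$mean_precision, mean(res$precision))
  expect_true(all(res$auc >= 0 & res$auc <= 1))

  # n_replicates = 1 equals one manual split + auc + precision
  res1 <- run_experiment(g, index_spec("cn"), ratio = 0.8, L = 5,
                         n_replicates = 1, base_seed = 20)
  s <- split_edges(g, 0.8, 21)
  sc <- score_matrix(training_graph(g, s), "cn")
  expect_equal(res1$auc, auc_score(sc, s, g))
  expect_equal(res1$precision, precision_at_l(sc, s, g, L = 5))

  res_a <- run_experiment(g, index_spec("ra"), ratio = 0.8, L = 5,
                          n_replicates = 4, base_seed = 30)
  res_b <- run_experiment(g, index_spec("ra"), ratio = 0.8, L = 5,
                          n_replicates = 4, base_seed = 30)
  expect_identical(res_a$auc, res_b$auc)
  df <- as.data.frame(res_a)
  expect_equal(names(df), c("method", "ratio", "replicate", "auc", "precision"))
  expect_equal(nrow(df), 4)
})

test_that("scores are built on the training graph only (no probe leakage)", {
  g <- er_graph(8, n = 25, p = 0.2)
  seen <- NULL
  spy <- function(g_train, split, g_full) {
    seen <<- g_train
    score_matrix(g_train, "cn")
  }
  invisible(run_experiment(g, spy, ratio = 0.8, L = 5, n_replicates = 1,
                           base_seed = 40))
  s <- split_edges(g, 0.8, 41)
  expect_identical(seen$edges, s$training_edges)
  # probe edges absent from the graph the scores were computed on
  key <- function(e) paste(e[, 1], e[, 2])
  expect_length(intersect(key(seen$edges), key(s$probe_edges)), 0)
})

test_that("common-neighbor signal on planted communities beats chance", {
  g <- generate_graph("planted_partition", seed = 77, n = 120,
                      k_communities = 3, p_in = 0.2, p_out = 0.02)
  res <- run_experiment(g, index_spec("cn"), ratio = 0.9, L = 10,
                        n_replicates = 5, base_seed = 1)
  expect_gt(res$mean_auc, 0.5)
})

test_that("the calibration grid sweep has the documented shape and beta=0 column", {
  g <- generate_graph("planted_partition", seed = 3, n = 60,
                      k_communities = 3, p_in = 0.3, p_out = 0.05)
  sw <- parameter_sweep(g, "cn", "ra", alpha_grid = c(0, 3, 6),
                        beta_grid = c(0, 1), outer_ratio = 0.9,
                        n_replicates = 3, seed = 5)
  expect_equal(dim(sw$grid), c(3, 2))
  expect_true(all(sw$grid >= 0 & sw$grid <= 1))
  expect_true(sw$best_alpha %in% c(0, 3, 6) && sw$best_beta %in% c(0, 1))
  # beta = 0 column equals the pure-C1 evaluation of the same inner splits
  gt <- training_graph(g, sw$outer_split)
  acc <- 0
  for (r in 1:3) {
    inner <- split_edges(gt, 0.9, 5 + r)
    sc <- score_matrix(training_graph(gt, inner), "cn")
    acc <- acc + auc_score(sc, inner, gt)
  }
  expect_equal(unname(sw$grid[2, 1]), acc / 3)  # alpha = 3, beta = 0
  expect_equal(unname(sw$grid[2, 1]), unname(sw$grid[3, 1]))  # constant in alpha scale
})

test_that("ratio sweeps tabulate methods by ratios and reduce to run_experiment", {
  g <- generate_graph("planted_partition", seed = 9, n = 60,
                      k_communities = 3, p_in = 0.3, p_out = 0.05)
  sw <- ratio_sweep(g, list(index_spec("cn"), index_spec("ra")),
                    ratios = c(0.6, 0.9), L = 5, n_replicates = 2, seed = 4)
  expect_equal(dim(sw$auc), c(2, 2))
  expect_equal(rownames(sw$auc), c("CN", "RA"))
  single <- ratio_sweep(g, index_spec("cn"), ratios = 0.9, L = 5,
                        n_replicates = 2, seed = 4)
  direct <- run_experiment(g, index_spec("cn"), ratio = 0.9, L = 5,
                           n_replicates = 2, base_seed = 4)
  expect_equal(unname(single$auc[1, 1]), direct$mean_auc)
  expect_error(ratio_sweep(g, index_spec("cn"), ratios = c(0.5, 1.5)),
               "in \\(0, 1\\)")
})
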