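#' Split observed edges into training and probe sets
#'
#' Samples the probe set E^P uniformly at random without replacement from
#' the observed edges; the remainder is the training set E^T. The split is
#' deterministic given `(g, ratio, seed)`. No connectivity of the training
#' graph is guaranteed.
#'
#' @param g an [lp_graph] with at least 2 edges.
#' @param ratio fraction of edges kept for training, in (0, 1);
#'   `|E^T| = round(ratio * |E|)`.
#' @param seed integer RNG seed.
#' @return An object of class `edge_split`: matrices `training_edges`,
#'   `probe_edges` (rows of `g$edges`), plus `ratio` and `seed`.
#' @export
split_edges <- function(g, ratio, seed) {
  m <- n_edges(g)
  if (m < 2L) stop("need at least 2 edges to split")
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop("ratio must be in (0, 1)")
  }
  n_train <- round(ratio * m)
  if (n_train < 1L || n_train >= m) {
    stop("ratio leaves an empty training or probe set")
  }
  probe_idx <- withr::with_seed(
    seed, sample.int(m, m - n_train),
    .rng_kind = "Mersenne-Twister", .rng_sample_kind = "Rejection"
  )
  structure(list(
    training_edges = g$edges[-probe_idx, , drop = FALSE],
    probe_edges = g$edges[sort(probe_idx), , drop = FALSE],
    ratio = ratio, seed = as.integer(seed)
  ), class = "edge_split")
}

#' Training graph of a split
#'
#' The graph `(V, E^T)`: same nodes and labels, training edges only. All
#' score matrices used for evaluation must be built on this graph, never on
#' the full one.
#'
#' @param g the full [lp_graph].
#' @param split an [split_edges()] result.
#' @return An [lp_graph].
#' @export
training_graph <- function(g, split) {
  lp_graph(split$training_edges, n_nodes = g$n_nodes, labels = g$labels)
}

pair_scores <- function(scores, pairs) scores[pairs[, 1:2, drop = FALSE]]

nonedge_scores <- function(scores, g_full) {
  mask <- upper.tri(scores) & as.matrix(g_full$adj) == 0
  scores[mask]
}

#' AUC of a score matrix against a train/probe split
#'
#' The probability that a probe link outscores a nonexistent link (a pair
#' absent from the full graph), ties counted 0.5. `mode = "exact"` compares
#' every probe link with every nonexistent link (midrank formulation);
#' `mode = "sampled"` draws `n` independent seeded comparisons and returns
#' `(n' + 0.5 n'') / n` where `n'` counts strictly higher and `n''` equal
#' probe scores.
#'
#' @param scores score matrix built on the *training* graph.
#' @param split an [split_edges()] result.
#' @param g_full the full observed [lp_graph] (defines the nonexistent
#'   links).
#' @param mode `"exact"` (default) or `"sampled"`.
#' @param n number of sampled comparisons (sampled mode).
#' @param seed RNG seed for sampled mode.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, split, g_full, mode = c("exact", "sampled"),
                      n = 1e5, seed = 1L) {
  mode <- match.arg(mode)
  pos <- pair_scores(scores, split$probe_edges)
  neg <- nonedge_scores(scores, g_full)
  if (length(pos) == 0L) stop("empty probe set")
  if (length(neg) == 0L) stop("no nonexistent links to compare against")
  if (mode == "exact") {
    # midranks give exactly the (n' + 0.5 n'')/n counting over all pairs
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  } else {
    idx <- withr::with_seed(
      seed,
      list(p = sample.int(length(pos), n, replace = TRUE),
           q = sample.int(length(neg), n, replace = TRUE)),
      .rng_kind = "Mersenne-Twister", .rng_sample_kind = "Rejection"
    )
    s1 <- pos[idx$p]; s2 <- neg[idx$q]
    (sum(s1 > s2) + 0.5 * sum(s1 == s2)) / n
  }
}

#' Precision of the top-L predictions
#'
#' Ranks every candidate pair (all pairs not in the training set, i.e. probe
#' links plus nonexistent links) by score descending, ties broken by
#' ascending lexicographic node-id pair for determinism, and returns the
#' fraction of the top `L` that are probe links.
#'
#' @inheritParams auc_score
#' @param L number of top-ranked pairs to inspect (>= 1).
#' @return Precision in \[0, 1\].
#' @export
precision_at_l <- function(scores, split, g_full, L = 100L) {
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  n <- nrow(scores)
  g_train <- lp_graph(split$training_edges, n_nodes = n)
  mask <- upper.tri(scores) & as.matrix(g_train$adj) == 0
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < L) stop("fewer than L candidate pairs")
  s <- scores[mask]
  ord <- order(-s, idx[, 1], idx[, 2])[seq_len(L)]
  top_key <- (idx[ord, 1] - 1) * n + idx[ord, 2]
  probe_key <- (split$probe_edges[, 1] - 1) * n + split$probe_edges[, 2]
  sum(top_key %in% probe_key) / L
}

#' Build a prediction score matrix for a method
#'
#' Dispatches on the method object: an [index_spec] yields its
#' [score_matrix()], an [sfcn_config] its [sfcn_score_matrix()], and a
#' function is called as `method(g_train, split, g_full)` and must return a
#' symmetric score matrix (the hook used to inject reference scorers in
#' tests).
#'
#' @param method an [index_spec], [sfcn_config], or function.
#' @param g_train training [lp_graph].
#' @param split,g_full passed to function methods only.
#' @return Numeric score matrix.
#' @export
build_scores <- function(method, g_train, split = NULL, g_full = NULL) {
  if (inherits(method, "index_spec")) return(score_matrix(g_train, method))
  if (inherits(method, "sfcn_config")) return(sfcn_score_matrix(g_train, method))
  if (is.function(method)) return(method(g_train, split, g_full))
  stop("method must be an index_spec, an sfcn_config, or a function")
}

#' Replicated link-prediction experiment
#'
#' For each replicate r: split the edges with seed `base_seed + r`, rebuild
#' the method's score matrix on the training graph only, and measure AUC
#' (exact mode by default) and precision at L. Fully reproducible from
#' `base_seed`.
#'
#' @param g the full observed [lp_graph].
#' @param method an [index_spec], [sfcn_config], or scorer function (see
#'   [build_scores()]).
#' @param ratio training fraction, default 0.9.
#' @param L precision cutoff, default 100.
#' @param n_replicates number of independent splits, default 100.
#' @param base_seed integer; replicate r uses seed `base_seed + r`.
#' @param auc_mode `"exact"` or `"sampled"`.
#' @param auc_n comparisons per replicate in sampled mode.
#' @return An object of class `experiment_result`: `label`, numeric vectors
#'   `auc` and `precision` (one entry per replicate), `mean_auc`,
#'   `mean_precision`, `L`, `n_replicates`, `ratio`, `seeds`.
#' @export
run_experiment <- function(g, method, ratio = 0.9, L = 100L,
                           n_replicates = 100L, base_seed = 1L,
                           auc_mode = c("exact", "sampled"), auc_n = 1e5) {
  auc_mode <- match.arg(auc_mode)
  seeds <- as.integer(base_seed) + seq_len(n_replicates)
  aucs <- numeric(n_replicates)
  precs <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    split <- split_edges(g, ratio, seeds[r])
    g_train <- training_graph(g, split)
    scores <- build_scores(method, g_train, split, g)
    aucs[r] <- auc_score(scores, split, g, mode = auc_mode, n = auc_n,
                         seed = seeds[r] + 500000L)
    precs[r] <- precision_at_l(scores, split, g, L)
  }
  structure(list(
    label = method_label(method), auc = aucs, precision = precs,
    mean_auc = mean(aucs), mean_precision = mean(precs),
    L = as.integer(L), n_replicates = as.integer(n_replicates),
    ratio = ratio, seeds = seeds
  ), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("%s: mean AUC %.4f, mean precision@%d %.4f (%d replicates, ratio %g)\n",
              x$label, x$mean_auc, x$L, x$mean_precision,
              x$n_replicates, x$ratio))
  invisible(x)
}

#' Tidy per-replicate table of an experiment
#' @param x an `experiment_result`.
#' @param ... unused.
#' @return data.frame with columns `method`, `ratio`, `replicate`, `auc`,
#'   `precision`.
#' @export
as.data.frame.experiment_result <- function(x, ...) {
  data.frame(method = x$label, ratio = x$ratio,
             replicate = seq_len(x$n_replicates),
             auc = x$auc, precision = x$precision,
             stringsAsFactors = FALSE)
}

#' Calibration grid sweep over the SFCN mixing weights
#'
#' The a-priori calibration protocol: the observed edges are first split
#' into E^T / E^P at `outer_ratio`; then, using only E^T, each replicate
#' sub-splits into a sub-training set E^T1 and sub-probe set E^P1 at
#' `inner_ratio`, scores E^P1 from E^T1 for every (alpha, beta) combination,
#' and the mean AUC per grid cell is returned. Within a replicate the C1
#' matrix and the future-contribution matrix are built once, so the grid
#' only costs one matrix combination per cell.
#'
#' @param g the full observed [lp_graph].
#' @param c1,c2 [index_spec]s (or names) for the two base indexes.
#' @param alpha_grid,beta_grid numeric grids; defaults are 0 to 15 by 3 and
#'   0 to 2 by 0.4 (the 6 x 6 calibration grid).
#' @param outer_ratio,inner_ratio training fractions for the outer and
#'   inner splits; both default to 0.9.
#' @param n_replicates inner replicates, default 20.
#' @param seed base RNG seed.
#' @param lp_epsilon LP path weight for name arguments.
#' @return List with `grid` (matrix of mean AUC, alpha rows x beta columns),
#'   `best_alpha`, `best_beta` (argmax, first in row-major order on ties),
#'   `outer_split`.
#' @export
parameter_sweep <- function(g, c1, c2,
                            alpha_grid = seq(0, 15, by = 3),
                            beta_grid = seq(0, 2, by = 0.4),
                            outer_ratio = 0.9, inner_ratio = outer_ratio,
                            n_replicates = 20L, seed = 1L,
                            lp_epsilon = 0.001) {
  if (!length(alpha_grid) || !length(beta_grid)) stop("empty grid")
  if (!inherits(c1, "index_spec")) c1 <- index_spec(c1, lp_epsilon)
  if (!inherits(c2, "index_spec")) c2 <- index_spec(c2, lp_epsilon)
  outer <- split_edges(g, outer_ratio, seed)
  g_t <- training_graph(g, outer)
  acc <- matrix(0, length(alpha_grid), length(beta_grid),
                dimnames = list(alpha = alpha_grid, beta = beta_grid))
  for (r in seq_len(n_replicates)) {
    inner <- split_edges(g_t, inner_ratio, as.integer(seed) + r)
    g_t1 <- training_graph(g_t, inner)
    c1m <- score_matrix(g_t1, c1)
    fm <- fcn_contribution_matrix(g_t1, score_matrix(g_t1, c2))
    for (i in seq_along(alpha_grid)) {
      for (j in seq_along(beta_grid)) {
        sc <- alpha_grid[i] * c1m + beta_grid[j] * fm
        acc[i, j] <- acc[i, j] + auc_score(sc, inner, g_t)
      }
    }
  }
  grid <- acc / n_replicates
  best <- which(grid == max(grid), arr.ind = TRUE)[1, ]
  list(grid = grid,
       best_alpha = alpha_grid[best[1]], best_beta = beta_grid[best[2]],
       outer_split = outer)
}

#' Robustness sweep over the training/probe ratio
#'
#' Runs a full replicated experiment for every (method, ratio) combination
#' and tabulates the mean AUC with methods as rows and ratios as columns.
#'
#' @param g the full observed [lp_graph].
#' @param methods named or unnamed list of method objects (see
#'   [build_scores()]); unnamed entries are labelled automatically.
#' @param ratios numeric vector of training fractions in (0, 1).
#' @param L precision cutoff passed through to [run_experiment()].
#' @param n_replicates replicates per cell.
#' @param seed base RNG seed.
#' @return List with `auc` (method x ratio matrix of mean AUC), `precision`
#'   (same shape), and `tidy` (per-replicate long data.frame).
#' @export
ratio_sweep <- function(g, methods, ratios, L = 100L, n_replicates = 100L,
                        seed = 1L) {
  if (!all(ratios > 0 & ratios < 1)) stop("every ratio must be in (0, 1)")
  if (inherits(methods, c("index_spec", "sfcn_config")) ||
      is.function(methods)) {
    methods <- list(methods)
  }
  labels <- names(methods)
  auto <- vapply(methods, method_label, "")
  if (is.null(labels)) labels <- auto else labels[labels == ""] <- auto[labels == ""]
  auc_m <- matrix(NA_real_, length(methods), length(ratios),
                  dimnames = list(labels, ratios))
  prec_m <- auc_m
  tidy <- list()
  for (i in seq_along(methods)) {
    for (j in seq_along(ratios)) {
      res <- run_experiment(g, methods[[i]], ratio = ratios[j], L = L,
                            n_replicates = n_replicates, base_seed = seed)
      auc_m[i, j] <- res$mean_auc
      prec_m[i, j] <- res$mean_precision
      df <- as.data.frame(res)
      df$method <- labels[i]
      tidy[[length(tidy) + 1L]] <- df
    }
  }
  list(auc = auc_m, precision = prec_m, tidy = do.call(rbind, tidy))
}
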