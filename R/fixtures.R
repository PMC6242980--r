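#' Five-node toy graph
#'
#' The small graph used throughout the examples and tests: nodes 1..5 with
#' edges 1-2, 1-3, 2-3, 2-4, 3-4, 4-5 (two triangles sharing the edge 2-3,
#' plus a pendant node).
#'
#' @return An [lp_graph] with |V| = 5, |E| = 6.
#' @examples
#' g <- toy_graph()
#' score_pair(g, 1, 4, "cn")
#' @export
toy_graph <- function() {
  lp_graph(cbind(c(1, 1, 2, 2, 3, 4), c(2, 3, 3, 4, 4, 5)), n_nodes = 5)
}

#' Worked-example pair vectors on a 10-node network
#'
#' The reference fixture for the SFCN vector construction: the four vectors
#' of the target pair (1, 3) on a 10-node network, with C1 = LHN and
#' C2 = RA. The similarity entries are exact fractions, carried both as
#' numerics and as integer numerators over a common denominator so that the
#' expected contributions (1/6, 1/5, 1/15; total 13/30) can be verified by
#' integer arithmetic.
#'
#' @return A list with fields `n_nodes` (10), `x` (1), `y` (3), `c1_name`,
#'   `c2_name`, the numeric vectors `gamma_1`, `gamma_3`, `s_1`, `s_3`, and
#'   exact-fraction forms `s_1_num`/`s_1_den`, `s_3_num`/`s_3_den`
#'   (`s_1 = s_1_num / s_1_den` elementwise). A `pair_vectors` object built
#'   from them is returned in `$vectors` for direct use with
#'   [identify_fcn()].
#' @export
example1_fixture <- function() {
  gamma_1 <- c(0, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  gamma_3 <- c(0, 1, 0, 0, 1, 0, 0, 0, 0, 0)
  s_1_num <- c(0, 0, 0, 0, 1, 0, 1, 1, 0, 1); s_1_den <- 5L
  s_3_num <- c(0, 0, 0, 1, 0, 1, 0, 1, 1, 1); s_3_den <- 6L
  s_1 <- s_1_num / s_1_den
  s_3 <- s_3_num / s_3_den
  vectors <- structure(
    list(gamma_x = gamma_1, gamma_y = gamma_3, s_x = s_1, s_y = s_3,
         x = 1L, y = 3L),
    class = "pair_vectors"
  )
  list(n_nodes = 10L, x = 1L, y = 3L, c1_name = "lhn", c2_name = "ra",
       gamma_1 = gamma_1, gamma_3 = gamma_3, s_1 = s_1, s_3 = s_3,
       s_1_num = s_1_num, s_1_den = s_1_den,
       s_3_num = s_3_num, s_3_den = s_3_den,
       vectors = vectors)
}

#' Seeded synthetic graph generators
#'
#' Random simple undirected graphs for testing and benchmarking, generated
#' deterministically from a seed:
#'
#' * `"erdos_renyi"` — G(n, p); arguments `n`, `p`.
#' * `"barabasi_albert"` — preferential attachment; arguments `n`, `m`
#'   (edges added per new node).
#' * `"planted_partition"` — `k_communities` equal-sized blocks over `n`
#'   nodes with within-block edge probability `p_in` and between-block
#'   probability `p_out`; the community signal creates common-neighbor
#'   structure, making these graphs a predictable benchmark for
#'   link prediction.
#'
#' @param model one of `"erdos_renyi"`, `"barabasi_albert"`,
#'   `"planted_partition"`.
#' @param seed integer RNG seed; the same `(model, parameters, seed)`
#'   always yields the same edge set.
#' @param n number of nodes.
#' @param p edge probability (Erdos-Renyi).
#' @param m edges per step (Barabasi-Albert).
#' @param k_communities,p_in,p_out planted-partition parameters; `n` must be
#'   divisible by `k_communities`.
#' @return An [lp_graph].
#' @examples
#' g <- generate_graph("erdos_renyi", seed = 1, n = 30, p = 0.2)
#' @export
generate_graph <- function(model = c("erdos_renyi", "barabasi_albert",
                                     "planted_partition"),
                           seed, n, p = NULL, m = NULL,
                           k_communities = NULL, p_in = NULL, p_out = NULL) {
  model <- match.arg(model)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  ig <- withr::with_seed(
    seed,
    switch(model,
      erdos_renyi = {
        if (is.null(p) || p < 0 || p > 1) stop("need edge probability p in [0, 1]")
        igraph::sample_gnp(n, p)
      },
      barabasi_albert = {
        if (is.null(m) || m < 1) stop("need m >= 1 edges per step")
        igraph::sample_pa(n, m = m, directed = FALSE)
      },
      planted_partition = {
        if (is.null(k_communities) || is.null(p_in) || is.null(p_out)) {
          stop("need k_communities, p_in, p_out")
        }
        if (n %% k_communities != 0) {
          stop("n must be divisible by k_communities")
        }
        k <- as.integer(k_communities)
        pm <- matrix(p_out, k, k)
        diag(pm) <- p_in
        igraph::sample_sbm(n, pref.matrix = pm,
                           block.sizes = rep(n %/% k, k))
      }
    ),
    .rng_kind = "Mersenne-Twister", .rng_sample_kind = "Rejection"
  )
  ig <- igraph::simplify(ig)
  el <- igraph::as_edgelist(ig, names = FALSE)
  lp_graph(el, n_nodes = n)
}

#' Published summary statistics of five benchmark networks
#'
#' Reference descriptive statistics of five widely used real networks — a
#' scientific-collaboration network (NS), the US political blogs network
#' (PB), a yeast protein-interaction network (Yeast), the C. elegans neural
#' network (CE), and the Florida Bay food web (FWFB) — as commonly tabulated
#' in the link-prediction literature. These are reference inputs (the edge
#' lists themselves are distributed separately and are not shipped); the
#' package uses them to check the arithmetic self-consistency of its own
#' statistics, e.g. that `avg_degree = 2|E|/|V|` reproduces the tabulated
#' `<k>`.
#'
#' @return data.frame with columns `network`, `n_nodes`, `n_links`,
#'   `avg_shortest_distance`, `avg_degree`, `degree_heterogeneity`,
#'   `clustering_coefficient`, `assortativity`.
#' @export
reference_network_stats <- function() {
  data.frame(
    network = c("CE", "FWFB", "NS", "PB", "Yeast"),
    n_nodes = c(297L, 128L, 379L, 1222L, 2375L),
    n_links = c(2148L, 2075L, 914L, 16714L, 11693L),
    avg_shortest_distance = c(2.46, 1.78, 4.93, 2.74, 5.09),
    avg_degree = c(14.4646, 32.4219, 4.82, 27.3552, 9.8467),
    degree_heterogeneity = c(1.8008, 1.2370, 1.66, 2.9707, 3.4756),
    clustering_coefficient = c(0.3079, 0.3346, 0.798, 0.3600, 0.3883),
    assortativity = c(-0.163, -0.112, -0.082, -0.221, 0.454),
    stringsAsFactors = FALSE
  )
}
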