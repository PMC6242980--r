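# Brute-force reference implementations used to cross-check the package.
# Everything here is computed straight from the edge list with elementary
# set operations and loops, independent of the matrix-product code paths.

o_nbrs <- function(g, x) {
  e <- g$edges
  sort(unique(c(e[e[, 1] == x, 2], e[e[, 2] == x, 1])))
}

o_has_edge <- function(g, i, j) {
  a <- min(i, j); b <- max(i, j)
  any(g$edges[, 1] == a & g$edges[, 2] == b)
}

o_degree <- function(g, x) length(o_nbrs(g, x))

# per-pair index formulas, written from the definitions
o_score <- function(g, x, y, name, eps = 0.001) {
  nx <- o_nbrs(g, x); ny <- o_nbrs(g, y)
  cn <- intersect(nx, ny)
  kx <- length(nx); ky <- length(ny)
  switch(name,
    cn = length(cn),
    salton = if (kx * ky == 0) 0 else length(cn) / sqrt(kx * ky),
    ra = sum(vapply(cn, function(z) 1 / o_degree(g, z), 0)),
    hpi = if (min(kx, ky) == 0) 0 else length(cn) / min(kx, ky),
    hdi = if (max(kx, ky) == 0) 0 else length(cn) / max(kx, ky),
    lhn = if (kx * ky == 0) 0 else length(cn) / (kx * ky),
    lnbra = {
      n <- g$n_nodes; m <- nrow(g$edges)
      eta <- n * (n - 1) / (2 * m) - 1
      s <- 0
      for (z in cn) {
        nb <- o_nbrs(g, z)
        kz <- length(nb)
        nd <- 0
        if (kz >= 2) {
          for (a in 1:(kz - 1)) for (b in (a + 1):kz) {
            if (o_has_edge(g, nb[a], nb[b])) nd <- nd + 1
          }
        }
        nn <- kz * (kz - 1) / 2 - nd
        s <- s + (1 / kz) * (log2(eta) + log2((nd + 1) / (nn + 1)))
      }
      s
    },
    lp = {
      w3 <- 0
      for (u in nx) for (v in o_nbrs(g, u)) {
        if (v != y && o_has_edge(g, v, y)) w3 <- w3 + 1
      }
      length(cn) + eps * w3
    }
  )
}

# naive triple-rule FCN classification and contributions for a pair,
# testing each candidate i against the three printed rules directly
o_fcn <- function(g, c2m, x, y) {
  t1 <- integer(0); t2 <- integer(0); t3 <- integer(0)
  c1 <- 0; c2 <- 0; c3 <- 0
  for (i in seq_len(g$n_nodes)) {
    if (i == x || i == y) next
    r_xi <- as.numeric(o_has_edge(g, x, i))
    r_iy <- as.numeric(o_has_edge(g, i, y))
    s_xi <- c2m[x, i]; s_iy <- c2m[i, y]
    if (r_xi * s_iy != 0) t1 <- c(t1, i)
    if (s_xi * r_iy != 0) t2 <- c(t2, i)
    if (s_xi * s_iy != 0 && !(r_xi * s_iy != 0) && !(s_xi * r_iy != 0)) {
      t3 <- c(t3, i)
    }
    c1 <- c1 + r_xi * s_iy
    c2 <- c2 + s_xi * r_iy
    c3 <- c3 + s_xi * s_iy
  }
  list(type1 = t1, type2 = t2, type3 = t3,
       contribution1 = c1, contribution2 = c2, contribution3 = c3,
       total = c1 + c2 + c3)
}

# exhaustive compare-every-pair AUC
o_auc <- function(scores, split, g_full) {
  pos <- scores[split$probe_edges]
  a <- as.matrix(g_full$adj)
  neg <- scores[upper.tri(a) & a == 0]
  cmp <- outer(pos, neg, ">")
  tie <- outer(pos, neg, "==")
  (sum(cmp) + 0.5 * sum(tie)) / (length(pos) * length(neg))
}

# full sort-and-count precision oracle
o_precision <- function(scores, split, g_full, L) {
  n <- nrow(scores)
  gt <- lp_graph(split$training_edges, n_nodes = n)
  at <- as.matrix(gt$adj)
  idx <- which(upper.tri(at) & at == 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], s = scores[idx])
  df <- df[order(-df$s, df$i, df$j), ]
  top <- df[seq_len(L), ]
  hit <- mapply(function(i, j) {
    any(split$probe_edges[, 1] == i & split$probe_edges[, 2] == j)
  }, top$i, top$j)
  sum(hit) / L
}

all_indexes <- c("cn", "salton", "ra", "hpi", "hdi", "lhn", "lnbra", "lp")

# small seeded ER graph that is guaranteed splittable
er_graph <- function(seed, n = 20, p = 0.2) {
  generate_graph("erdos_renyi", seed = seed, n = n, p = p)
}

toy_edge_file <- function() {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  write_edge_list(toy_graph(), f)
  f
}
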