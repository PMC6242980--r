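#' Similarity index specification
#'
#' Identifies one of the eight base common-neighbor similarity indexes.
#' The LP index's own path weight (the length-3 walk coefficient) is carried
#' here as `lp_epsilon`, to keep it distinct from the SFCN mixing weights.
#'
#' @param name one of `"cn"`, `"salton"`, `"ra"`, `"hpi"`, `"hdi"`, `"lhn"`,
#'   `"lnbra"`, `"lp"` (case-insensitive).
#' @param lp_epsilon positive weight of the `A^3` term of the LP index;
#'   ignored by the other indexes. Default 0.001.
#' @return An object of class `index_spec`.
#' @seealso [score_pair()], [score_matrix()]
#' @export
index_spec <- function(name, lp_epsilon = 0.001) {
  name <- tolower(name)
  valid <- c("cn", "salton", "ra", "hpi", "hdi", "lhn", "lnbra", "lp")
  if (!name %in% valid) {
    stop("unknown index '", name, "'; valid: ", paste(valid, collapse = ", "))
  }
  if (name == "lp" && (!is.numeric(lp_epsilon) || lp_epsilon <= 0)) {
    stop("lp_epsilon must be > 0")
  }
  structure(list(name = name, lp_epsilon = lp_epsilon), class = "index_spec")
}

#' @export
print.index_spec <- function(x, ...) {
  cat("similarity index:", toupper(x$name))
  if (x$name == "lp") cat(" (epsilon =", x$lp_epsilon, ")")
  cat("\n")
  invisible(x)
}

method_label <- function(method) {
  if (inherits(method, "index_spec")) return(toupper(method$name))
  if (inherits(method, "sfcn_config")) {
    return(paste0("SFCN-", toupper(method$c1$name), "-",
                  toupper(method$c2$name)))
  }
  if (is.function(method)) return("custom")
  stop("unsupported method object")
}

common_neighbors <- function(g, x, y) {
  intersect(node_neighbors(g, x), node_neighbors(g, y))
}

lnbra_eta <- function(g) {
  m <- n_edges(g)
  if (m < 1L) stop("LNBRA requires at least one training edge")
  n <- g$n_nodes
  # (n(n-1) - 2m) / (2m); written this way the toy-graph log cancellation
  # is exact in doubles
  eta <- (n * (n - 1) - 2 * m) / (2 * m)
  if (eta <= 0) stop("LNBRA undefined: graph has no nonexistent links")
  eta
}

# per-neighbor role factor of LNBRA: (1/k_z) * log2(eta * R_z)
lnbra_weights <- function(g) {
  eta <- lnbra_eta(g)
  k <- degrees(g)
  a <- as.matrix(g$adj)
  a3diag <- diag(a %*% a %*% a)
  n_delta <- a3diag / 2               # connected pairs among Gamma(z)
  n_nabla <- k * (k - 1) / 2 - n_delta
  w <- ifelse(k > 0, (1 / k) * log2(eta * (n_delta + 1) / (n_nabla + 1)), 0)
  w
}

#' Similarity score of one node pair
#'
#' Per-pair form of the eight base indexes, computed directly from neighbor
#' sets (the all-pairs [score_matrix()] is computed by matrix products; the
#' two routes agree entrywise). With `Gamma_x` the neighbor set and `k_x` the
#' degree of `x`:
#'
#' * CN: `|Gamma_x n Gamma_y|`
#' * Salton: `CN / sqrt(k_x k_y)`
#' * RA: `sum_z 1/k_z` over common neighbors `z`
#' * HPI: `CN / min(k_x, k_y)`
#' * HDI: `CN / max(k_x, k_y)`
#' * LHN: `CN / (k_x k_y)`
#' * LNBRA: `sum_z (1/k_z) (log2 eta + log2 R_z)`, where
#'   `eta = |V|(|V|-1)/(2|E|) - 1` and `R_z = (N_tri + 1)/(N_open + 1)`
#'   compares the connected vs disconnected node pairs among `Gamma(z)`;
#'   may be negative
#' * LP: `(A^2)_xy + epsilon (A^3)_xy`
#'
#' Indexes with a degree denominator return 0 when the denominator is 0 (an
#' isolated endpoint has no common neighbors anyway).
#'
#' @param g an [lp_graph]; for LNBRA this is the training graph.
#' @param x,y distinct node ids.
#' @param spec an [index_spec], or an index name passed to [index_spec()].
#' @param lp_epsilon used when `spec` is the name `"lp"`.
#' @return A single numeric score.
#' @examples
#' g <- toy_graph()
#' score_pair(g, 1, 4, "cn")      # 2 common neighbors
#' score_pair(g, 1, 4, "ra")      # 1/3 + 1/3
#' @export
score_pair <- function(g, x, y, spec, lp_epsilon = 0.001) {
  if (!inherits(spec, "index_spec")) spec <- index_spec(spec, lp_epsilon)
  x <- as.integer(x); y <- as.integer(y)
  if (x == y) stop("x and y must be distinct (the diagonal is fixed at 0)")
  cn <- common_neighbors(g, x, y)
  k <- degrees(g)
  switch(spec$name,
    cn = length(cn),
    salton = if (k[x] * k[y] == 0) 0 else length(cn) / sqrt(k[x] * k[y]),
    ra = if (length(cn)) sum(1 / k[cn]) else 0,
    hpi = if (min(k[x], k[y]) == 0) 0 else length(cn) / min(k[x], k[y]),
    hdi = if (max(k[x], k[y]) == 0) 0 else length(cn) / max(k[x], k[y]),
    lhn = if (k[x] * k[y] == 0) 0 else length(cn) / (k[x] * k[y]),
    lnbra = {
      eta <- lnbra_eta(g)
      if (!length(cn)) 0 else {
        s <- 0
        for (z in cn) {
          nb <- node_neighbors(g, z)
          n_delta <- sum(as.matrix(g$adj)[nb, nb]) / 2
          n_nabla <- k[z] * (k[z] - 1) / 2 - n_delta
          s <- s + (1 / k[z]) * log2(eta * (n_delta + 1) / (n_nabla + 1))
        }
        s
      }
    },
    lp = {
      if (spec$lp_epsilon <= 0) stop("lp_epsilon must be > 0")
      # (A^3)_xy = number of length-3 walks x -> u -> v -> y
      w3 <- 0
      for (u in node_neighbors(g, x)) {
        w3 <- w3 + length(common_neighbors(g, u, y))
      }
      length(cn) + spec$lp_epsilon * w3
    }
  )
}

#' All-pairs similarity score matrix
#'
#' Dense symmetric |V| x |V| matrix of the chosen index with zero diagonal,
#' computed by adjacency-matrix products. Entrywise equal to [score_pair()]
#' on every off-diagonal pair. Scores between already-connected nodes are
#' computed like any other pair; prediction later restricts the ranking to
#' non-training pairs.
#'
#' @inheritParams score_pair
#' @return Numeric matrix with `rownames`/`colnames` set to the node labels.
#' @export
score_matrix <- function(g, spec, lp_epsilon = 0.001) {
  if (!inherits(spec, "index_spec")) spec <- index_spec(spec, lp_epsilon)
  a <- as.matrix(g$adj)
  k <- rowSums(a)
  cn <- a %*% a
  s <- switch(spec$name,
    cn = cn,
    salton = zero_where(cn / sqrt(outer(k, k)), outer(k, k) == 0),
    ra = a %*% (a * ifelse(k > 0, 1 / k, 0)),
    hpi = zero_where(cn / outer(k, k, pmin), outer(k, k, pmin) == 0),
    hdi = zero_where(cn / outer(k, k, pmax), outer(k, k, pmax) == 0),
    lhn = zero_where(cn / outer(k, k), outer(k, k) == 0),
    lnbra = a %*% (a * lnbra_weights(g)),
    lp = {
      if (spec$lp_epsilon <= 0) stop("lp_epsilon must be > 0")
      cn + spec$lp_epsilon * cn %*% a
    }
  )
  diag(s) <- 0
  dimnames(s) <- list(g$labels, g$labels)
  s
}

zero_where <- function(m, mask) {
  m[mask] <- 0
  m
}

#' Export / import a score matrix as a long-form table
#'
#' `score_matrix_to_df()` flattens the strict upper triangle to the columns
#' `node_label_1`, `node_label_2`, `score`; `score_matrix_from_df()` inverts
#' it (the round trip is lossless for a symmetric zero-diagonal matrix).
#'
#' @param g the [lp_graph] the matrix was computed on.
#' @param m a symmetric score matrix from [score_matrix()] or
#'   [sfcn_score_matrix()].
#' @param df a data.frame as produced by `score_matrix_to_df()`.
#' @return A data.frame, or a numeric matrix respectively.
#' @export
score_matrix_to_df <- function(g, m) {
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    node_label_1 = g$labels[idx[, 1]],
    node_label_2 = g$labels[idx[, 2]],
    score = m[idx],
    stringsAsFactors = FALSE
  )
}

#' @rdname score_matrix_to_df
#' @export
score_matrix_from_df <- function(g, df) {
  m <- matrix(0, g$n_nodes, g$n_nodes,
              dimnames = list(g$labels, g$labels))
  i <- match(df$node_label_1, g$labels)
  j <- match(df$node_label_2, g$labels)
  if (anyNA(i) || anyNA(j)) stop("unknown node label in score table")
  m[cbind(i, j)] <- df$score
  m[cbind(j, i)] <- df$score
  m
}
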