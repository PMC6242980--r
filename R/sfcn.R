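#' SFCN model configuration
#'
#' The similarity-based future common neighbors (SFCN) score of a node pair
#' (x, y) mixes two pluggable base indexes:
#'
#' `s_xy = alpha * C1(x, y) + beta * (Gamma_x . S_y + S_x . Gamma_y + S_x . S_y)`
#'
#' where `Gamma_x` is the 0/1 connection row of `x`, `S_x` the row of C2
#' scores of `x` (entries at positions x and y forced to 0), and the three
#' dot products accumulate the contributions of the three classes of future
#' common neighbors: nodes already linked to x, nodes already linked to y,
#' and nodes linked to neither but with nonzero C2 similarity to both.
#'
#' @param c1 base index scoring the target pair directly (the current
#'   common-neighbor term); an [index_spec] or an index name.
#' @param c2 base index scoring the candidate links that would create future
#'   common neighbors; an [index_spec] or an index name.
#' @param alpha weight of the current common-neighbor term (>= 0). Default 9.
#' @param beta weight of the future common-neighbor term (>= 0). Default 1.
#'   The defaults are the operating point used for method comparison after a
#'   grid calibration; `alpha` and `beta` may not both be 0.
#' @param lp_epsilon LP path weight, applied when `c1` or `c2` is `"lp"`.
#' @param strict_fcn if `TRUE`, C2 entries of nodes that are already current
#'   common neighbors of the pair are zeroed before the dot products, so only
#'   nodes that are not yet common neighbors contribute to the beta term.
#'   Off by default: the operative model scores every node's terms.
#' @return An object of class `sfcn_config`.
#' @export
sfcn_config <- function(c1 = "cn", c2 = "ra", alpha = 9, beta = 1,
                        lp_epsilon = 0.001, strict_fcn = FALSE) {
  if (!inherits(c1, "index_spec")) c1 <- index_spec(c1, lp_epsilon)
  if (!inherits(c2, "index_spec")) c2 <- index_spec(c2, lp_epsilon)
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (alpha == 0 && beta == 0) stop("alpha and beta may not both be 0")
  structure(list(c1 = c1, c2 = c2, alpha = alpha, beta = beta,
                 strict_fcn = isTRUE(strict_fcn)),
            class = "sfcn_config")
}

#' @export
print.sfcn_config <- function(x, ...) {
  cat(sprintf("%s (alpha = %g, beta = %g%s)\n", method_label(x),
              x$alpha, x$beta, if (x$strict_fcn) ", strict FCN" else ""))
  invisible(x)
}

#' Per-pair connection and similarity vectors
#'
#' Builds the four length-|V| vectors the SFCN score is assembled from:
#' `gamma_x[i] = 1` iff (x, i) is an edge, `s_x[i]` = the C2 score of
#' (x, i), and likewise for y; positions x and y are then forced to 0 in all
#' four vectors (the non-self-connection rule).
#'
#' @param g an [lp_graph].
#' @param c2_matrix C2 [score_matrix()] built on `g`.
#' @param x,y distinct node ids.
#' @param strict_fcn zero the C2 entries of current common neighbors of
#'   (x, y); see [sfcn_config()].
#' @return An object of class `pair_vectors`: list with numeric vectors
#'   `gamma_x`, `gamma_y`, `s_x`, `s_y` and the ids `x`, `y`.
#' @export
build_pair_vectors <- function(g, c2_matrix, x, y, strict_fcn = FALSE) {
  x <- as.integer(x); y <- as.integer(y)
  if (x == y) stop("x and y must be distinct")
  a <- g$adj
  gamma_x <- as.numeric(a[x, ])
  gamma_y <- as.numeric(a[y, ])
  s_x <- as.numeric(c2_matrix[x, ])
  s_y <- as.numeric(c2_matrix[, y])
  if (isTRUE(strict_fcn)) {
    ccn <- gamma_x * gamma_y != 0
    s_x[ccn] <- 0
    s_y[ccn] <- 0
  }
  zero_at <- c(x, y)
  gamma_x[zero_at] <- 0; gamma_y[zero_at] <- 0
  s_x[zero_at] <- 0; s_y[zero_at] <- 0
  structure(list(gamma_x = gamma_x, gamma_y = gamma_y,
                 s_x = s_x, s_y = s_y, x = x, y = y),
            class = "pair_vectors")
}

#' Identify the future common neighbors of a pair
#'
#' Classifies every candidate node i (excluding x and y) into the three
#' future-common-neighbor types and accumulates their contributions:
#'
#' * type 1 — already linked to x, nonzero C2 score to y
#'   (`gamma_x[i] * s_y[i] != 0`); contribution1 = `Gamma_x . S_y`.
#' * type 2 — already linked to y, nonzero C2 score to x
#'   (`s_x[i] * gamma_y[i] != 0`); contribution2 = `S_x . Gamma_y`.
#' * type 3 — linked to neither, nonzero C2 score to both
#'   (`s_x[i] * s_y[i] != 0`), reported net of type-1/2 membership so the
#'   three sets are disjoint; contribution3 = `S_x . S_y` in full (a node
#'   may contribute to more than one dot product).
#'
#' @param v a [build_pair_vectors()] result.
#' @return An object of class `fcn_report`: integer vectors `type1`,
#'   `type2`, `type3` and numerics `contribution1..3`,
#'   `total_future_contribution` (their sum; the coefficient of beta).
#' @export
identify_fcn <- function(v) {
  stopifnot(inherits(v, "pair_vectors"))
  t1 <- which(v$gamma_x * v$s_y != 0)
  t2 <- which(v$s_x * v$gamma_y != 0)
  t3 <- setdiff(which(v$s_x * v$s_y != 0), union(t1, t2))
  c1 <- sum(v$gamma_x * v$s_y)
  c2 <- sum(v$s_x * v$gamma_y)
  c3 <- sum(v$s_x * v$s_y)
  structure(list(type1 = t1, type2 = t2, type3 = t3,
                 contribution1 = c1, contribution2 = c2, contribution3 = c3,
                 total_future_contribution = c1 + c2 + c3,
                 x = v$x, y = v$y),
            class = "fcn_report")
}

#' @export
print.fcn_report <- function(x, ...) {
  fmt <- function(s) if (length(s)) paste(s, collapse = ", ") else "-"
  cat(sprintf("future common neighbors of (%d, %d)\n", x$x, x$y))
  cat(sprintf("  type 1 (linked to x): {%s}  contribution %.6g\n",
              fmt(x$type1), x$contribution1))
  cat(sprintf("  type 2 (linked to y): {%s}  contribution %.6g\n",
              fmt(x$type2), x$contribution2))
  cat(sprintf("  type 3 (linked to neither): {%s}  contribution %.6g\n",
              fmt(x$type3), x$contribution3))
  cat(sprintf("  total future contribution: %.6g (coefficient of beta)\n",
              x$total_future_contribution))
  invisible(x)
}

#' Serialize an FCN report to JSON
#'
#' @param report an [identify_fcn()] result.
#' @param labels optional node-label vector; ids are translated if given.
#' @return A JSON string.
#' @export
fcn_report_json <- function(report, labels = NULL) {
  lab <- function(ids) {
    if (is.null(labels)) as.character(ids) else labels[ids]
  }
  jsonlite::toJSON(list(
    pair = lab(c(report$x, report$y)),
    type1 = lab(report$type1), type2 = lab(report$type2),
    type3 = lab(report$type3),
    contribution1 = report$contribution1,
    contribution2 = report$contribution2,
    contribution3 = report$contribution3,
    total_future_contribution = report$total_future_contribution
  ), auto_unbox = FALSE, digits = NA)
}

#' SFCN score of one node pair
#'
#' `alpha * c1_matrix[x, y] + beta * (Gamma_x . S_y + S_x . Gamma_y +
#' S_x . S_y)` with the vectors of [build_pair_vectors()].
#'
#' @param g an [lp_graph].
#' @param c1_matrix,c2_matrix score matrices built on `g` with the config's
#'   C1 and C2 indexes.
#' @param x,y distinct node ids.
#' @param cfg an [sfcn_config()].
#' @return A single numeric score.
#' @export
sfcn_score <- function(g, c1_matrix, c2_matrix, x, y, cfg) {
  v <- build_pair_vectors(g, c2_matrix, x, y, strict_fcn = cfg$strict_fcn)
  fr <- identify_fcn(v)
  cfg$alpha * c1_matrix[x, y] + cfg$beta * fr$total_future_contribution
}

# beta-term matrix: A.S + S.A + S.S. The per-pair zeroing of positions x, y
# is automatic here because A and S both have zero diagonals, so every
# excluded term multiplies a diagonal entry.
fcn_contribution_matrix <- function(g, c2_matrix) {
  a <- as.matrix(g$adj)
  s <- c2_matrix
  f <- a %*% s + s %*% a + s %*% s
  diag(f) <- 0
  f
}

#' All-pairs SFCN score matrix
#'
#' Builds the C1 and C2 matrices once on `g`, then scores every unordered
#' pair. Symmetric with zero diagonal; entrywise equal to per-pair
#' [sfcn_score()]. In strict-FCN mode the zeroing depends on the pair, so
#' the matrix is assembled pair by pair; otherwise three matrix products
#' suffice.
#'
#' @param g an [lp_graph].
#' @param cfg an [sfcn_config()].
#' @return Numeric matrix with node labels as dimnames.
#' @export
sfcn_score_matrix <- function(g, cfg) {
  c1m <- score_matrix(g, cfg$c1)
  c2m <- score_matrix(g, cfg$c2)
  if (cfg$strict_fcn) {
    n <- g$n_nodes
    s <- matrix(0, n, n)
    for (x in seq_len(n - 1)) {
      for (y in (x + 1):n) {
        s[x, y] <- s[y, x] <- sfcn_score(g, c1m, c2m, x, y, cfg)
      }
    }
  } else {
    s <- cfg$alpha * c1m + cfg$beta * fcn_contribution_matrix(g, c2m)
  }
  diag(s) <- 0
  dimnames(s) <- list(g$labels, g$labels)
  s
}
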