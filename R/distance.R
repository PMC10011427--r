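#' Dissimilarity functions for object rows
#'
#' Pairwise dissimilarities between two observation vectors.  These are the
#' building blocks of [pairwise_distances()] and are exported mainly for
#' checking and small-scale work; the matrix versions are vectorized.
#'
#' * `euclidean_dist()`: `sqrt(sum((x - y)^2))`.
#' * `canberra_dist()`: `sum(|x - y| / (|x| + |y|))`, with a term defined
#'   as 0 whenever `x_l = y_l = 0` (the usual 0/0 convention).
#' * `matching_dist()`: one minus the simple matching similarity, i.e. the
#'   fraction of variables on which the two objects disagree; in `[0, 1]`.
#'
#' @param x,y vectors of equal length.
#' @return a single non-negative number.
#' @examples
#' euclidean_dist(c(0, 0), c(3, 4))       # 5
#' canberra_dist(c(0, 1), c(1, 1))        # 1
#' matching_dist(c(1, 0, 2, 2), c(1, 0, 2, 1))  # 0.25
#' @name row_distances
NULL

#' @rdname row_distances
#' @export
euclidean_dist <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  sqrt(sum((x - y)^2))
}

#' @rdname row_distances
#' @export
canberra_dist <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  num <- abs(x - y)
  den <- abs(x) + abs(y)
  term <- ifelse(den == 0, 0, num / den)
  sum(term)
}

#' @rdname row_distances
#' @export
matching_dist <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  1 - mean(x == y)
}

#' Generalized (Gower-type) distance between two mixed rows
#'
#' A weighted additive dissimilarity for complete mixed data:
#' `d = (alpha * sum(delta_b) + beta * sum(delta_c) + gamma * sum(delta_n))^omega`
#' where `delta_b` and `delta_c` are 0/1 mismatch indicators on binary and
#' nominal variables and `delta_n` is the absolute difference on numeric
#' variables.  Numeric (and rank-scaled ordinal) parts are expected on a
#' common `[0, 1]` scale -- apply [minmax_standardize()] first.  With the
#' default weights `(1, 1, 1, 1)` this is a plain summed dissimilarity,
#' unnormalized by the number of variables.
#'
#' @param x,y rows conforming to `kinds`.
#' @param kinds per-variable kind: `"binary"`, `"nominal"`, `"ordinal"`
#'   (treated as numeric after rank scaling) or `"numeric"`.
#' @param weights numeric `(alpha, beta, gamma, omega)`, default all 1.
#' @return a single non-negative number.
#' @examples
#' gower_dist(c(1, 0, 0.2), c(0, 0, 0.7), kinds = c("binary", "binary", "numeric"))
#' # one binary mismatch + |0.2 - 0.7| = 1.5
#' @export
gower_dist <- function(x, y, kinds, weights = c(1, 1, 1, 1)) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(kinds) != length(x)) stop("schema does not match the rows")
  b <- kinds == "binary"
  cc <- kinds == "nominal"
  nn <- kinds %in% c("numeric", "ordinal")
  (weights[1] * sum(x[b] != y[b]) +
   weights[2] * sum(x[cc] != y[cc]) +
   weights[3] * sum(abs(x[nn] - y[nn])))^weights[4]
}

resolve_method <- function(method, kinds) {
  method <- match.arg(method,
                      c("auto", "euclidean", "canberra", "matching", "gower"))
  if (method != "auto") return(method)
  if (all(kinds == "numeric")) "euclidean"
  else if (all(kinds %in% c("binary", "nominal"))) "matching"
  else "gower"
}

#' All pairwise dissimilarities of a feature table
#'
#' Computes the full `n x n` symmetric dissimilarity matrix under one of the
#' supported methods.  `"auto"` picks Euclidean for all-numeric tables,
#' simple matching for all-categorical tables and the generalized Gower
#' distance for mixed tables.
#'
#' @param ft a [feature_table] (standardized beforehand where the method
#'   assumes `[0, 1]` comparability; see [minmax_standardize()]).
#' @param method `"auto"`, `"euclidean"`, `"canberra"`, `"matching"` or
#'   `"gower"`.
#' @param weights Gower weights `(alpha, beta, gamma, omega)`.
#' @return an `n x n` numeric matrix with zero diagonal, row/column names
#'   set to the object identifiers and the method in attribute `"method"`.
#' @export
pairwise_distances <- function(ft, method = "auto", weights = c(1, 1, 1, 1)) {
  stopifnot(inherits(ft, "feature_table"))
  X <- ft$values
  kinds <- ft$schema$kind
  method <- resolve_method(method, kinds)
  n <- nrow(X)
  D <- switch(method,
    euclidean = as.matrix(stats::dist(X)),
    canberra = {
      M <- matrix(0, n, n)
      for (j in seq_len(ncol(X))) {
        num <- abs(outer(X[, j], X[, j], "-"))
        den <- outer(abs(X[, j]), abs(X[, j]), "+")
        term <- num / den
        term[den == 0] <- 0
        M <- M + term
      }
      M
    },
    matching = {
      M <- matrix(0, n, n)
      for (j in seq_len(ncol(X))) M <- M + outer(X[, j], X[, j], "!=")
      M / ncol(X)
    },
    gower = {
      b <- kinds == "binary"; cc <- kinds == "nominal"
      nn <- kinds %in% c("numeric", "ordinal")
      acc <- function(cols, mismatch) {
        M <- matrix(0, n, n)
        for (j in which(cols))
          M <- M + if (mismatch) outer(X[, j], X[, j], "!=")
                   else abs(outer(X[, j], X[, j], "-"))
        M
      }
      (weights[1] * acc(b, TRUE) + weights[2] * acc(cc, TRUE) +
       weights[3] * acc(nn, FALSE))^weights[4]
    })
  dimnames(D) <- list(ft$ids, ft$ids)
  attr(D, "method") <- method
  D
}

#' Distances of every object to a set of medoids
#'
#' The `n x k` matrix of dissimilarities from each object to each medoid --
#' the only proximity structure the deviation ratio index needs.  Column `g`
#' holds the distance of every object to medoid `g`; the entry of a medoid
#' against its own column is zero.
#'
#' @param ft a [feature_table].
#' @param medoids distinct 1-based object indices.
#' @inheritParams pairwise_distances
#' @param pairwise optionally, a precomputed matrix from
#'   [pairwise_distances()] to avoid recomputation.
#' @return an `n x k` matrix of class `"medoid_distances"` with the medoid
#'   indices in attribute `"medoids"`.
#' @export
medoid_distances <- function(ft, medoids, method = "auto",
                             weights = c(1, 1, 1, 1), pairwise = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  n <- nrow(ft$values)
  medoids <- as.integer(medoids)
  if (anyDuplicated(medoids)) stop("medoid indices must be distinct")
  if (any(medoids < 1L) || any(medoids > n))
    stop("medoid indices must lie in 1..", n)
  if (is.null(pairwise)) pairwise <- pairwise_distances(ft, method, weights)
  md <- pairwise[, medoids, drop = FALSE]
  colnames(md) <- ft$ids[medoids]
  structure(md, medoids = medoids, class = c("medoid_distances", "matrix"))
}
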