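#' Per-object deviation statistics and block ordering
#'
#' The seeding stage of block-based k-medoids summarizes every object row by
#' its sum `w_i = sum_l x_il` and its sample standard deviation
#' `u_i = sqrt(sum_l (x_il - mean_i)^2 / (p - 1))`, then sorts objects
#' ascending in `u_i`, breaking ties ascending in `w_i` and then by original
#' index.  A *block* is a maximal run of exactly equal `u_i` values in this
#' ordering.
#'
#' Row statistics are computed on the values as supplied; standardize first
#' ([minmax_standardize()]) when variables live on different scales.
#'
#' @param ft a [feature_table] with `p >= 2` variables.
#' @return an object of class `"block_ordering"`: list with `u`, `w`
#'   (per-object, input order), `order` (positional sort), and `block`
#'   (block id per sorted position).
#' @export
block_order <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  X <- ft$values
  p <- ncol(X)
  if (p < 2L) stop("row deviation needs at least p = 2 variables")
  w <- rowSums(X)
  u <- sqrt(rowSums((X - w / p)^2) / (p - 1))
  ord <- order(u, w, seq_len(nrow(X)))
  block <- cumsum(!duplicated(u[ord]))
  structure(list(u = unname(u), w = unname(w), order = ord, block = block,
                 ids = ft$ids),
            class = "block_ordering")
}

#' @export
print.block_ordering <- function(x, ...) {
  cat("Block ordering of", length(x$u), "objects in", max(x$block), "blocks\n")
  head_n <- min(5L, length(x$order))
  i <- x$order[seq_len(head_n)]
  cat("First", head_n, "objects:", paste(x$ids[i], collapse = ", "), "\n")
  invisible(x)
}

#' Initial medoids from the deviation blocks
#'
#' Takes the first object of each of the first `k` blocks of the
#' `(u_i, w_i)` ordering.  When fewer than `k` distinct deviation blocks
#' exist (heavily tied data), falls back to the first `k` objects in sorted
#' order.
#'
#' @param ordering a [block_order()] result.
#' @param k number of clusters, `2 <= k <= n`.
#' @return integer vector of `k` distinct object indices.
#' @export
initial_medoids <- function(ordering, k) {
  stopifnot(inherits(ordering, "block_ordering"))
  n <- length(ordering$u)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("'k' must lie in 2..n (n = ", n, ")")
  firsts <- ordering$order[!duplicated(ordering$block)]
  if (length(firsts) >= k) firsts[seq_len(k)] else ordering$order[seq_len(k)]
}

# Nearest-medoid assignment.  Ties go to the lowest medoid position, except
# that a medoid always anchors its own cluster (duplicate rows can make two
# medoids coincide; without the pin one cluster would silently empty).
assign_to_medoids <- function(D, medoids) {
  lab <- max.col(-D[, medoids, drop = FALSE], ties.method = "first")
  lab[medoids] <- seq_along(medoids)
  lab
}

# Per-cluster medoid update: the member minimizing the average distance to
# the other members of its cluster; ties broken by lowest object index.
update_medoids <- function(D, labels, k = max(labels)) {
  vapply(seq_len(k), function(g) {
    members <- which(labels == g)
    if (length(members) == 0L)
      stop("cluster ", g, " is empty during the medoid update")
    members[which.min(colSums(D[members, members, drop = FALSE]))]
  }, integer(1))
}

#' Block-based k-medoids partitioning
#'
#' Partitions `n` objects into `k` clusters, each represented by a medoid (a
#' real data object), using deterministic deviation-block seeding followed
#' by alternating nearest-medoid assignment and per-cluster medoid updates:
#'
#' 1. Compute per-object row sums and standard deviations ([block_order()]).
#' 2. Seed one initial medoid from each of the first `k` deviation blocks
#'    ([initial_medoids()]).
#' 3. Assign every object to its nearest medoid.
#' 4. Replace each cluster's medoid by the member minimizing the average
#'    distance to its co-members, reassign, and repeat until the medoid set
#'    is unchanged, the within-group deviation `SDW(k)` exactly repeats, or
#'    `max_iter` is reached.
#'
#' `SDW(k) = sum_i d(x_i, m(x_i))` -- the summed distance of all objects to
#' their own cluster medoid -- is recorded after every assignment and is
#' non-increasing across iterations.  All ties (sorting, assignment, medoid
#' update) break towards the lowest index, so the algorithm is fully
#' deterministic and seed-free.
#'
#' @param ft a [feature_table]; standardize first where appropriate.
#' @param k number of clusters, `2 <= k <= n`.
#' @inheritParams pairwise_distances
#' @param max_iter safety cap on update rounds.
#' @param pairwise optional precomputed [pairwise_distances()] matrix.
#' @return an object of class `"block_kmedoids"`: list with `labels`
#'   (1-based cluster per object), `medoids` (object indices), `medoid_ids`,
#'   `sdw` (final within-group deviation), `sdw_history` (one value per
#'   assignment, starting from the seeding), `iterations` (update rounds
#'   performed), `converged`, `k`, `n`, and `method`.
#' @examples
#' env <- environment_scores()
#' fit <- block_kmedoids(env, k = 3)
#' fit$medoid_ids
#' @export
block_kmedoids <- function(ft, k, method = "auto", weights = c(1, 1, 1, 1),
                           max_iter = 100L, pairwise = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  n <- nrow(ft$values)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("'k' must lie in 2..n (n = ", n, ")")
  if (is.null(pairwise)) pairwise <- pairwise_distances(ft, method, weights)
  D <- pairwise
  ord <- block_order(ft)
  med <- initial_medoids(ord, k)
  lab <- assign_to_medoids(D, med)
  sdw_of <- function(med, lab) sum(D[cbind(seq_len(n), med[lab])])
  history <- sdw_of(med, lab)
  iter <- 0L
  converged <- TRUE
  repeat {
    iter <- iter + 1L
    new_med <- update_medoids(D, lab, k)
    if (all(new_med == med)) break
    med <- new_med
    lab <- assign_to_medoids(D, med)
    s <- sdw_of(med, lab)
    history <- c(history, s)
    if (s == history[length(history) - 1L]) break
    if (iter >= max_iter) {
      converged <- FALSE
      warning("block_kmedoids did not converge in ", max_iter, " iterations")
      break
    }
  }
  structure(list(labels = lab, medoids = med, medoid_ids = ft$ids[med],
                 sdw = history[length(history)], sdw_history = history,
                 iterations = iter, converged = converged,
                 k = k, n = n, method = attr(D, "method")),
            class = "block_kmedoids")
}

#' @export
print.block_kmedoids <- function(x, ...) {
  cat("Block-based k-medoids: k =", x$k, "on n =", x$n,
      "objects (", x$method, "distance )\n")
  cat("Medoids:", paste(x$medoid_ids, collapse = ", "), "\n")
  cat("SDW per assignment:", paste(formatC(x$sdw_history, format = "fg",
                                           digits = 4), collapse = " -> "), "\n")
  cat("Cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  if (!x$converged) cat("NOTE: stopped at the iteration cap\n")
  invisible(x)
}
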