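#' Within- and between-group deviation from medoid distances
#'
#' `sdw()` is the within-group deviation `SDW(k) = sum_i d(x_i, m(x_i))`:
#' every object's distance to its own cluster's medoid, summed.  `sdb()` is
#' the between-group deviation `SDB(k) = sum_i sum_{g != g(i)} d(x_i, m_g)`:
#' every object's distances to the `k - 1` medoids of the *other* clusters,
#' summed.  Both need only the `n x k` object-to-medoid matrix.
#'
#' @param md a [medoid_distances()] matrix (`n x k`).
#' @param labels cluster assignment in `1..k`, consistent with the medoid
#'   columns of `md`.
#' @return a single non-negative number.
#' @export
sdw <- function(md, labels) {
  k <- ncol(md)
  if (length(labels) != nrow(md) || any(labels < 1L) || any(labels > k))
    stop("labels do not match the medoid-distance matrix")
  sum(md[cbind(seq_len(nrow(md)), labels)])
}

#' @rdname sdw
#' @export
sdb <- function(md, labels) {
  if (ncol(md) < 2L) stop("between-group deviation needs k >= 2")
  sum(md) - sdw(md, labels)
}

#' Deviation ratio for a k-cluster solution
#'
#' `DR(k) = (SDW(k) / (n - k)) / (SDB(k) / (k - 1))` -- the within-group
#' deviation per residual degree of freedom relative to the between-group
#' deviation per added cluster.  Compact, well-separated partitions give
#' small values; `DR(k) = 0` exactly when every object coincides with its
#' medoid (perfect separation).  Not defined for `k = 1`.
#'
#' @param sdw,sdb within- and between-group deviations (see [sdw()]).
#' @param n number of objects.
#' @param k number of clusters, `2 <= k < n`.
#' @return a single non-negative number.
#' @export
deviation_ratio <- function(sdw, sdb, n, k) {
  if (k < 2 || k >= n) stop("'k' must lie in 2..(n - 1)")
  if (sdb <= 0) stop("SDB is zero: all objects coincide with all medoids")
  (sdw / (n - k)) / (sdb / (k - 1))
}

#' Deviation ratio index curve over a range of cluster numbers
#'
#' Fits [block_kmedoids()] for every `k` in `k_min..k_max`, computes the
#' deviation ratio `DR(k)` from the final medoids, and forms the deviation
#' ratio index `DRI(k) = DR(k) / DR(k + 1)` for `k < k_max`.  The chosen
#' number of clusters (rule `"dri"` in [select_k()]) is the smallest `k`
#' with `DRI(k) < 1`, i.e. the first `k` whose deviation ratio is beaten by
#' its own successor -- by parsimony, the smallest size after which adding a
#' cluster stops paying.
#'
#' Optionally computes comparator indices per `k`: the distance-based
#' variance ratio criterion ([vrc()]), the mean silhouette width
#' ([silhouette_widths()]) and the mean medoid shadow value
#' ([shadow_values()]).
#'
#' With `early_stop = TRUE` the scan stops at the first `k` with
#' `DR(k) < DR(k + 1)` instead of covering the whole range.
#'
#' @param ft a [feature_table]; standardize first where appropriate.
#' @inheritParams pairwise_distances
#' @param k_min,k_max cluster-number range, `2 <= k_min <= k_max < n`.
#' @param indices character subset of `c("dri", "vrc", "silhouette", "msv")`.
#' @param early_stop stop scanning at the first `k` with `DR(k) < DR(k+1)`.
#' @param max_iter per-fit iteration cap.
#' @return an object of class `"dri_curve"`: list with `summary` (one row
#'   per `k`: `k, sdw, sdb, dr, dri`, plus any comparator columns), `fits`
#'   (the `block_kmedoids` objects), `medoid_distances` (per-`k` matrices),
#'   `n`, and `method`.
#' @examples
#' curve <- dri_curve(environment_scores(), k_max = 5)
#' curve$summary
#' select_k(curve)
#' @export
dri_curve <- function(ft, method = "auto", weights = c(1, 1, 1, 1),
                      k_min = 2L, k_max = 10L, indices = "dri",
                      early_stop = FALSE, max_iter = 100L) {
  stopifnot(inherits(ft, "feature_table"))
  n <- nrow(ft$values)
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 2L) stop("'k_min' must be at least 2")
  if (k_max < k_min) stop("'k_max' must be >= 'k_min'")
  if (k_max >= n) stop("'k_max' must be below n = ", n)
  indices <- match.arg(indices, c("dri", "vrc", "silhouette", "msv"),
                       several.ok = TRUE)
  D <- pairwise_distances(ft, method, weights)
  ks <- k_min:k_max
  fits <- vector("list", length(ks))
  mds <- vector("list", length(ks))
  rows <- vector("list", length(ks))
  used <- 0L
  for (i in seq_along(ks)) {
    k <- ks[i]
    fit <- block_kmedoids(ft, k, max_iter = max_iter, pairwise = D)
    md <- medoid_distances(ft, fit$medoids, pairwise = D)
    row <- data.frame(k = k, sdw = sdw(md, fit$labels),
                      sdb = sdb(md, fit$labels))
    row$dr <- deviation_ratio(row$sdw, row$sdb, n, k)
    if ("vrc" %in% indices) row$vrc <- vrc(D, fit$labels)
    if ("silhouette" %in% indices)
      row$silhouette <- mean(silhouette_widths(D, fit$labels))
    if ("msv" %in% indices) row$msv <- mean(shadow_values(md))
    fits[[i]] <- fit; mds[[i]] <- md; rows[[i]] <- row
    used <- i
    if (early_stop && i > 1L && rows[[i - 1L]]$dr < row$dr) break
  }
  summary <- do.call(rbind, rows[seq_len(used)])
  summary$dri <- c(summary$dr[-used] / summary$dr[-1L], NA_real_)
  structure(list(summary = summary, fits = fits[seq_len(used)],
                 medoid_distances = mds[seq_len(used)], n = n,
                 method = attr(D, "method"), early_stop = early_stop),
            class = "dri_curve")
}

#' @export
print.dri_curve <- function(x, digits = 4, ...) {
  cat("Deviation ratio index curve (", x$method, " distance, n = ", x$n,
      ")\n", sep = "")
  print(format(x$summary, digits = digits), row.names = FALSE)
  sel <- select_k(x)
  if (is.na(sel$k)) cat("DRI rule: no k with DRI < 1 in range\n")
  else cat("DRI rule selects k =", sel$k, "\n")
  invisible(x)
}

#' Select the number of clusters from an index curve
#'
#' Rules: `"dri"` -- the smallest `k` with `DRI(k) < 1` (equivalently the
#' first `k` with `DR(k) < DR(k + 1)`); `"vrc"` -- the `k` maximizing the
#' variance ratio criterion; `"silhouette"` -- the `k` maximizing the mean
#' silhouette width; `"msv"` -- the `k` maximizing the mean medoid shadow
#' value (a diagnostic rule, reported for comparison only).
#'
#' @param curve a [dri_curve()] result containing the columns the rule needs.
#' @param rule one of `"dri"`, `"vrc"`, `"silhouette"`, `"msv"`.
#' @return list with `k` (`NA` when no `k` qualifies), `rule`, and `reason`
#'   (`"none in range"` for an empty DRI selection).
#' @export
select_k <- function(curve, rule = c("dri", "vrc", "silhouette", "msv")) {
  stopifnot(inherits(curve, "dri_curve"))
  rule <- match.arg(rule)
  s <- curve$summary
  if (rule == "dri") {
    ok <- which(!is.na(s$dri) & s$dri < 1)
    if (length(ok) == 0L)
      return(list(k = NA_integer_, rule = rule, reason = "none in range"))
    return(list(k = s$k[ok[1L]], rule = rule, reason = NULL))
  }
  col <- c(vrc = "vrc", silhouette = "silhouette", msv = "msv")[[rule]]
  if (is.null(s[[col]]))
    stop("the curve was computed without the '", col, "' index")
  list(k = s$k[which.max(s[[col]])], rule = rule, reason = NULL)
}

#' Distance-based variance ratio criterion (Calinski-Harabasz)
#'
#' `VRC = (BGSS / (k - 1)) / (WGSS / (n - k))`, computed from pairwise
#' distances: `WGSS = (1/2) sum_g (n_g - 1) dbar_g^2`,
#' `BGSS = (1/2) ((k - 1) dbar^2 + (n - k) A_k)` with
#' `A_k = (1/(n - k)) sum_g (n_g - 1)(dbar^2 - dbar_g^2)`, where `dbar^2`
#' and `dbar_g^2` are the mean squared pairwise distances overall and within
#' group `g`.  Larger is better; the maximizing `k` is the VRC choice of the
#' cluster number.  With `squared = FALSE` the means are taken over raw
#' rather than squared distances.
#'
#' @param D full pairwise distance matrix ([pairwise_distances()]).
#' @param labels cluster assignment in `1..k`, all clusters non-empty.
#' @param squared average squared distances (default) or raw distances.
#' @return a single number; `Inf` (perfect separation) when all
#'   within-group distances vanish.
#' @export
vrc <- function(D, labels, squared = TRUE) {
  n <- nrow(D)
  k <- max(labels)
  if (k < 2L) stop("VRC needs k >= 2")
  if (n == k) stop("VRC is undefined for n = k (zero denominator)")
  Dm <- if (squared) D^2 else D
  mean_pair <- function(idx) {
    m <- length(idx)
    if (m < 2L) return(0)
    sum(Dm[idx, idx]) / (m * (m - 1))
  }
  dbar2 <- mean_pair(seq_len(n))
  sizes <- tabulate(labels, k)
  dg2 <- vapply(seq_len(k), function(g) mean_pair(which(labels == g)), 0)
  wgss <- sum((sizes - 1) * dg2) / 2
  ak <- sum((sizes - 1) * (dbar2 - dg2)) / (n - k)
  bgss <- ((k - 1) * dbar2 + (n - k) * ak) / 2
  if (wgss == 0) return(Inf)
  (bgss / (k - 1)) / (wgss / (n - k))
}

#' Silhouette widths of a partition
#'
#' For each object, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)` is
#' the mean distance to the object's own-cluster co-members and `b(i)` the
#' smallest mean distance to the members of another cluster.  Values lie in
#' `[-1, 1]`; members of singleton clusters get 0 by convention.
#'
#' @inheritParams vrc
#' @return numeric vector of per-object widths.
#' @export
silhouette_widths <- function(D, labels) {
  n <- nrow(D)
  k <- max(labels)
  if (k < 2L) stop("silhouette needs k >= 2")
  sizes <- tabulate(labels, k)
  # n x k matrix of summed distances from each object to each cluster
  S <- vapply(seq_len(k), function(g) rowSums(D[, labels == g, drop = FALSE]),
              numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- labels[i]
    if (sizes[g] == 1L) next             # singleton convention: s = 0
    a <- S[i, g] / (sizes[g] - 1L)
    b <- min(S[i, -g] / sizes[-g])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Medoid shadow values
#'
#' For each object, `msv = (d2 - d1) / d2` where `d1` and `d2` are its
#' distances to the closest and second-closest medoid.  Values lie in
#' `[0, 1]`: 1 when the object sits on its medoid, 0 when it is equidistant
#' to its two nearest medoids (and, by convention, when it coincides with
#' two medoids at once).  Larger mean values indicate crisper assignment.
#'
#' @param md a [medoid_distances()] matrix with `k >= 2` columns.
#' @return numeric vector of per-object shadow values.
#' @export
shadow_values <- function(md) {
  if (ncol(md) < 2L) stop("shadow values need k >= 2 medoids")
  apply(md, 1L, function(d) {
    two <- sort(d, partial = 2)[1:2]
    if (two[2] == 0) 0 else (two[2] - two[1]) / two[2]
  })
}

#' Clustering accuracy against known classes
#'
#' The fraction of objects correctly assigned under the best one-to-one
#' mapping between predicted clusters and true classes (the assignment
#' maximizing total agreement, found exactly).  Invariant to any
#' relabelling of the predicted clusters; 1 for a perfect recovery.
#'
#' @param labels predicted cluster labels.
#' @param truth true class labels of the same length.
#' @return a number in `[0, 1]`.
#' @examples
#' clustering_accuracy(c(2, 2, 1, 1), c("a", "a", "b", "b"))   # 1
#' @export
clustering_accuracy <- function(labels, truth) {
  if (length(labels) != length(truth)) stop("label vectors differ in length")
  if (length(labels) == 0L) stop("empty label vectors")
  tab <- table(labels, truth)
  if (nrow(tab) < ncol(tab)) tab <- t(tab)   # DP over the smaller side
  a <- nrow(tab); b <- ncol(tab)
  if (b > 20L) stop("too many classes for exact matching")
  # assignment by dynamic programming over subsets of the smaller side
  best <- rep(-Inf, 2^b); best[1] <- 0
  for (i in seq_len(a)) {
    nxt <- best
    for (mask in which(best > -Inf) - 1L) {
      for (j in seq_len(b)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0L) {
          v <- best[mask + 1L] + tab[i, j]
          if (v > nxt[mask + bit + 1L]) nxt[mask + bit + 1L] <- v
        }
      }
    }
    # rows may stay unmatched when a > b
    best <- pmax(best, nxt)
  }
  max(best) / length(labels)
}
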