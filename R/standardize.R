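#' Min-max standardization of a feature table
#'
#' Rescales every numeric column linearly onto `[0, 1]` by subtracting the
#' column minimum and dividing by the range, and rank-scales every ordinal
#' column via [ordinal_standardize()].  Binary and nominal columns pass
#' through untouched.  Standardization is a prerequisite of the mixed-data
#' generalized distance: it puts all quantitative variables on a common
#' scale so that no single variable dominates a summed dissimilarity.
#'
#' A constant numeric column is an error rather than being mapped to zero:
#' a silent 0/0 convention would fabricate distances.
#'
#' @param ft a [feature_table].
#' @return a `feature_table` of the same shape, with a per-column
#'   `"provenance"` attribute taking values `"raw"`, `"minmax"` or
#'   `"ordinal-rank"`.
#' @examples
#' ft <- feature_table(data.frame(x = c(2, 4, 6)), kinds = "numeric")
#' minmax_standardize(ft)$values   # 0, 0.5, 1
#' @export
minmax_standardize <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  values <- ft$values
  prov <- rep("raw", ncol(values))
  for (j in seq_len(ncol(values))) {
    kind <- ft$schema$kind[j]
    if (kind == "numeric") {
      rng <- range(values[, j])
      if (rng[1] == rng[2])
        stop("numeric column '", ft$schema$name[j],
             "' is constant: zero range, cannot min-max standardize")
      values[, j] <- (values[, j] - rng[1]) / (rng[2] - rng[1])
      prov[j] <- "minmax"
    } else if (kind == "ordinal") {
      values[, j] <- ordinal_standardize(values[, j], ft$schema$levels[j])
      prov[j] <- "ordinal-rank"
    }
  }
  out <- ft
  out$values <- values
  # rank-scaled ordinals become plain [0,1] quantities for the distance layer
  out$schema$kind[ft$schema$kind == "ordinal"] <- "numeric"
  attr(out, "provenance") <- stats::setNames(prov, ft$schema$name)
  out
}

#' Rank-scale ordinal scores onto \[0, 1\]
#'
#' Maps a rank `r` in `1..M` to `(r - 1) / (M - 1)`, so the lowest rank
#' becomes 0 and the highest 1, with equal spacing in between.
#'
#' @param ranks integer ranks in `1..M`.
#' @param M number of ordinal levels, at least 2.
#' @return numeric vector in `[0, 1]`.
#' @examples
#' ordinal_standardize(c(1, 3, 5), 5)   # 0, 0.5, 1
#' @export
ordinal_standardize <- function(ranks, M) {
  if (length(M) != 1L || is.na(M) || M < 2) stop("'M' must be a single value >= 2")
  if (any(ranks != round(ranks)) || any(ranks < 1) || any(ranks > M))
    stop("ranks must be integers in 1..", M)
  (ranks - 1) / (M - 1)
}
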