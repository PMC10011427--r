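#' Synthetic benchmark generators for cluster-number recovery
#'
#' Three families of artificial data with known group structure, used to
#' score how often a selection rule recovers the true number of clusters:
#'
#' * `gen_numerical()`: `n = 150` points split evenly over three bivariate
#'   standard-normal clusters centred at `(0, 0)`, `(0, 5)` and `(5, -3)`.
#' * `gen_categorical()`: `n = 100` objects on 10 binary variables in two
#'   equal groups; variable `j` in group `g` is Bernoulli with success
#'   probability `contrast[g]` (default 0.8 vs 0.2 on every variable).
#' * `gen_mixed()`: `n = 250` objects in five equal groups on two binary,
#'   one ordinal (5 levels) and one numeric variable.  The binary pair
#'   cycles through the four high/low signatures (the fifth group repeats
#'   the first signature and is separated by the full ordinal and numeric
#'   range); the ordinal variable puts mass `ordinal_peak` on the group's
#'   own level and spreads the rest uniformly; the numeric variable is
#'   normal with unit variance and means `numeric_gap * (g - 1)`.
#'
#' Every generator is a pure function of its `seed`.
#'
#' @param n number of objects (split evenly over the groups).
#' @param seed integer seed; required for reproducibility.
#' @return list with `table` (a [feature_table]) and `truth` (integer class
#'   labels).
#' @name synthetic_data
NULL

#' @rdname synthetic_data
#' @param centres 3 x 2 matrix of cluster centres.
#' @export
gen_numerical <- function(n = 150L, centres = rbind(c(0, 0), c(0, 5), c(5, -3)),
                          seed) {
  if (!missing(seed)) set.seed(seed)
  k <- nrow(centres)
  sizes <- rep(n %/% k, k); sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  truth <- rep(seq_len(k), sizes)
  X <- matrix(stats::rnorm(n * ncol(centres)), n) + centres[truth, ]
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  list(table = feature_table(X, kinds = rep("numeric", ncol(X))),
       truth = truth)
}

#' @rdname synthetic_data
#' @param p number of binary variables.
#' @param contrast success probabilities of the two groups.
#' @export
gen_categorical <- function(n = 100L, p = 10L, contrast = c(0.8, 0.2), seed) {
  if (!missing(seed)) set.seed(seed)
  sizes <- c(ceiling(n / 2), floor(n / 2))
  truth <- rep(1:2, sizes)
  X <- matrix(stats::rbinom(n * p, 1L, contrast[truth]), n, p)
  colnames(X) <- paste0("b", seq_len(p))
  list(table = feature_table(X, kinds = rep("binary", p)), truth = truth)
}

#' @rdname synthetic_data
#' @param binary_contrast high Bernoulli rate of the signature (the low rate
#'   is its complement).
#' @param ordinal_peak probability mass on the group's own ordinal level.
#' @param numeric_gap distance between consecutive group means of the
#'   numeric variable (unit variance).
#' @export
gen_mixed <- function(n = 250L, binary_contrast = 0.95, ordinal_peak = 0.6,
                      numeric_gap = 3, seed) {
  if (!missing(seed)) set.seed(seed)
  k <- 5L
  hi <- binary_contrast; lo <- 1 - binary_contrast
  p1 <- c(hi, lo, lo, hi, hi)     # 4-corner signature cycle
  p2 <- c(hi, hi, lo, lo, hi)     # group 5 repeats group 1's signature
  sizes <- rep(n %/% k, k); sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  truth <- rep(seq_len(k), sizes)
  nn <- length(truth)
  b1 <- stats::rbinom(nn, 1L, p1[truth])
  b2 <- stats::rbinom(nn, 1L, p2[truth])
  off <- (1 - ordinal_peak) / 4
  ord <- vapply(truth, function(g) {
    pr <- rep(off, 5); pr[g] <- ordinal_peak
    sample.int(5L, 1L, prob = pr)
  }, integer(1))
  num <- stats::rnorm(nn, numeric_gap * (truth - 1), 1)
  X <- cbind(b1 = b1, b2 = b2, ord = ord, num = num)
  list(table = feature_table(X,
                             kinds = c("binary", "binary", "ordinal", "numeric"),
                             levels = c(NA, NA, 5L, NA)),
       truth = truth)
}

family_policy <- function(family) {
  switch(family,
         numerical = list(gen = gen_numerical, standardize = TRUE,
                          method = "euclidean", true_k = 3L),
         categorical = list(gen = gen_categorical, standardize = FALSE,
                            method = "matching", true_k = 2L),
         mixed = list(gen = gen_mixed, standardize = TRUE,
                      method = "gower", true_k = 5L),
         stop("unknown family: ", family))
}

#' Repeated-trial scoring of cluster-number recovery
#'
#' Runs `trials` independent draws of one or more synthetic families,
#' standardizes each per the family's policy (min-max for numeric and
#' rank-scaling for ordinal variables; categorical data are used as drawn),
#' scans the deviation ratio index over `k_min..k_max` with the family's
#' distance (Euclidean / simple matching / Gower), applies a selection
#' rule, and tallies the selected cluster numbers into buckets relative to
#' the true `k`.  Trial `i` uses seed `base_seed + i`, so any single trial
#' is reproducible in isolation.
#'
#' @param families character subset of
#'   `c("categorical", "numerical", "mixed")`.
#' @param trials number of trials per family.
#' @param base_seed integer; trial `i` is seeded with `base_seed + i`.
#' @param rule selection rule passed to [select_k()].
#' @param k_min,k_max scan range of cluster numbers.
#' @param numerical_method distance for the numerical family
#'   (`"euclidean"` or `"canberra"`).
#' @return an object of class `"trial_table"`: data frame with one row per
#'   family and columns `family`, `true_k`, `trials`, the bucket counts
#'   `le_km2`, `km1`, `k`, `kp1`, `ge_kp2` (selected `k` at most `k - 2`,
#'   exactly `k - 1`, correct, `k + 1`, at least `k + 2`), and `none`
#'   (trials where no `k` in range had `DRI < 1`).  Buckets plus `none` sum
#'   to `trials`.  The per-trial selections are kept in attribute
#'   `"selections"`.
#' @examples
#' run_trials("numerical", trials = 3, base_seed = 7)
#' @export
run_trials <- function(families = c("categorical", "numerical", "mixed"),
                       trials = 50L, base_seed = 1L, rule = "dri",
                       k_min = 2L, k_max = 10L,
                       numerical_method = c("euclidean", "canberra")) {
  families <- match.arg(families, c("categorical", "numerical", "mixed"),
                        several.ok = TRUE)
  numerical_method <- match.arg(numerical_method)
  if (trials < 1L) stop("'trials' must be at least 1")
  rows <- list()
  selections <- list()
  for (family in families) {
    pol <- family_policy(family)
    method <- if (family == "numerical") numerical_method else pol$method
    sel <- integer(trials)
    for (i in seq_len(trials)) {
      draw <- pol$gen(seed = base_seed + i)
      tab <- if (pol$standardize) minmax_standardize(draw$table) else draw$table
      curve <- dri_curve(tab, method = method, k_min = k_min, k_max = k_max,
                         indices = "dri")
      sel[i] <- select_k(curve, rule)$k
    }
    kt <- pol$true_k
    rows[[family]] <- data.frame(
      family = family, true_k = kt, trials = trials,
      le_km2 = sum(sel <= kt - 2L, na.rm = TRUE),
      km1 = sum(sel == kt - 1L, na.rm = TRUE),
      k = sum(sel == kt, na.rm = TRUE),
      kp1 = sum(sel == kt + 1L, na.rm = TRUE),
      ge_kp2 = sum(sel >= kt + 2L, na.rm = TRUE),
      none = sum(is.na(sel)),
      stringsAsFactors = FALSE)
    selections[[family]] <- sel
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, selections = selections,
            class = c("trial_table", "data.frame"))
}

#' @export
print.trial_table <- function(x, ...) {
  cat("Cluster-number recovery over repeated synthetic trials\n")
  NextMethod()
  correct <- sum(x$k); total <- sum(x$trials)
  cat(sprintf("Overall correct: %d / %d (%.1f%%)\n",
              correct, total, 100 * correct / total))
  invisible(x)
}
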