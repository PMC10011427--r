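# Small random instances and brute-force reference implementations used as
# independent oracles across the test files.

random_numeric_table <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  feature_table(X, kinds = rep("numeric", p))
}

random_mixed_table <- function(n, seed) {
  set.seed(seed)
  X <- cbind(b = rbinom(n, 1, 0.5),
             c = sample(1:3, n, replace = TRUE),
             o = sample(1:4, n, replace = TRUE),
             x = runif(n))
  feature_table(X, kinds = c("binary", "nominal", "ordinal", "numeric"),
                levels = c(NA, NA, 4, NA))
}

# silhouette by explicit loops
brute_silhouette <- function(D, labels) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
}

# shadow values by explicit full sort
brute_msv <- function(md) {
  apply(md, 1, function(d) {
    d <- sort(d)
    if (d[2] == 0) 0 else (d[2] - d[1]) / d[2]
  })
}

# VRC from the raw pairwise-distance definitions (explicit pair loops)
brute_vrc <- function(D, labels, squared = TRUE) {
  n <- nrow(D); k <- max(labels)
  Dm <- if (squared) D^2 else D
  pair_mean <- function(idx) {
    tot <- 0; cnt <- 0
    for (i in idx) for (j in idx) if (i < j) { tot <- tot + Dm[i, j]; cnt <- cnt + 1 }
    if (cnt == 0) 0 else tot / cnt
  }
  dbar2 <- pair_mean(seq_len(n))
  sizes <- tabulate(labels, k)
  dg2 <- vapply(seq_len(k), function(g) pair_mean(which(labels == g)), 0)
  ak <- sum((sizes - 1) * (dbar2 - dg2)) / (n - k)
  # closed-form ratio equivalent to (BGSS/(k-1)) / (WGSS/(n-k))
  (dbar2 + ak * (n - k) / (k - 1)) / (dbar2 - ak)
}

# clustering accuracy by enumeration of all one-to-one mappings
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

brute_accuracy <- function(labels, truth) {
  tab <- table(labels, truth)
  if (nrow(tab) < ncol(tab)) tab <- t(tab)
  a <- nrow(tab); b <- ncol(tab)
  best <- 0
  for (rows in perms(seq_len(a))) {
    m <- sum(tab[cbind(rows[seq_len(b)], seq_len(b))])
    best <- max(best, m)
  }
  best / length(labels)
}
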