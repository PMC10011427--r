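env_fit <- local({
  env <- environment_scores()
  fit <- block_kmedoids(env, 3)
  md <- medoid_distances(env, fit$medoids)
  list(env = env, fit = fit, md = md)
})

test_that("within- and between-group deviations match the worked example", {
  with(env_fit, {
    w <- sdw(md, fit$labels)
    b <- sdb(md, fit$labels)
    expect_equal(w, 6.7, tolerance = 0.05 / 6.7)
    # published between-group total, carried here at the fixture's 2-dp input
    # precision
    expect_equal(b, 46.9, tolerance = 0.2 / 46.9)
    # the two deviations partition the full object-to-medoid mass
    expect_equal(w + b, sum(md))
    expect_equal(w, sum(apply(md, 1, min)))
  })
})

test_that("sdb at k = 2 is the column total minus sdw", {
  ft <- random_numeric_table(12, 3, seed = 21)
  fit <- block_kmedoids(ft, 2)
  md <- medoid_distances(ft, fit$medoids)
  expect_equal(sdb(md, fit$labels), sum(md) - sdw(md, fit$labels))
  expect_error(sdb(md[, 1, drop = FALSE], rep(1L, 12)), "k >= 2")
})

test_that("the deviation ratio reproduces the published value", {
  with(env_fit, {
    dr <- deviation_ratio(sdw(md, fit$labels), sdb(md, fit$labels), 25, 3)
    expect_equal(dr, 0.013, tolerance = 0.0005 / 0.013)
  })
  expect_equal(deviation_ratio(0, 10, 20, 4), 0)     # perfect separation
  expect_equal(deviation_ratio(5, 5, 9, 5), 1)       # (n-k) = (k-1) cancels
  expect_error(deviation_ratio(1, 0, 10, 3), "SDB is zero")
  expect_error(deviation_ratio(1, 1, 10, 1), "2..")
})

test_that("the DRI curve satisfies its definitional identities", {
  env <- env_fit$env
  curve <- dri_curve(env, k_max = 8)
  s <- curve$summary
  expect_equal(s$dri[-nrow(s)], s$dr[-nrow(s)] / s$dr[-1])
  expect_true(is.na(s$dri[nrow(s)]))
  # DRI(k) < 1 exactly when DR(k) < DR(k+1)
  expect_equal(s$dri[-nrow(s)] < 1, s$dr[-nrow(s)] < s$dr[-1])
  # DR decomposition: stored values recompute from the medoid distances
  for (i in seq_along(curve$fits)) {
    md <- curve$medoid_distances[[i]]
    lab <- curve$fits[[i]]$labels
    expect_equal(deviation_ratio(sdw(md, lab), sdb(md, lab), curve$n, s$k[i]),
                 s$dr[i], tolerance = 1e-12)
  }
})

test_that("selection rules read the curve as documented", {
  fake <- structure(list(summary = data.frame(
    k = 2:5, dr = c(1.3, 1.0, 0.6, 0.9), dri = c(1.3, 1.667, 0.667, NA),
    vrc = c(5, 9, 7, 2), silhouette = c(0.5, 0.7, 0.6, 0.2),
    msv = c(0.3, 0.4, 0.9, 0.5))), class = "dri_curve")
  expect_equal(select_k(fake, "dri")$k, 4L)
  expect_equal(select_k(fake, "vrc")$k, 3L)
  expect_equal(select_k(fake, "silhouette")$k, 3L)
  expect_equal(select_k(fake, "msv")$k, 4L)

  none <- structure(list(summary = data.frame(k = 2:4, dri = c(1.2, 1.1, NA))),
                    class = "dri_curve")
  sel <- select_k(none, "dri")
  expect_true(is.na(sel$k))
  expect_equal(sel$reason, "none in range")
})

test_that("the fixture's DRI selection is three clusters", {
  curve <- dri_curve(env_fit$env, k_min = 2, k_max = 10)
  expect_gte(curve$summary$dri[curve$summary$k == 2], 1)
  expect_lt(curve$summary$dri[curve$summary$k == 3], 1)
  expect_equal(select_k(curve, "dri")$k, 3L)
})

test_that("early stopping truncates the scan at the first DR increase", {
  env <- env_fit$env
  curve <- dri_curve(env, k_max = 10, early_stop = TRUE)
  s <- curve$summary
  expect_equal(max(s$k), 4L)   # DR(3) < DR(4) stops the scan at k = 4
  expect_equal(select_k(curve, "dri")$k, 3L)
})

test_that("VRC matches the brute-force pairwise computation", {
  for (seed in c(5, 6, 7)) {
    ft <- random_numeric_table(8, 2, seed = seed)
    D <- pairwise_distances(ft)
    set.seed(seed)
    labels <- sample(1:3, 8, replace = TRUE)
    labels <- as.integer(factor(labels))        # compact non-empty clusters
    if (max(labels) < 2) next
    expect_equal(vrc(D, labels), brute_vrc(D, labels))
    expect_equal(vrc(D, labels, squared = FALSE),
                 brute_vrc(D, labels, squared = FALSE))
  }
})

test_that("VRC flags degenerate geometry", {
  X <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  D <- pairwise_distances(feature_table(X, kinds = rep("numeric", 2)))
  expect_equal(vrc(D, c(1L, 1L, 2L, 2L)), Inf)
  expect_error(vrc(D, 1:4), "n = k")
  # two tight, far-apart clusters score much higher than a bad split
  Xg <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 10, 0.1), 5))
  Dg <- pairwise_distances(feature_table(Xg, kinds = rep("numeric", 2)))
  good <- vrc(Dg, rep(1:2, each = 5))
  bad <- vrc(Dg, rep(1:2, times = 5))
  expect_gt(good, 100 * max(bad, 1))
})

test_that("silhouette widths match explicit loops and stay in [-1, 1]", {
  for (seed in c(13, 14)) {
    ft <- random_numeric_table(15, 3, seed = seed)
    fit <- block_kmedoids(ft, 3)
    D <- pairwise_distances(ft)
    s <- silhouette_widths(D, fit$labels)
    expect_equal(s, brute_silhouette(D, fit$labels))
    expect_true(all(s >= -1 & s <= 1))
  }
})

test_that("silhouette agrees with the cluster package on a random instance", {
  skip_if_not_installed("cluster")
  ft <- random_numeric_table(20, 3, seed = 33)
  fit <- block_kmedoids(ft, 4)
  D <- pairwise_distances(ft)
  ours <- silhouette_widths(D, fit$labels)
  ref <- cluster::silhouette(fit$labels, dmatrix = D)[, "sil_width"]
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("well-separated tight clusters give mean silhouette near one", {
  set.seed(91)
  X <- rbind(matrix(rnorm(20, 0, 0.05), 10), matrix(rnorm(20, 8, 0.05), 10))
  D <- pairwise_distances(feature_table(X, kinds = rep("numeric", 2)))
  expect_gt(mean(silhouette_widths(D, rep(1:2, each = 10))), 0.95)
})

test_that("medoid shadow values follow the two-closest-medoid definition", {
  md <- structure(rbind(c(0, 2), c(1, 1), c(0.5, 2)), medoids = c(1L, 2L))
  v <- shadow_values(md)
  expect_equal(v, c(1, 0, 0.75))
  # coincides with two medoids at once -> 0 by convention
  expect_equal(shadow_values(rbind(c(0, 0, 3)))[1], 0)
  for (seed in c(25, 26)) {
    ft <- random_numeric_table(12, 2, seed = seed)
    fit <- block_kmedoids(ft, 3)
    md2 <- medoid_distances(ft, fit$medoids)
    v2 <- shadow_values(md2)
    expect_equal(v2, brute_msv(md2))
    expect_true(all(v2 >= 0 & v2 <= 1))
  }
})

test_that("clustering accuracy maximizes a one-to-one label matching", {
  expect_equal(clustering_accuracy(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(clustering_accuracy(c(2, 2, 1, 1), c(1, 1, 2, 2)), 1)
  # 2x2 contingency {{40,10},{5,45}}
  labels <- rep(c(1, 1, 2, 2), c(40, 10, 5, 45))
  truth <- rep(c(1, 2, 1, 2), c(40, 10, 5, 45))
  expect_equal(clustering_accuracy(labels, truth), 0.85)
  expect_error(clustering_accuracy(1:3, 1:4), "length")
})

test_that("accuracy is invariant to relabelling and matches enumeration", {
  set.seed(47)
  for (rep in 1:5) {
    n <- 30
    truth <- sample(1:3, n, replace = TRUE)
    labels <- sample(1:4, n, replace = TRUE)
    acc <- clustering_accuracy(labels, truth)
    expect_equal(acc, brute_accuracy(labels, truth))
    relab <- c(3L, 1L, 4L, 2L)[labels]
    expect_equal(clustering_accuracy(relab, truth), acc)
    expect_gte(acc, 1 / n)
    expect_lte(acc, 1)
  }
})
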