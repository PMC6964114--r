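test_that("silhouette widths match hand-computed values on five points", {
  coords <- cbind(c(0, 1, 2, 10, 11), 0)
  labels <- c("A", "A", "A", "B", "B")
  got <- silhouette_widths(coords, labels)
  want <- c(6 / 7, 17 / 19, 14 / 17, 8 / 9, 9 / 10)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("silhouette matches the full-distance-matrix oracle and cluster::silhouette", {
  blobs <- make_blobs(25, rbind(c(0, 0), c(1.5, 0.5)), sd = 0.6, seed = 8)
  got <- silhouette_widths(blobs$coords, blobs$labels)
  expect_equal(got, silhouette_oracle(blobs$coords, blobs$labels),
               tolerance = 1e-12)
  sil <- cluster::silhouette(as.integer(factor(blobs$labels)),
                             dist(blobs$coords))
  expect_equal(got, unname(sil[, "sil_width"]), tolerance = 1e-10)
})

test_that("silhouette limits: tight separation near 1, random labels near 0", {
  sep <- make_blobs(30, rbind(c(0, 0), c(100, 0)), sd = 0.1, seed = 12)
  expect_gt(mean(silhouette_widths(sep$coords, sep$labels)), 0.99)

  withr::with_seed(13, {
    blob <- matrix(rnorm(400), 200, 2)
    rand <- sample(rep(c("A", "B"), 100))
  })
  expect_lt(abs(mean(silhouette_widths(blob, rand))), 0.05)

  # rigid motion invariance
  rot <- matrix(c(0, 1, -1, 0), 2)
  expect_equal(silhouette_widths(blob %*% rot - 2, rand),
               silhouette_widths(blob, rand), tolerance = 1e-10)
})

test_that("ARI matches the contingency-table formula and mclust", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, 3), c("a", "a", "b", "b", "c")), 1)
  expect_equal(adjusted_rand_index(1:6, rep(1, 6)), 0)
  # contingency {A:{x:2,y:1}, B:{x:1,y:2}} -> (2 - 2.4)/(6 - 2.4)
  a <- c("A", "A", "A", "B", "B", "B")
  b <- c("x", "x", "y", "x", "y", "y")
  expect_equal(adjusted_rand_index(a, b), -1 / 9, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(b, a), adjusted_rand_index(a, b))

  withr::with_seed(3, {
    p1 <- sample(3, 40, replace = TRUE)
    p2 <- sample(4, 40, replace = TRUE)
  })
  expect_equal(adjusted_rand_index(p1, p2),
               mclust::adjustedRandIndex(p1, p2), tolerance = 1e-12)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("k-means recovers well-separated blobs and beats random partitions", {
  blobs <- make_blobs(20, rbind(c(0, 0), c(10, 0), c(0, 10)), sd = 0.3,
                      seed = 19)
  cl <- kmeans_cluster(blobs$coords, 3, seed = 1)
  expect_equal(adjusted_rand_index(cl, blobs$labels), 1)
  expect_identical(kmeans_cluster(blobs$coords, 1, seed = 1), rep(1L, 60))
  expect_identical(cl, kmeans_cluster(blobs$coords, 3, seed = 1))

  withr::with_seed(20, pts <- matrix(rnorm(100), 50, 2))
  fit_inertia <- function(labels) {
    sum(vapply(unique(labels), function(l) {
      sub <- pts[labels == l, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }
  got <- fit_inertia(kmeans_cluster(pts, 4, seed = 2))
  rand <- vapply(1:100, function(s) {
    withr::with_seed(300 + s, fit_inertia(sample(4, 50, replace = TRUE)))
  }, numeric(1))
  expect_true(all(got <= rand))
})

test_that("the subsampling protocols are deterministic and consistent", {
  blobs <- make_blobs(40, rbind(c(0, 0), c(4, 0)), sd = 0.5, seed = 29)
  batch <- rep(rep(c("b1", "b2"), each = 20), 2)
  ct <- blobs$labels

  p_full <- subsample_protocol(fraction = 1, repeats = 1, base_seed = 5)
  asw_full <- asw_protocol(blobs$coords, batch, ct, p_full)
  expect_equal(asw_full$asw_celltype,
               mean(silhouette_widths(blobs$coords, ct)))
  expect_equal(asw_full$asw_batch,
               mean(silhouette_widths(blobs$coords, batch)))

  p <- subsample_protocol(fraction = 0.8, repeats = 6, base_seed = 9)
  a1 <- asw_protocol(blobs$coords, batch, ct, p)
  a2 <- asw_protocol(blobs$coords, batch, ct, p)
  expect_identical(a1, a2)
  r1 <- ari_protocol(blobs$coords, batch, ct, p)
  r2 <- ari_protocol(blobs$coords, batch, ct, p)
  expect_identical(r1, r2)

  # repeat-to-repeat spread shrinks as the fraction approaches 1
  spread <- vapply(c(0.5, 0.95), function(f) {
    pr <- subsample_protocol(fraction = f, repeats = 10, base_seed = 11)
    var(asw_protocol(blobs$coords, batch, ct, pr)$per_repeat_celltype)
  }, numeric(1))
  expect_lt(spread[2], spread[1])
})

test_that("ARI protocol separates ideal integration from batch-aligned clusters", {
  # clusters perfectly aligned with cell types, orthogonal to batches
  blobs <- make_blobs(60, rbind(c(0, 0), c(30, 0)), sd = 0.5, seed = 37)
  batch <- rep(c("b1", "b2"), 60)  # interleaved within each type
  p <- subsample_protocol(fraction = 0.8, repeats = 5, base_seed = 3)
  res <- ari_protocol(blobs$coords, batch, blobs$labels, p)
  expect_equal(res$ari_celltype, 1)
  expect_lt(abs(res$ari_batch), 0.05)

  # swapping the roles of two fully-crossed label sets swaps the arms:
  # with all cells of common type and equal label counts, the batch arm
  # of one orientation equals the cell-type arm of the other
  res_xy <- ari_protocol(blobs$coords, batch, blobs$labels, p)
  res_yx <- ari_protocol(blobs$coords, blobs$labels, batch, p)
  expect_equal(res_xy$per_repeat_batch, res_yx$per_repeat_celltype)
})

test_that("the partition F1 follows the harmonic-mean formula", {
  expect_equal(f1_partition(0, 1), 1)
  expect_equal(f1_partition(1, 0.7), 0)
  expect_equal(f1_partition(1, 1), 2 * 0 * 1 / (0 + 1))
  expect_equal(f1_partition(0.4, 0.9), 0.72)
  expect_equal(normalize_unit(c(-1, 0, 1, -1.5)), c(0, 0.5, 1, 0))
})
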