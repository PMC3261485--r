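test_that("density surface conserves counts and flags the three modes", {
  bl <- blob_maps()
  surf <- build_density_surface(bl$maps, bins = 40)
  expect_equal(sum(surf$counts), 300L)
  expect_error(build_density_surface(bl$maps, bins = 0), "positive")

  # degenerate input: all mass in one bin
  one <- build_density_surface(as_maps(rep(1.1, 50), rep(0.5, 50)))
  expect_equal(sum(one$counts > 0), 1L)
  expect_equal(max(one$counts), 50L)

  # noise-free default phantom: at least three separated modes
  surf2 <- build_density_surface(fx_noisefree()$maps)
  expect_equal(sum(surf2$counts), sum(!fx_noisefree()$maps$values$flag))
  expect_gte(nrow(density_peaks(surf2)), 3L)
})

test_that("k-means recovers well-separated blobs", {
  bl <- blob_maps(n_per = 100, sd = 0.05, seed = 42)
  model <- kmeans_partition(bl$maps, k = 3, seed = 1)
  # each blob maps to exactly one cluster
  tab <- table(bl$truth, model$membership)
  expect_equal(sum(apply(tab, 1, max)), 300)
  # centroids near blob means (3 sd / sqrt(n) plus slack)
  perm <- apply(tab, 1, which.max)
  err <- sqrt(rowSums((model$centroids[perm, ] - bl$centers)^2))
  expect_true(all(err < 3 * 0.05 / sqrt(100) + 0.01))
})

test_that("k-means is deterministic given the seed", {
  bl <- blob_maps(seed = 7)
  a <- kmeans_partition(bl$maps, seed = 5)
  b <- kmeans_partition(bl$maps, seed = 5)
  expect_identical(a$membership, b$membership)
  expect_identical(a$centroids, b$centroids)
})

test_that("k = 1 yields the grand mean; too few distinct points error", {
  bl <- blob_maps(n_per = 20)
  m1 <- kmeans_partition(bl$maps, k = 1, seed = 1)
  expect_equal(drop(m1$centroids),
               c(md = mean(bl$maps$values$md), fa = mean(bl$maps$values$fa)),
               tolerance = 1e-12)
  expect_error(kmeans_partition(as_maps(c(1, 1, 2), c(1, 1, 1)), k = 3),
               "distinct")
})

test_that("k-means attains the exhaustive-partition global optimum", {
  # small instances where every assignment can be enumerated
  set.seed(31)
  cases <- list(
    cbind(c(rnorm(3, 1, .1), rnorm(3, 2, .1), rnorm(3, 3.2, .1)),
          c(rnorm(3, .7, .05), rnorm(3, .45, .05), rnorm(3, .1, .05))),
    cbind(runif(9, 0, 3), runif(9, 0, 1)),
    cbind(runif(10, 0, 2), runif(10, 0, 1))
  )
  for (X in cases) {
    model <- kmeans_partition(as_maps(X[, 1], X[, 2]), k = 3, seed = 2,
                              nstart = 25)
    expect_equal(model$inertia, exact_kmeans_ss(X, 3), tolerance = 1e-8)
  }
})

test_that("restriction keeps centroid cores and is monotone in threshold", {
  bl <- blob_maps(n_per = 50, sd = 0.08, seed = 9)
  model <- kmeans_partition(bl$maps, seed = 1)

  r1 <- restrict_clusters(model, 0.1)
  r2 <- restrict_clusters(model, 0.2)
  r4 <- restrict_clusters(model, 0.4)
  expect_true(all(r2$retained[r1$retained]))   # 0.1 subset of 0.2
  expect_true(all(r4$retained[r2$retained]))   # 0.2 subset of 0.4
  expect_error(restrict_clusters(model, 0), "positive")

  # a point exactly at a centroid is always retained
  ctr <- model$centroids
  aug <- as_maps(c(bl$maps$values$md, ctr[1, 1]),
                 c(bl$maps$values$fa, ctr[1, 2]))
  m2 <- restrict_clusters(kmeans_partition(aug, seed = 1), 1e-9)
  at_ctr <- which(abs(m2$values$md - ctr[1, 1]) < 1e-12 &
                  abs(m2$values$fa - ctr[1, 2]) < 1e-12)
  expect_true(any(m2$retained[at_ctr]))

  # a point halfway between two centroids is excluded at 0.2
  d <- sqrt(sum((ctr[1, ] - ctr[2, ])^2))
  mid <- (ctr[1, ] + ctr[2, ]) / 2
  aug2 <- as_maps(c(bl$maps$values$md, mid[1]), c(bl$maps$values$fa, mid[2]))
  m3 <- restrict_clusters(kmeans_partition(aug2, seed = 1), 0.2)
  expect_false(m3$retained[length(m3$retained)])
})

test_that("memberships partition the voxel set before restriction", {
  nf <- fx_noisefree()
  model <- kmeans_partition(nf$maps, seed = 1)
  expect_identical(length(model$membership), sum(!nf$maps$values$flag))
  expect_identical(sum(model$counts), length(model$membership))
  expect_true(all(model$membership %in% 1:3))
})

test_that("tissue assignment follows the MD/FA ordering rules", {
  model <- structure(list(
    centroids = cbind(md = c(0.97, 1.8, 3.06), fa = c(0.70, 0.45, 0.28)),
    counts = c(500L, 200L, 80L), k = 3L,
    tissue = rep(NA_character_, 3)), class = "cluster_model")
  out <- assign_tissues(model)
  expect_identical(out$tissue, c("WM", "GM", "CSF"))

  # permuting the cluster order permutes labels consistently
  perm <- c(3L, 1L, 2L)
  m2 <- model
  m2$centroids <- model$centroids[perm, ]
  m2$counts <- model$counts[perm]
  expect_identical(suppressWarnings(assign_tissues(m2))$tissue,
                   c("WM", "GM", "CSF")[perm])

  # count order violations warn but do not change the mapping
  m3 <- model
  m3$counts <- c(80L, 200L, 500L)
  expect_warning(expect_warning(out3 <- assign_tissues(m3), "WM cluster"),
                 "CSF cluster")
  expect_identical(out3$tissue, c("WM", "GM", "CSF"))

  # coincident centroids are degenerate
  m4 <- model
  m4$centroids[2, ] <- m4$centroids[1, ]
  expect_error(assign_tissues(m4), "degenerate")
})

test_that("back-mapping recovers ground-truth anatomy on clean data", {
  nf <- fx_noisefree()
  model <- kmeans_partition(nf$maps, seed = 1)
  model <- restrict_clusters(model, 0.2)
  model <- suppressWarnings(assign_tissues(model))
  labs <- backmap(model)

  # labels live exactly on the clustered ROI
  nz <- which(labs$labels != 0)
  lin <- (model$values$x - 1) + labs$shape[1] * (model$values$y - 1) +
    prod(labs$shape[1:2]) * (model$values$slice - 1) + 1
  expect_setequal(nz, lin)

  acc <- backmap_accuracy(labs, nf$phantom)
  expect_gte(acc$accuracy, 0.90)

  # near-zero threshold excludes (almost) everything
  tiny <- suppressWarnings(assign_tissues(restrict_clusters(model, 1e-12)))
  labs0 <- backmap(tiny)
  expect_true(all(labs0$labels[lin] == 4L | labs0$labels[lin] == 0L) ||
              mean(labs0$labels[lin] == 4L) > 0.99)
})

test_that("restricted tissue centroids recover the generator parameters", {
  # clean default-geometry phantom: the post-restriction per-tissue values
  # (the method's reported centroids) match the tissue models
  nf <- fx_noisefree()
  model <- suppressWarnings(assign_tissues(restrict_clusters(
    kmeans_partition(nf$maps, seed = 1), 0.2)))
  cc <- subject_centroids(model)
  for (r in seq_len(nrow(cc))) {
    tm <- nf$phantom$tissues[[cc$tissue[r]]]
    expect_lt(abs(cc$fa[r] - tm$fa), 0.05,
              label = paste(cc$tissue[r], "FA recovery"))
    expect_lt(abs(cc$md[r] - tm$md), 0.1,
              label = paste(cc$tissue[r], "MD recovery"))
  }
})
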