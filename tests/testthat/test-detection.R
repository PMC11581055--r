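test_that("region descriptors match a per-pixel accumulation oracle", {
  set.seed(41)
  spx <- matrix(sample(1:6, 15 * 15, replace = TRUE), 15, 15)
  maps <- replicate(4, matrix(rnorm(225), 15, 15), simplify = FALSE)
  got <- compute_descriptors(spx, maps[[1]], maps[[2]], maps[[3]], maps[[4]])
  for (l in 1:6) {
    sel <- spx == l
    row <- got[as.character(l), ]
    for (k in 1:4) {
      x <- maps[[k]][sel]
      expect_lt(abs(row[2 * k - 1] - sum(x) / length(x)), 1e-10)
      expect_lt(abs(row[2 * k] - sum((x - mean(x))^2) / length(x)), 1e-10)
    }
    expect_equal(unname(row[9]), sum(sel))
  }
  # constant region: mean c, variance 0
  spx1 <- matrix(1L, 4, 4); cmap <- matrix(0.37, 4, 4)
  d1 <- compute_descriptors(spx1, cmap, cmap, cmap, cmap)
  expect_equal(unname(d1[1, "intensity_mean"]), 0.37)
  expect_equal(unname(d1[1, "intensity_var"]), 0)
  expect_error(compute_descriptors(spx1, matrix(0, 2, 2), cmap, cmap, cmap),
               "shape")
})

test_that("DBSCAN separates Gaussian blobs and handles degenerate geometry", {
  set.seed(42)
  blob1 <- matrix(rnorm(200 * 3, 0, 0.5), ncol = 3)
  blob2 <- matrix(rnorm(200 * 3, 8, 0.5), ncol = 3)
  X <- rbind(blob1, blob2)
  truth <- rep(1:2, each = 200)
  asg <- dbscan_cluster(X, eps = NULL, min_pts = 10)
  expect_equal(max(asg$cluster), 2)
  expect_lte(mean(asg$cluster == -1), 0.05)
  core <- asg$cluster > 0
  expect_gte(abs(stats::cor(asg$cluster[core], truth[core])), 0.99)

  same <- matrix(rep(c(1, 2, 3), each = 30), ncol = 3)
  asg2 <- dbscan_cluster(same, eps = 0.1, min_pts = 5)
  expect_equal(unique(asg2$cluster), 1L)

  set.seed(43)
  sparse <- matrix(runif(60 * 3, 0, 100), ncol = 3)
  asg3 <- dbscan_cluster(sparse, eps = 1e-6, min_pts = 5)
  expect_true(all(asg3$cluster == -1L))
  expect_error(dbscan_cluster(sparse[1:3, ], min_pts = 10), "fewer")
})

test_that("cluster balancing equalizes the two largest clusters without altering features", {
  set.seed(44)
  X <- matrix(rnorm(1150 * 3), ncol = 3)
  asg <- structure(list(cluster = rep(c(1L, 2L, 3L), c(1000, 100, 50)),
                        is_core = rep(TRUE, 1150)),
                   class = "cluster_assignment")
  bal <- balance_training_set(X, asg, seed = 5)
  sizes <- table(asg$cluster[bal$keep])
  expect_equal(unname(sizes[["1"]]), 100)
  expect_equal(unname(sizes[["2"]]), 100)
  expect_equal(unname(sizes[["3"]]), 50)
  expect_identical(bal$samples, X[bal$keep, ])  # multiplicities only

  even <- structure(list(cluster = rep(c(1L, 2L), each = 80)),
                    class = "cluster_assignment")
  balE <- balance_training_set(matrix(0, 160, 2), even, seed = 1)
  expect_equal(length(balE$keep), 160)

  single <- structure(list(cluster = rep(1L, 50)), class = "cluster_assignment")
  expect_warning(balS <- balance_training_set(matrix(0, 50, 2), single),
                 "fewer than 2")
  expect_equal(length(balS$keep), 50)
})

test_that("the detector network has exactly 212 parameters and learns separable data", {
  set.seed(45)
  X <- rbind(matrix(rnorm(300 * 9, 0, 1), ncol = 9),
             matrix(rnorm(300 * 9, 6, 1), ncol = 9))
  y <- rep(c(0L, 1L), each = 300)
  model <- train_detector(X, y, epochs = 60, seed = 3)
  expect_equal(n_parameters(model), 212L)
  expect_equal(dim(model$par$W1), c(9L, 12L))
  expect_equal(dim(model$par$W2), c(12L, 6L))
  expect_equal(dim(model$par$W3), c(6L, 2L))
  expect_lte(utils::tail(model$loss_curve, 1), model$loss_curve[1])
  pred <- classify_superpixels(model, X)
  expect_gte(mean(pred == y), 0.99)

  # class centroids classify to their class
  expect_equal(classify_superpixels(model, t(colMeans(X[y == 0, ]))), 0L)
  expect_equal(classify_superpixels(model, t(colMeans(X[y == 1, ]))), 1L)
  expect_equal(classify_superpixels(model, X[0, , drop = FALSE]), integer(0))
  expect_error(train_detector(X, rep(1L, 600)), "both classes")
})

test_that("shuffled labels give chance-level accuracy", {
  set.seed(46)
  X <- rbind(matrix(rnorm(200 * 9, 0, 1), ncol = 9),
             matrix(rnorm(200 * 9, 6, 1), ncol = 9))
  y_shuf <- sample(rep(c(0L, 1L), each = 200))
  model <- train_detector(X, y_shuf, epochs = 30, seed = 3)
  set.seed(47)
  Xnew <- rbind(matrix(rnorm(200 * 9, 0, 1), ncol = 9),
                matrix(rnorm(200 * 9, 6, 1), ncol = 9))
  acc <- mean(classify_superpixels(model, Xnew) == rep(c(0L, 1L), each = 200))
  expect_gte(acc, 0.4); expect_lte(acc, 0.6)
})

test_that("training is bitwise deterministic given the seed and survives serialization", {
  set.seed(48)
  X <- rbind(matrix(rnorm(100 * 9), ncol = 9),
             matrix(rnorm(100 * 9, 4), ncol = 9))
  y <- rep(c(0L, 1L), each = 100)
  m1 <- train_detector(X, y, epochs = 20, seed = 7)
  m2 <- train_detector(X, y, epochs = 20, seed = 7)
  expect_identical(m1$par, m2$par)
  m3 <- train_detector(X, y, epochs = 20, seed = 8)
  expect_false(identical(m1$par, m3$par))

  path <- withr::local_tempfile(fileext = ".json")
  save_detector(m1, path)
  m1b <- load_detector(path)
  expect_equal(m1b$par, m1$par, tolerance = 1e-12)
  expect_identical(classify_superpixels(m1b, X), classify_superpixels(m1, X))
})
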