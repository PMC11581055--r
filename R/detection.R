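## Superpixel classification into cell / non-cell. Each watershed
## superpixel is summarized by a 9-dimensional descriptor (four
## mean/variance pairs over the region -- diffused intensity, detector
## response, motion-displacement magnitude, spatio-temporal gradient
## magnitude -- plus the region area). The training set is rebalanced by
## DBSCAN cluster-prototype undersampling, and a fully connected
## 9 x 12 x 6 x 2 network with ReLU activations and softmax cross-entropy
## classifies the descriptors.

#' Regional descriptors of watershed superpixels
#'
#' One 9-vector per superpixel: mean and variance (population, i.e.
#' mean of squared deviations) of the diffused intensity, of the detector
#' response, of the motion-displacement magnitude and of the
#' spatio-temporal intensity-gradient magnitude over the region's pixels,
#' plus the region area in px.
#'
#' @param superpixels Integer superpixel label matrix.
#' @param diffused,response,motion_mag,gradmag Matrices of the same shape.
#' @return Matrix with one row per superpixel (rownames = superpixel id)
#'   and 9 named columns.
#' @export
compute_descriptors <- function(superpixels, diffused, response, motion_mag,
                                gradmag) {
  maps <- list(intensity = diffused, response = response,
               motion = motion_mag, gradmag = gradmag)
  for (m in maps) if (!identical(dim(m), dim(superpixels))) stop("shape mismatch")
  ids <- setdiff(sort(unique(as.vector(superpixels))), 0L)
  f <- factor(superpixels[superpixels > 0], levels = ids)
  area <- as.numeric(table(f))
  out <- matrix(0, length(ids), 9,
                dimnames = list(ids, c("intensity_mean", "intensity_var",
                                       "response_mean", "response_var",
                                       "motion_mean", "motion_var",
                                       "gradmag_mean", "gradmag_var", "area")))
  sel <- superpixels > 0
  for (k in seq_along(maps)) {
    x <- maps[[k]][sel]
    mu <- as.numeric(tapply(x, f, mean))
    v <- as.numeric(tapply(x, f, function(z) mean((z - mean(z))^2)))
    out[, 2 * k - 1] <- mu; out[, 2 * k] <- v
  }
  out[, 9] <- area
  out
}

## ---- DBSCAN with Mahalanobis distances -------------------------------

mahalanobis_dist <- function(samples, ridge = 1e-8) {
  S <- stats::cov(samples)
  S <- S + diag(ridge * (mean(diag(S)) + 1), ncol(S))  # ridge-regularized
  W <- samples %*% t(solve(chol(S)))                   # whitening transform
  as.matrix(stats::dist(W))
}

#' Density-based clustering (DBSCAN) under the Mahalanobis metric
#'
#' Classic DBSCAN on the Mahalanobis distance matrix of the descriptor
#' samples: core points have at least \code{min_pts} samples (including
#' themselves) within \code{eps}; clusters are the transitive closure of
#' core-point reachability; non-core points adjacent to a cluster are
#' border points; the rest is noise. Expansion follows sample order, so
#' the assignment is deterministic.
#'
#' @param samples Numeric matrix, one descriptor per row.
#' @param eps Neighbourhood radius in Mahalanobis units; \code{NULL} picks
#'   the 15th percentile of pairwise distances on a subsample of at most
#'   500 rows.
#' @param min_pts Core-point density threshold.
#' @param eps_percentile Percentile used when \code{eps} is NULL.
#' @return A \code{cluster_assignment}: list with \code{cluster}
#'   (integer per sample, -1 = noise), \code{is_core}, \code{eps}.
#' @export
dbscan_cluster <- function(samples, eps = NULL, min_pts = 10,
                           eps_percentile = 0.15) {
  n <- nrow(samples)
  if (n < min_pts) stop("fewer samples than min_pts")
  D <- mahalanobis_dist(samples)
  if (is.null(eps)) {
    sub <- if (n > 500) seq(1, n, length.out = 500) else seq_len(n)
    sub <- unique(round(sub))
    dv <- D[sub, sub][upper.tri(matrix(0, length(sub), length(sub)))]
    eps <- max(stats::quantile(dv, eps_percentile), 1e-12)
  }
  neigh <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  is_core <- vapply(neigh, length, 0L) >= min_pts
  cluster <- rep(-1L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || cluster[i] != -1L) next
    cid <- cid + 1L
    queue <- i; cluster[i] <- cid
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      if (!is_core[p]) next
      for (q in neigh[[p]]) {
        if (cluster[q] == -1L) {
          cluster[q] <- cid
          if (is_core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  structure(list(cluster = cluster, is_core = is_core, eps = eps),
            class = "cluster_assignment")
}

#' Balance a training set by undersampling the largest DBSCAN cluster
#'
#' The most populous cluster is randomly undersampled (without
#' replacement, seeded) to the size of the second most populous; all other
#' clusters and noise points are kept unchanged, so the feature-space
#' structure is preserved while class-prototype imbalance is reduced.
#'
#' @param samples Descriptor matrix.
#' @param assignment A \code{cluster_assignment} over its rows.
#' @param seed Integer RNG seed for the undersampling draw.
#' @param min_cluster_frac Degeneracy guard: when the second-largest
#'   cluster holds less than this fraction of all samples, the clustering
#'   carries no usable prototype structure (one bulk cluster plus
#'   satellites) and undersampling the bulk to satellite size would
#'   annihilate the training set; balancing is skipped with a warning.
#' @return List with \code{keep} (row indices retained, in original order)
#'   and \code{samples}.
#' @export
balance_training_set <- function(samples, assignment, seed = 1L,
                                 min_cluster_frac = 0.05) {
  cl <- assignment$cluster
  sizes <- sort(table(cl[cl > 0]), decreasing = TRUE)
  if (length(sizes) < 2) {
    warning("fewer than 2 clusters: training set left unchanged")
    return(list(keep = seq_len(nrow(samples)), samples = samples))
  }
  if (sizes[2] < min_cluster_frac * nrow(samples)) {
    warning("second-largest cluster below ", min_cluster_frac,
            " of the samples: degenerate prototype structure, ",
            "training set left unchanged")
    return(list(keep = seq_len(nrow(samples)), samples = samples))
  }
  big <- as.integer(names(sizes)[1]); target <- as.integer(sizes[2])
  big_idx <- which(cl == big)
  old <- .Random.seed_get()
  set.seed(seed)
  kept_big <- sort(sample(big_idx, target))
  .Random.seed_restore(old)
  keep <- sort(c(setdiff(seq_len(nrow(samples)), big_idx), kept_big))
  list(keep = keep, samples = samples[keep, , drop = FALSE])
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

## ---- 9 x 12 x 6 x 2 fully connected network --------------------------

mlp_init <- function(seed) {
  old <- .Random.seed_get()
  set.seed(seed)
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  par <- list(W1 = he(9, 12), b1 = numeric(12),
              W2 = he(12, 6), b2 = numeric(6),
              W3 = he(6, 2), b3 = numeric(2))
  .Random.seed_restore(old)
  par
}

mlp_forward <- function(par, X) {
  Z1 <- sweep(X %*% par$W1, 2, par$b1, `+`); A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% par$W2, 2, par$b2, `+`); A2 <- pmax(Z2, 0)
  Z3 <- sweep(A2 %*% par$W3, 2, par$b3, `+`)
  m <- pmax(Z3[, 1], Z3[, 2])
  lse <- m + log(exp(Z3[, 1] - m) + exp(Z3[, 2] - m))
  P <- exp(Z3 - lse)  # softmax, numerically stable
  list(A1 = A1, A2 = A2, Z3 = Z3, P = P)
}

mlp_loss <- function(fw, y) -mean(log(pmax(fw$P[cbind(seq_along(y), y + 1L)], 1e-12)))

mlp_grad <- function(par, X, y, fw) {
  n <- nrow(X)
  dZ3 <- fw$P
  dZ3[cbind(seq_len(n), y + 1L)] <- dZ3[cbind(seq_len(n), y + 1L)] - 1
  dZ3 <- dZ3 / n
  dW3 <- t(fw$A2) %*% dZ3; db3 <- colSums(dZ3)
  dA2 <- dZ3 %*% t(par$W3); dZ2 <- dA2 * (fw$A2 > 0)
  dW2 <- t(fw$A1) %*% dZ2; db2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(par$W2); dZ1 <- dA1 * (fw$A1 > 0)
  dW1 <- t(X) %*% dZ1; db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

#' Train the 9x12x6x2 cell/non-cell detector network
#'
#' Fully connected network with ReLU activations and softmax
#' cross-entropy loss, trained by seeded stochastic gradient descent with
#' momentum on z-scored descriptors (standardization constants are stored
#' in the model and re-applied at prediction time). The model has exactly
#' 212 parameters (9*12 + 12*6 + 6*2 weights and 12 + 6 + 2 biases).
#'
#' @param samples Descriptor matrix (one row per superpixel).
#' @param labels Integer vector, 1 = cell, 0 = non-cell.
#' @param epochs,lr,batch,momentum SGD hyper-parameters.
#' @param seed RNG seed; identical seeds give bitwise-identical models.
#' @return A \code{detector_model}.
#' @export
train_detector <- function(samples, labels, epochs = 200, lr = 1e-2,
                           batch = 64, momentum = 0.9, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  mu <- colMeans(samples)
  sd <- apply(samples, 2, stats::sd); sd[sd == 0] <- 1
  X <- sweep(sweep(samples, 2, mu), 2, sd, `/`)
  par <- mlp_init(seed)
  vel <- lapply(par, function(p) p * 0)
  n <- nrow(X)
  loss_curve <- numeric(epochs)
  old <- .Random.seed_get()
  set.seed(seed + 1L)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1, n)]
      fw <- mlp_forward(par, X[idx, , drop = FALSE])
      g <- mlp_grad(par, X[idx, , drop = FALSE], labels[idx], fw)
      for (k in names(par)) {
        vel[[k]] <- momentum * vel[[k]] - lr * g[[k]]
        par[[k]] <- par[[k]] + vel[[k]]
      }
    }
    loss_curve[e] <- mlp_loss(mlp_forward(par, X), labels)
  }
  .Random.seed_restore(old)
  structure(list(par = par, feat_mean = mu, feat_sd = sd,
                 loss_curve = loss_curve, seed = seed, epochs = epochs),
            class = "detector_model")
}

#' Number of trainable parameters of a detector model
#' @param model A \code{detector_model}.
#' @export
n_parameters <- function(model) sum(vapply(model$par, length, 0L))

#' Classify superpixel descriptors into cell / non-cell
#'
#' @param model A \code{detector_model}.
#' @param descriptors Descriptor matrix (9 columns).
#' @return Integer vector per row: 1 = cell, 0 = non-cell (argmax of the
#'   two output units).
#' @export
classify_superpixels <- function(model, descriptors) {
  if (is.null(dim(descriptors)) || nrow(descriptors) == 0) return(integer(0))
  if (ncol(descriptors) != 9) stop("descriptors must have 9 columns")
  X <- sweep(sweep(descriptors, 2, model$feat_mean), 2, model$feat_sd, `/`)
  fw <- mlp_forward(model$par, X)
  as.integer(fw$P[, 2] > fw$P[, 1])
}

#' Save / load a detector model as portable JSON
#' @param model A \code{detector_model}.
#' @param path File path.
#' @export
save_detector <- function(model, path) {
  obj <- list(par = lapply(model$par, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
    else list(dim = NULL, data = as.numeric(p))
  }), feat_mean = model$feat_mean, feat_sd = model$feat_sd,
  seed = model$seed, epochs = model$epochs, loss_curve = model$loss_curve)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(NULL)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- lapply(obj$par, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(par = par, feat_mean = unlist(obj$feat_mean),
                 feat_sd = unlist(obj$feat_sd), seed = obj$seed,
                 epochs = obj$epochs, loss_curve = obj$loss_curve),
            class = "detector_model")
}
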