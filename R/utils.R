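## Small image-matrix helpers shared across modules. Images are plain R
## matrices indexed [row, col]; 3-frame spatio-temporal slabs are
## [row, col, tau] arrays with tau = 1..3 standing for t-1, t, t+1.

#' @useDynLib stiptrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Shift a matrix by (dr, dc) with replicate (Neumann) boundary handling.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Central finite differences (spacing 1), replicate boundaries.
deriv_row <- function(m) (shift_mat(m, -1, 0) - shift_mat(m, 1, 0)) / 2
deriv_col <- function(m) (shift_mat(m, 0, -1) - shift_mat(m, 0, 1)) / 2

gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with replicate boundaries, implemented by
# accumulating shifted copies (kernels here are short).
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  tmp <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) tmp <- tmp + k[i] * shift_mat(m, i - r - 1L, 0L)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(tmp, 0L, i - r - 1L)
  out
}

# Box-filter mean with replicate boundaries (odd window).
box_mean <- function(m, radius) {
  if (radius <= 0) return(m)
  n <- 2L * radius + 1L
  tmp <- matrix(0, nrow(m), ncol(m))
  for (d in -radius:radius) tmp <- tmp + shift_mat(m, d, 0L)
  out <- matrix(0, nrow(m), ncol(m))
  for (d in -radius:radius) out <- out + shift_mat(tmp, 0L, d)
  out / n^2
}

grad_mag <- function(m) sqrt(deriv_row(m)^2 + deriv_col(m)^2)

# Min-max rescale to [0, 1]; constant input maps to all zeros.
minmax01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

# Max (or min) over the 4- or 8-neighbourhood of every pixel,
# excluding the pixel itself; replicate boundary (border pixels compare
# against their in-frame neighbours only, which replicate handles because
# a replicated neighbour equals the pixel itself and f is max/min).
neighbor_reduce <- function(m, connectivity = 8L, fun = pmax) {
  offs4 <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  offs8 <- c(offs4, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  offs <- if (connectivity == 4L) offs4 else offs8
  out <- NULL
  for (o in offs) {
    s <- shift_mat(m, o[1], o[2])
    out <- if (is.null(out)) s else fun(out, s)
  }
  out
}

label_components <- function(mask, connectivity = 4L) {
  .cc_label(mask, as.integer(connectivity))
}

# Centroids of each positive label in a label matrix; returns a data.frame
# with label, row, col (1-based, fractional).
label_centroids <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(), row = numeric(), col = numeric()))
  rr <- (idx - 1) %% nrow(lab) + 1
  cc <- (idx - 1) %/% nrow(lab) + 1
  l <- lab[idx]
  data.frame(
    label = sort(unique(l)),
    row = as.numeric(tapply(rr, l, mean)),
    col = as.numeric(tapply(cc, l, mean))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
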