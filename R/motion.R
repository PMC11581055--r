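## Dense motion estimation between consecutive frames by combined
## local-global optical flow: the Lucas-Kanade structure-tensor data term,
## integrated over a rho-neighbourhood, embedded in the Horn-Schunck
## global smoothness energy with weight alpha. The Euler-Lagrange system
##   alpha * laplacian(u) = J11 u + J12 v + J13
##   alpha * laplacian(v) = J12 u + J22 v + J23
## is solved by Jacobi fixed-point iteration with a per-pixel 2x2 solve.

#' Combined local/global optical flow between two frames
#'
#' Coarse-to-fine estimation: the frames are downsampled by factors of 2,
#' the combined local-global energy is solved at the coarsest level, and
#' each finer level warps the current frame back by the upsampled estimate
#' and solves for the residual flow, so displacements beyond the
#' linearization range of a single level are recovered.
#'
#' @param prior Frame at time t (numeric matrix).
#' @param current Frame at time t+1, same shape.
#' @param alpha Global smoothness weight; default
#'   \code{(0.05 * range)^2} where range is the intensity range of the
#'   inputs.
#' @param rho Local integration scale for the structure tensor (px).
#' @param n_iters Maximum fixed-point iterations per level; iteration
#'   stops early when the mean update falls below 1e-4 px.
#' @param pyramid_levels Number of resolution levels (1 = single scale).
#' @return A \code{motion_field}: list with \code{u} (column/x
#'   displacement) and \code{v} (row/y displacement), both matrices
#'   mapping prior-frame pixels to the current frame.
#' @export
clgof <- function(prior, current, alpha = NULL, rho = 2, n_iters = 200,
                  pyramid_levels = 2L) {
  if (!identical(dim(prior), dim(current))) stop("shape mismatch")
  if (is.null(alpha)) {
    rng <- max(max(prior), max(current)) - min(min(prior), min(current))
    alpha <- max((0.05 * rng)^2, 1e-8)
  }
  if (alpha <= 0) stop("alpha must be positive")
  if (rho < 0) stop("rho must be >= 0")

  if (pyramid_levels > 1 && min(dim(prior)) >= 32) {
    pc <- downsample2(prior); cc <- downsample2(current)
    coarse <- clgof(pc, cc, alpha, rho, n_iters, pyramid_levels - 1L)
    u0 <- upsample2(coarse$u, dim(prior)) * 2
    v0 <- upsample2(coarse$v, dim(prior)) * 2
  } else {
    u0 <- matrix(0, nrow(prior), ncol(prior)); v0 <- u0
  }
  # residual problem: sample the current frame at the predicted positions
  cur_w <- bilinear_sample(current,
                           row_at = row(prior) + v0, col_at = col(prior) + u0)
  avg <- (prior + cur_w) / 2
  Ix <- deriv_col(avg); Iy <- deriv_row(avg); It <- cur_w - prior
  sm <- function(m) gauss_blur(m, rho)
  J11 <- sm(Ix * Ix); J12 <- sm(Ix * Iy); J22 <- sm(Iy * Iy)
  J13 <- sm(Ix * It); J23 <- sm(Iy * It)

  u <- matrix(0, nrow(prior), ncol(prior)); v <- u
  a4 <- 4 * alpha
  A11 <- a4 + J11; A22 <- a4 + J22
  det2 <- A11 * A22 - J12^2
  nbar <- function(m) (shift_mat(m, -1, 0) + shift_mat(m, 1, 0) +
                       shift_mat(m, 0, -1) + shift_mat(m, 0, 1)) / 4
  for (it in seq_len(n_iters)) {
    ub <- nbar(u); vb <- nbar(v)
    b1 <- a4 * ub - J13; b2 <- a4 * vb - J23
    un <- (b1 * A22 - J12 * b2) / det2
    vn <- (A11 * b2 - J12 * b1) / det2
    upd <- mean(abs(un - u) + abs(vn - v))
    u <- un; v <- vn
    if (upd < 1e-4) break
  }
  structure(list(u = u + u0, v = v + v0), class = "motion_field")
}

downsample2 <- function(m) {
  nr <- nrow(m) %/% 2; nc <- ncol(m) %/% 2
  (m[2 * seq_len(nr) - 1, 2 * seq_len(nc) - 1, drop = FALSE] +
   m[2 * seq_len(nr), 2 * seq_len(nc) - 1, drop = FALSE] +
   m[2 * seq_len(nr) - 1, 2 * seq_len(nc), drop = FALSE] +
   m[2 * seq_len(nr), 2 * seq_len(nc), drop = FALSE]) / 4
}

upsample2 <- function(m, target_dim) {
  ri <- pmin(pmax(ceiling(seq_len(target_dim[1]) / 2), 1), nrow(m))
  ci <- pmin(pmax(ceiling(seq_len(target_dim[2]) / 2), 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

bilinear_sample <- function(m, row_at, col_at) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(row_at, 1), nr); c <- pmin(pmax(col_at, 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  m[i00] * (1 - fr) * (1 - fc) + m[i00 + 1] * fr * (1 - fc) +
    m[i00 + nr] * (1 - fr) * fc + m[i00 + nr + 1] * fr * fc
}

#' Warp a label map along a motion field
#'
#' Transports each labelled prior-frame pixel to its displaced position in
#' the current frame by nearest-neighbour (rounded) displacement. Pixels
#' mapped outside the frame are dropped; on collision the larger label
#' wins (labels are processed in increasing order), which is deterministic.
#' Labels are never invented: the output label set is a subset of the
#' input's.
#'
#' @param prior_labels Integer label matrix (0 = background).
#' @param field \code{motion_field} of the same shape.
#' @return Warped integer label matrix.
#' @export
warp_labels <- function(prior_labels, field) {
  if (!identical(dim(prior_labels), dim(field$u))) stop("shape mismatch")
  nr <- nrow(prior_labels); nc <- ncol(prior_labels)
  out <- matrix(0L, nr, nc)
  idx <- which(prior_labels > 0)
  if (length(idx) == 0) return(out)
  rr <- (idx - 1) %% nr + 1; cc <- (idx - 1) %/% nr + 1
  tr <- rr + round(field$v[idx]); tc <- cc + round(field$u[idx])
  keep <- tr >= 1 & tr <= nr & tc >= 1 & tc <= nc
  lab <- prior_labels[idx][keep]
  ord <- order(lab)  # increasing label order: larger label wins collisions
  tgt <- (tc[keep][ord] - 1) * nr + tr[keep][ord]
  out[tgt] <- lab[ord]
  out
}

flow_magnitude <- function(field) sqrt(field$u^2 + field$v^2)

zero_motion_field <- function(dim) {
  z <- matrix(0, dim[1], dim[2])
  structure(list(u = z, v = z), class = "motion_field")
}
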