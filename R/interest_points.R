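## Spatio-temporal interest point detectors on a diffused 3-slab volume.
## Derivatives are central finite differences on the diffused maps (the
## diffusion itself provides the regularization at each scale); the
## detector strength S is evaluated on the central slab tau = t.

slab_first_derivs <- function(L) {
  mid <- L[, , 2]
  list(Lx = deriv_col(mid), Ly = deriv_row(mid), Lz = (L[, , 3] - L[, , 1]) / 2)
}

#' 3D structure-tensor (second-moment) corner response
#'
#' Extension of the Harris detector to space-time: the structure tensor M
#' is the Gaussian-smoothed (integration scale \code{sigma_i} spatially,
#' \code{tau_i} over the 3-frame window) outer product of the first
#' spatio-temporal derivatives, and the strength is
#' \eqn{S = \det(M) - \kappa\,\mathrm{trace}^3(M)}.
#'
#' @param L_slab Diffused [row, col, 3] volume.
#' @param sigma_i Spatial integration scale (px).
#' @param tau_i Temporal integration scale (frames) over the 3-slab window.
#' @param kappa Harris sensitivity constant (smaller than the classic 2D
#'   0.04 because the trace is cubed).
#' @return A \code{response_map}: list with \code{S} (matrix),
#'   \code{detector}, and the scales used.
#' @export
structure_tensor_response <- function(L_slab, sigma_i = 2, tau_i = 1,
                                      kappa = 0.005) {
  if (!all(is.finite(L_slab))) stop("non-finite input")
  if (sigma_i <= 0 || tau_i <= 0) stop("integration scales must be positive")
  d <- slab_first_derivs(L_slab)
  sm <- function(m) gauss_blur(m, sigma_i)
  m11 <- sm(d$Lx^2); m22 <- sm(d$Ly^2); m33 <- sm(d$Lz^2)
  m12 <- sm(d$Lx * d$Ly); m13 <- sm(d$Lx * d$Lz); m23 <- sm(d$Ly * d$Lz)
  det3 <- m11 * (m22 * m33 - m23^2) - m12 * (m12 * m33 - m23 * m13) +
    m13 * (m12 * m23 - m22 * m13)
  tr <- m11 + m22 + m33
  new_response(det3 - kappa * tr^3, "moments", sigma_i = sigma_i, tau_i = tau_i)
}

#' Spatio-temporal Hessian response |det H|
#'
#' 3x3 matrix of second spatio-temporal derivatives at the central slab;
#' strength is the magnitude of its determinant, which responds to blob-like
#' structure in space-time.
#'
#' @inheritParams structure_tensor_response
#' @export
hessian_st_response <- function(L_slab) {
  if (!all(is.finite(L_slab))) stop("non-finite input")
  mid <- L_slab[, , 2]
  Lxx <- deriv_col(deriv_col(mid)); Lyy <- deriv_row(deriv_row(mid))
  Lxy <- deriv_row(deriv_col(mid))
  Lzz <- L_slab[, , 3] - 2 * mid + L_slab[, , 1]
  Lxz <- deriv_col((L_slab[, , 3] - L_slab[, , 1]) / 2)
  Lyz <- deriv_row((L_slab[, , 3] - L_slab[, , 1]) / 2)
  det3 <- Lxx * (Lyy * Lzz - Lyz^2) - Lxy * (Lxy * Lzz - Lyz * Lxz) +
    Lxz * (Lxy * Lyz - Lyy * Lxz)
  new_response(abs(det3), "hessian_st")
}

#' Spatial Hessian of the temporal derivative
#'
#' The first-order temporal derivative Lt (central difference over the
#' 3-frame window) responds only to moving or appearing structure; the
#' strength is |det| of its 2x2 spatial Hessian, highlighting moving blobs
#' such as migrating cells.
#'
#' @inheritParams structure_tensor_response
#' @export
hessian_temporal_response <- function(L_slab) {
  if (length(dim(L_slab)) != 3 || dim(L_slab)[3] != 3)
    stop("slab must have 3 temporal slices")
  Lt <- (L_slab[, , 3] - L_slab[, , 1]) / 2
  Hxx <- deriv_col(deriv_col(Lt)); Hyy <- deriv_row(deriv_row(Lt))
  Hxy <- deriv_row(deriv_col(Lt))
  new_response(abs(Hxx * Hyy - Hxy^2), "hessian_temporal")
}

new_response <- function(S, detector, sigma_i = NA_real_, tau_i = NA_real_) {
  structure(list(S = S, detector = detector, sigma_i = sigma_i, tau_i = tau_i),
            class = "response_map")
}

detector_response <- function(L_slab, config = detector_config()) {
  switch(config$type,
    moments = structure_tensor_response(L_slab, config$sigma_i, config$tau_i,
                                        config$kappa),
    hessian_st = hessian_st_response(L_slab),
    hessian_temporal = hessian_temporal_response(L_slab),
    stop("unknown detector type: ", config$type))
}

detector_config <- function(type = "hessian_temporal", kappa = 0.005,
                            sigma_i = 2, tau_i = 1, min_strength_rel = 1e-3,
                            connectivity = 8L) {
  list(type = type, kappa = kappa, sigma_i = sigma_i, tau_i = tau_i,
       min_strength_rel = min_strength_rel, connectivity = connectivity)
}

#' Regional maxima of a response map
#'
#' Interest-point loci: pixels whose strength is >= all connected
#' neighbours and > \code{min_strength}. A flat plateau that is a regional
#' maximum contributes a single locus at its centroid, rounded to the
#' nearest plateau pixel.
#'
#' @param resp A \code{response_map} (or plain matrix).
#' @param min_strength Absolute strength threshold (> 0 excludes flat
#'   backgrounds).
#' @param connectivity Neighbourhood, 4 or 8.
#' @return An \code{interest_point_set}: data.frame-backed list with
#'   \code{points} (row, col) and \code{strengths}.
#' @export
regional_maxima <- function(resp, min_strength, connectivity = 8L) {
  S <- if (inherits(resp, "response_map")) resp$S else resp
  stopifnot(all(is.finite(S)))
  nb_max <- neighbor_reduce(S, connectivity, pmax)
  cand <- (S >= nb_max) & (S > min_strength)
  if (!any(cand))
    return(new_point_set(data.frame(row = integer(), col = integer(),
                                    strength = numeric())))
  # adjacent candidates necessarily share the same value, so candidate
  # components are plateaus; reduce each to its rounded centroid
  lab <- label_components(cand, connectivity)
  cen <- label_centroids(lab)
  rows <- integer(nrow(cen)); cols <- integer(nrow(cen)); str <- numeric(nrow(cen))
  for (i in seq_len(nrow(cen))) {
    idx <- which(lab == cen$label[i])
    rr <- (idx - 1) %% nrow(S) + 1; cc <- (idx - 1) %/% nrow(S) + 1
    j <- which.min((rr - cen$row[i])^2 + (cc - cen$col[i])^2)
    rows[i] <- rr[j]; cols[i] <- cc[j]; str[i] <- S[rows[i], cols[i]]
  }
  new_point_set(data.frame(row = rows, col = cols, strength = str))
}

new_point_set <- function(df) {
  structure(list(points = df[, c("row", "col")], strengths = df$strength,
                 n = nrow(df)), class = "interest_point_set")
}

# Relative-threshold wrapper used by the pipeline: min_strength is
# min_strength_rel * max(S) of the current frame, so thresholding
# survives frame-to-frame contrast changes.
detect_points <- function(resp, config = detector_config()) {
  S <- resp$S
  thr <- config$min_strength_rel * max(S)
  if (max(S) <= 0) thr <- Inf
  regional_maxima(resp, thr, config$connectivity)
}
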