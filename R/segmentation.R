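## Watershed superpixels on the selected-scale map. A Parzen (Gaussian
## kernel-sum) density of the interest-point loci is inverted and fused
## with the gradient magnitude of the diffused map into a relief that is
## low inside cells and high on boundaries; markers fuse the dilated
## interest-point maxima with the regional minima of that relief, and a
## marker-controlled watershed partitions the frame.

#' Parzen density estimate of an interest-point set
#'
#' Sum of isotropic Gaussian kernels centred at each point.
#'
#' @param points An \code{interest_point_set} (or data.frame with row, col).
#' @param shape c(rows, cols) of the output map.
#' @param bandwidth Kernel standard deviation (px).
#' @return A \code{density_map}: list with \code{d} (matrix >= 0) and
#'   \code{bandwidth}. Empty point set gives an all-zero map with a warning.
#' @export
parzen_density <- function(points, shape, bandwidth) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  pts <- if (inherits(points, "interest_point_set")) points$points else points
  d <- matrix(0, shape[1], shape[2])
  if (nrow(pts) == 0) {
    warning("empty point set: all-zero density")
    return(structure(list(d = d, bandwidth = bandwidth), class = "density_map"))
  }
  rseq <- seq_len(shape[1]); cseq <- seq_len(shape[2])
  for (i in seq_len(nrow(pts))) {
    kr <- exp(-(rseq - pts$row[i])^2 / (2 * bandwidth^2))
    kc <- exp(-(cseq - pts$col[i])^2 / (2 * bandwidth^2))
    d <- d + outer(kr, kc)
  }
  structure(list(d = d, bandwidth = bandwidth), class = "density_map")
}

#' Relief map for watershed segmentation
#'
#' Equal-weight sum of the min-max normalized gradient magnitude of the
#' selected-scale diffused map and the min-max normalized inverted Parzen
#' density: low inside cells (high density, flat intensity), high on
#' boundaries.
#'
#' @param diffused Selected-scale intensity map (matrix; if a 3-slab volume
#'   is given its central slab is used).
#' @param density A \code{density_map} of the same shape.
#' @return Numeric matrix in [0, 2].
#' @export
relief_map <- function(diffused, density) {
  if (length(dim(diffused)) == 3) diffused <- diffused[, , 2]
  d <- if (inherits(density, "density_map")) density$d else density
  if (!identical(dim(diffused), dim(d))) stop("shape mismatch")
  minmax01(grad_mag(diffused)) + minmax01(max(d) - d)
}

#' Fuse interest-point maxima and edge-map minima into watershed markers
#'
#' The edge map (gradient magnitude of the selected diffused map, min-max
#' normalized) is quantized with tolerance \code{tol} and its
#' regional-minima plateau components extracted: the near-flat background
#' together with the moat just outside each cell-boundary ridge forms one
#' large component, and each cell interior forms its own. The mask is
#' eroded by 1 px to cut thin bridges through ridge gaps. Interest-point
#' seeds are added as single pixels; seed pixels inside or 8-adjacent to
#' a minima component are absorbed by it (a wider seed straddling a
#' boundary ridge would otherwise claim both of its slopes and merge cell
#' interiors with the background). Each connected component of the union
#' is one marker id.
#'
#' @param feature_maxima An \code{interest_point_set}.
#' @param edge_map Min-max-normalized edge-strength matrix whose regional
#'   minima seed the cell-interior and background basins.
#' @param connectivity Component connectivity (4 or 8).
#' @param tol Flatness tolerance of the minima extraction, in units of the
#'   normalized edge map.
#' @return Integer marker matrix (0 = unmarked).
#' @export
fuse_markers <- function(feature_maxima, edge_map, connectivity = 4L,
                         tol = 0.02) {
  minima <- regional_minima_mask(edge_map, tol = tol)
  near_minima <- minima | neighbor_reduce(minima, 8L, `|`)
  seeds <- matrix(FALSE, nrow(edge_map), ncol(edge_map))
  pts <- feature_maxima$points
  if (nrow(pts) > 0)
    seeds[cbind(pts$row, pts$col)] <- TRUE
  label_components((seeds & !near_minima) | minima, connectivity)
}

# Plateau mask of regional minima: quantize with tolerance tol, keep
# pixels <= all 8-neighbours, erode by 1 px to sever 1-px-wide bridges.
# Components wiped out entirely by the erosion (the interiors of small
# cells) are restored un-eroded: being separate components of the raw
# mask, they cannot re-introduce a bridge.
regional_minima_mask <- function(m, tol = 0) {
  q <- if (tol > 0) floor(m / tol) else m
  nb_min <- neighbor_reduce(q, 8L, pmin)
  minima <- q <= nb_min
  if (tol > 0) {
    eroded <- minima & neighbor_reduce(minima, 8L, `&`)
    lab <- label_components(minima, 4L)
    surviving <- unique(lab[eroded])
    lost <- minima & !(lab %in% surviving)
    minima <- eroded | lost
  }
  minima
}

#' Marker-controlled watershed superpixels
#'
#' Priority-flood watershed of the relief from the given markers; every
#' pixel is assigned, boundaries fall on ridge lines. Superpixels smaller
#' than \code{min_size} pixels are merged into the neighbouring region with
#' the lowest shared ridge.
#'
#' @param relief Relief matrix.
#' @param markers Integer marker matrix (unique positive ids; 0 elsewhere).
#' @param connectivity Flood connectivity (4 or 8).
#' @param min_size Minimum superpixel area in px.
#' @return A \code{superpixel_map}: integer matrix, complete positive
#'   partition of the frame.
#' @export
watershed_superpixels <- function(relief, markers, connectivity = 4L,
                                  min_size = 5L) {
  if (!any(markers > 0)) stop("no markers")
  lab <- .ws_flood(relief, markers, as.integer(connectivity))
  merge_small_superpixels(lab, relief, min_size)
}

merge_small_superpixels <- function(lab, relief, min_size) {
  if (min_size <= 1) return(lab)
  repeat {
    sizes <- tabulate(lab)
    small <- which(sizes > 0 & sizes < min_size)
    if (length(small) == 0 || length(sizes[sizes > 0]) <= 1) break
    l <- small[1]
    idx <- which(lab == l)
    rr <- (idx - 1) %% nrow(lab) + 1; cc <- (idx - 1) %/% nrow(lab) + 1
    best <- NA_integer_; best_h <- Inf
    for (k in seq_along(idx)) {
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- rr[k] + o[1]; c2 <- cc[k] + o[2]
        if (r2 < 1 || r2 > nrow(lab) || c2 < 1 || c2 > ncol(lab)) next
        l2 <- lab[r2, c2]
        if (l2 == l) next
        h <- max(relief[rr[k], cc[k]], relief[r2, c2])  # ridge height
        if (h < best_h) { best_h <- h; best <- l2 }
      }
    }
    if (is.na(best)) break
    lab[idx] <- best
  }
  lab
}
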