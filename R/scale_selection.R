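## Automatic scale selection: noisy interest points decay rapidly over the
## first diffusion scales while cell features persist, so the per-frame
## feature-count curve drops steeply and then flattens. The selected scale
## is the elbow of that curve -- the interior scale where the discrete
## second difference of the normalized count curve is maximal (the end of
## the rapid noise-feature decay).

#' Interest-point counts across all scales of a scale space
#'
#' Runs the configured detector with identical settings at every scale and
#' counts the regional-maxima interest points.
#'
#' @param ss A \code{scale_space} from \code{\link{diffuse_triplet}}.
#' @param config Detector configuration (\code{detector_config()}).
#' @return A \code{scale_profile}: list with \code{counts},
#'   \code{normalized} (counts / counts at scale 0, falling back to the
#'   maximum when the first count is 0) and \code{second_diff} (interior
#'   discrete second differences of the normalized curve).
#' @export
feature_counts <- function(ss, config = detector_config()) {
  S <- length(ss$maps)
  counts <- integer(S)
  points <- vector("list", S)
  # identical detector settings at every scale: the strength threshold is
  # fixed once per frame from the undiffused (scale 0) response, so noisy
  # maxima whose strength collapses under diffusion drop out of the count
  thr <- NULL
  for (s in seq_len(S)) {
    resp <- detector_response(ss$maps[[s]], config)
    if (is.null(thr)) {
      thr <- config$min_strength_rel * max(resp$S)
      if (max(resp$S) <= 0) thr <- Inf
    }
    points[[s]] <- regional_maxima(resp, thr, config$connectivity)
    counts[s] <- points[[s]]$n
  }
  new_scale_profile(counts, points = points)
}

new_scale_profile <- function(counts, points = NULL) {
  S <- length(counts)
  denom <- if (counts[1] > 0) counts[1] else max(counts)
  normalized <- if (denom > 0) counts / denom else counts * 0
  second_diff <- if (S >= 3)
    normalized[1:(S - 2)] - 2 * normalized[2:(S - 1)] + normalized[3:S]
  else numeric(0)
  structure(list(counts = counts, normalized = normalized,
                 second_diff = second_diff, points = points),
            class = "scale_profile")
}

#' Select the per-frame scale from a feature-count profile
#'
#' Returns the smallest interior scale index (0-based, in 1..S-2) at which
#' the discrete second difference of the normalized count curve attains its
#' maximum; ties break toward the smaller scale to preserve detail. A
#' degenerate profile (all counts equal) returns scale 1 with
#' \code{attr(, "degenerate") = TRUE} and a warning.
#'
#' @param profile A \code{scale_profile}.
#' @return Integer 0-based scale index.
#' @export
select_scale <- function(profile) {
  S <- length(profile$counts)
  if (S < 3) stop("need at least 3 scales")
  if (length(unique(profile$counts)) == 1) {
    warning("degenerate scale profile: all counts equal")
    return(structure(1L, degenerate = TRUE))
  }
  d2 <- profile$second_diff
  # smallest interior scale within numerical tolerance of the maximum
  s <- which(d2 >= max(d2) - 1e-9)[1]
  structure(as.integer(s), degenerate = FALSE)
}

#' Retrieve the diffused map and interest points at the selected scale
#'
#' Pure lookup of the artifacts already computed by
#' \code{\link{diffuse_triplet}} and \code{\link{feature_counts}}; nothing
#' is recomputed.
#'
#' @param ss A \code{scale_space}.
#' @param profile The \code{scale_profile} whose points were computed on
#'   \code{ss}.
#' @param s_star 0-based selected scale index.
#' @return List with \code{map} (the central slab's full 3-slab volume),
#'   \code{points} (the \code{interest_point_set} at \code{s_star}).
#' @export
selected_artifacts <- function(ss, profile, s_star) {
  if (s_star < 0 || s_star >= length(ss$maps)) stop("scale index out of range")
  list(map = ss$maps[[s_star + 1L]], points = profile$points[[s_star + 1L]])
}
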