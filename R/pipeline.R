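## End-to-end pipelines: per-frame segmentation (scale space ->
## interest points -> scale selection -> watershed superpixels ->
## descriptor classification -> level-set refinement -> cluster
## splitting), detector training with DBSCAN balancing, and sequence
## tracking.

# All per-frame intermediates needed by segmentation and detection.
frame_features <- function(seq, t, config, prev_flow = NULL) {
  triplet <- frame_triplet(seq, t)
  ss <- diffuse_triplet(triplet, config$scale_space$n_scales,
                        config$scale_space$step,
                        config$scale_space$conductance_k,
                        config$scale_space$substeps)
  detcfg <- do.call(detector_config, config$detector[
    c("type", "kappa", "sigma_i", "tau_i", "min_strength_rel", "connectivity")])
  profile <- feature_counts(ss, detcfg)
  s_star <- select_scale(profile)
  art <- selected_artifacts(ss, profile, s_star)
  flow <- if (!is.null(prev_flow)) prev_flow
          else if (t > 0) clgof(seq$frames[[t]], seq$frames[[t + 1L]],
                                config$motion$alpha, config$motion$rho,
                                config$motion$n_iters,
                                config$motion$pyramid_levels)
          else zero_motion_field(dim(seq$frames[[1]]))
  resp <- detector_response(art$map, detcfg)
  bw <- config$segmentation$bandwidth_rel * config$detection$expected_radius
  dens <- suppressWarnings(parzen_density(art$points, dim(seq$frames[[1]]), bw))
  relief <- relief_map(art$map, dens)
  edge <- minmax01(grad_mag(art$map[, , 2]))
  markers <- fuse_markers(art$points, edge, config$segmentation$connectivity,
                          config$segmentation$marker_tol)
  spx <- watershed_superpixels(relief, markers,
                               config$segmentation$connectivity,
                               config$segmentation$min_superpixel_px)
  desc <- compute_descriptors(spx, art$map[, , 2], resp$S,
                              flow_magnitude(flow),
                              spatiotemporal_gradmag(art$map)[, , 2])
  list(t = t, scale = as.integer(s_star), map = art$map, points = art$points,
       flow = flow, relief = relief, superpixels = spx, descriptors = desc)
}

# Cell/non-cell labels for superpixels from a reference mask:
# a superpixel is a cell sample when >= 50% of its pixels are inside a
# reference cell region.
superpixel_labels <- function(superpixels, ref_mask) {
  ids <- setdiff(sort(unique(as.vector(superpixels))), 0L)
  fg <- ref_mask > 0
  vapply(ids, function(l) {
    sel <- superpixels == l
    as.integer(mean(fg[sel]) >= 0.5)
  }, 0L)
}

#' Train the cell detector on a sequence with reference masks
#'
#' Computes superpixel descriptors for every frame, labels them against
#' the reference masks (>= 50% overlap rule), balances class prototypes by
#' DBSCAN undersampling and trains the 9x12x6x2 network.
#'
#' @param seq A \code{sequence_handle}.
#' @param ref_masks List of reference label matrices.
#' @param config Pipeline configuration (\code{\link{stip_config}}).
#' @param frame_stride Use every \code{frame_stride}-th frame for training.
#' @return A \code{detector_model}.
#' @export
train_pipeline <- function(seq, ref_masks, config = stip_config(),
                           frame_stride = 1L) {
  descs <- list(); labels <- list()
  for (t in seq(0L, length(seq$frames) - 1L, by = frame_stride)) {
    ff <- frame_features(seq, t, config)
    descs[[length(descs) + 1L]] <- ff$descriptors
    labels[[length(labels) + 1L]] <- superpixel_labels(ff$superpixels,
                                                       ref_masks[[t + 1L]])
  }
  X <- do.call(rbind, descs); y <- unlist(labels)
  assign <- dbscan_cluster(X, eps = NULL, min_pts = config$detection$min_pts,
                           eps_percentile = config$detection$eps_percentile)
  bal <- balance_training_set(X, assign, seed = config$detection$seed)
  train_detector(X[bal$keep, , drop = FALSE], y[bal$keep],
                 epochs = config$detection$epochs, lr = config$detection$lr,
                 batch = config$detection$batch, seed = config$detection$seed)
}

# Refine the classified foreground of one frame into a final label map.
refine_frame <- function(intensity, cell_mask, config) {
  if (!any(cell_mask)) return(matrix(0L, nrow(cell_mask), ncol(cell_mask)))
  ref <- levelset_refine(intensity, cell_mask, config$refinement$n_iters,
                         config$refinement$nu, config$refinement$window)
  lab <- label_components(ref$mask, 4L)
  # drop specks below the minimum superpixel size
  sizes <- tabulate(lab)
  for (l in which(sizes > 0 & sizes < config$segmentation$min_superpixel_px))
    lab[lab == l] <- 0L
  flagged <- flag_clusters(lab, config$refinement$solidity_threshold)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nxt <- 0L
  for (l in setdiff(sort(unique(as.vector(lab))), 0L)) {
    sel <- lab == l
    if (l %in% flagged) {
      sub <- split_by_distance_watershed(sel, config$refinement$hmax)
      for (s in setdiff(sort(unique(as.vector(sub))), 0L)) {
        nxt <- nxt + 1L
        out[sub == s] <- nxt
      }
    } else {
      nxt <- nxt + 1L
      out[sel] <- nxt
    }
  }
  out
}

#' Segment a sequence into per-frame cell label maps
#'
#' @param seq A \code{sequence_handle}.
#' @param model A trained \code{detector_model}.
#' @param config Pipeline configuration.
#' @return List with \code{masks} (per-frame label matrices with
#'   frame-local labels), \code{scales} (selected scale per frame) and
#'   \code{flows} (motion fields between consecutive frames).
#' @export
segment_sequence <- function(seq, model, config = stip_config()) {
  T <- length(seq$frames)
  masks <- vector("list", T); scales <- integer(T)
  flows <- vector("list", max(T - 1, 0))
  for (t in seq_len(T) - 1L) {
    ff <- frame_features(seq, t, config)
    scales[t + 1L] <- ff$scale
    if (t > 0) flows[[t]] <- ff$flow
    pred <- classify_superpixels(model, ff$descriptors)
    ids <- as.integer(rownames(ff$descriptors))
    cell_mask <- matrix(FALSE, nrow(ff$superpixels), ncol(ff$superpixels))
    for (l in ids[pred == 1L]) cell_mask[ff$superpixels == l] <- TRUE
    masks[[t + 1L]] <- refine_frame(ff$map[, , 2], cell_mask, config)
  }
  list(masks = masks, scales = scales, flows = flows)
}

#' Track segmented cells across a sequence
#'
#' Motion-compensated maximum-likelihood bi-frame matching, chain
#' construction, mother/daughter splitting and lineage-graph assembly.
#'
#' @param seq A \code{sequence_handle} (used for motion estimation).
#' @param masks Per-frame label matrices (frame-local labels).
#' @param config Pipeline configuration.
#' @param flows Optional precomputed motion fields (from
#'   \code{\link{segment_sequence}}).
#' @return List with \code{masks} (relabelled by track id),
#'   \code{records} ("L B E P" data.frame), \code{tracks},
#'   \code{graph} (a \code{lineage_graph} over the relabelled masks).
#' @export
track_sequence <- function(seq, masks, config = stip_config(), flows = NULL) {
  T <- length(masks)
  matchings <- vector("list", max(T - 1, 0))
  for (t in seq_len(T - 1)) {
    field <- if (!is.null(flows) && !is.null(flows[[t]])) flows[[t]]
             else clgof(seq$frames[[t]], seq$frames[[t + 1L]],
                        config$motion$alpha, config$motion$rho,
                        config$motion$n_iters, config$motion$pyramid_levels)
    matchings[[t]] <- match_cells(
      masks[[t + 1L]], masks[[t]], field,
      reject_threshold = config$tracking$reject_threshold,
      expected_radius = config$detection$expected_radius *
        config$tracking$fallback_sigma_rel,
      max_daughters = config$tracking$max_daughters)
  }
  cells_per_frame <- lapply(masks, function(m)
    setdiff(sort(unique(as.vector(m))), 0L))
  bt <- build_tracks(matchings, cells_per_frame)
  tracks <- split_overlapping_tracks(bt$chains)
  out_masks <- relabel_masks_by_track(masks, tracks)
  records <- tracks_to_records(tracks)
  graph <- build_lineage_graph(lapply(tracks, function(tr) {
    tr$states$label <- tr$id  # states carry the track label in out_masks
    tr
  }), masks = out_masks)
  list(masks = out_masks, records = records, tracks = tracks, graph = graph,
       q_records = bt$q_records)
}
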