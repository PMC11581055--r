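## Graph-based cell tracking. Cells of consecutive frames are associated
## by maximum-likelihood matching: the prior frame's labels are warped
## along the estimated motion field and the likelihood that current cell i
## continues prior cell j is the intersection-over-union of the
## motion-compensated regions, with a reject option (low maximum
## likelihood signals cell appearance). Backward traversal of the linked
## associations yields chains; chains sharing a common ancestor prefix are
## factored into mother and daughter tracks, giving an acyclic oriented
## lineage graph whose edges encode migration and division.

#' Match likelihood between a current cell and a warped prior cell
#'
#' Intersection-over-union of the two pixel sets (0 when disjoint).
#'
#' @param current_pixels,warped_pixels Integer vectors of linear pixel
#'   indices.
#' @return Likelihood in [0, 1].
#' @export
match_likelihood <- function(current_pixels, warped_pixels) {
  inter <- length(intersect(current_pixels, warped_pixels))
  uni <- length(current_pixels) + length(warped_pixels) - inter
  if (uni == 0) return(0)
  inter / uni
}

#' Match the cells of the current frame to the warped prior frame
#'
#' Each current cell is assigned the prior cell maximizing the
#' motion-compensated IoU likelihood; a maximum below
#' \code{reject_threshold} yields "new" (appearance). When every IoU is 0
#' but a prior centroid lies within \code{2 * expected_radius}, a Gaussian
#' centroid-distance fallback (sigma = \code{expected_radius}) assigns the
#' nearest prior cell instead, tolerating low temporal resolution. A prior
#' cell claimed by more than \code{max_daughters} current cells keeps the
#' highest-likelihood claims; the rest become "new".
#'
#' @param current,prior Integer label matrices of consecutive frames.
#' @param field \code{motion_field} mapping prior to current.
#' @param reject_threshold Minimum IoU to accept a continuation.
#' @param expected_radius Typical cell radius in px (fallback scale).
#' @param max_daughters Division arity cap (2 = binary fission).
#' @return data.frame with columns \code{cur_label}, \code{prior_label}
#'   (NA = new cell) and \code{likelihood}.
#' @export
match_cells <- function(current, prior, field, reject_threshold = 0.1,
                        expected_radius = 6, max_daughters = 2L) {
  if (!identical(dim(current), dim(prior))) stop("shape mismatch")
  warped <- warp_labels(prior, field)
  cur_ids <- setdiff(sort(unique(as.vector(current))), 0L)
  pri_ids <- setdiff(sort(unique(as.vector(prior))), 0L)
  if (length(cur_ids) == 0)
    return(data.frame(cur_label = integer(0), prior_label = integer(0),
                      likelihood = numeric(0)))
  out <- data.frame(cur_label = cur_ids, prior_label = NA_integer_,
                    likelihood = 0)
  if (length(pri_ids) > 0) {
    both <- current > 0 & warped > 0
    tab <- if (any(both)) table(cur = current[both], pri = warped[both]) else NULL
    cur_area <- table(factor(current[current > 0], levels = cur_ids))
    war_area <- table(factor(warped[warped > 0], levels = pri_ids))
    cen_c <- label_centroids(current); cen_p <- label_centroids(prior)
    for (k in seq_along(cur_ids)) {
      ci <- cur_ids[k]
      lik <- numeric(length(pri_ids))
      if (!is.null(tab) && as.character(ci) %in% rownames(tab)) {
        for (m in seq_along(pri_ids)) {
          pj <- pri_ids[m]
          inter <- if (as.character(pj) %in% colnames(tab))
            tab[as.character(ci), as.character(pj)] else 0
          uni <- as.numeric(cur_area[as.character(ci)]) +
            as.numeric(war_area[as.character(pj)]) - inter
          lik[m] <- if (uni > 0) inter / uni else 0
        }
      }
      if (max(lik) >= reject_threshold) {
        j <- which.max(lik)
        out$prior_label[k] <- pri_ids[j]; out$likelihood[k] <- lik[j]
      } else if (all(lik == 0)) {
        # centroid-distance fallback for low temporal resolution
        rc <- cen_c[cen_c$label == ci, ]
        d <- sqrt((cen_p$row - rc$row)^2 + (cen_p$col - rc$col)^2)
        if (length(d) > 0 && min(d) <= 2 * expected_radius) {
          j <- which.min(d)
          out$prior_label[k] <- cen_p$label[j]
          out$likelihood[k] <- exp(-min(d)^2 / (2 * expected_radius^2))
        }
      }
    }
  }
  # cap division arity: keep the max_daughters highest-likelihood claims
  claimed <- out$prior_label[!is.na(out$prior_label)]
  for (pj in unique(claimed)) {
    rows <- which(!is.na(out$prior_label) & out$prior_label == pj)
    if (length(rows) > max_daughters) {
      drop <- rows[order(out$likelihood[rows], decreasing = TRUE)][-seq_len(max_daughters)]
      out$prior_label[drop] <- NA_integer_
      out$likelihood[drop] <- 0
    }
  }
  out
}

state_key <- function(t, label) paste0(t, ":", label)

#' Build cell track chains from per-frame matchings
#'
#' \code{matchings[[t]]} (t = 1..T-1) links the cells of frame t to frame
#' t-1 (0-based frames). Chains are formed by reverse-chronological
#' traversal of the linked associations from every chain end back to its
#' appearance; chains that pass through a division share their ancestor
#' states, i.e. temporarily overlap, until
#' \code{\link{split_overlapping_tracks}} factors them.
#'
#' @param matchings List of \code{\link{match_cells}} data.frames.
#' @param cells_per_frame List (length T) of integer label vectors present
#'   in each frame.
#' @return List with \code{chains} (each a data.frame t, label, oldest
#'   first) and \code{q_records} (one record per cell state: t, xi_m, t_p,
#'   xi_n with NA xi_n at appearances).
#' @export
build_tracks <- function(matchings, cells_per_frame) {
  T <- length(cells_per_frame)
  parent <- new.env(parent = emptyenv())
  claimed <- character(0)
  for (t in seq_len(T - 1)) {           # frame t (0-based) matched to t-1
    m <- matchings[[t]]
    if (any(duplicated(m$cur_label))) stop("inconsistent matching: duplicate current label")
    for (i in seq_len(nrow(m))) {
      if (!is.na(m$prior_label[i])) {
        assign(state_key(t, m$cur_label[i]),
               c(t - 1L, m$prior_label[i]), envir = parent)
        claimed <- c(claimed, state_key(t - 1L, m$prior_label[i]))
      }
    }
  }
  # ends: states never claimed as a prior by the next frame
  ends <- list()
  for (t in seq_len(T) - 1L) {
    for (l in cells_per_frame[[t + 1L]]) {
      if (t == T - 1L || !(state_key(t, l) %in% claimed))
        ends[[length(ends) + 1L]] <- c(t, l)
    }
  }
  chains <- list(); q_seen <- character(0); q <- list()
  for (e in ends) {
    t <- e[1]; l <- e[2]
    ts <- integer(0); ls <- integer(0)
    repeat {
      ts <- c(t, ts); ls <- c(l, ls)
      k <- state_key(t, l)
      if (!exists(k, envir = parent)) {
        if (!(k %in% q_seen)) {
          q[[length(q) + 1L]] <- data.frame(t = t, xi_m = l, t_p = t - 1L,
                                            xi_n = NA_integer_)
          q_seen <- c(q_seen, k)
        }
        break
      }
      p <- get(k, envir = parent)
      if (!(k %in% q_seen)) {
        q[[length(q) + 1L]] <- data.frame(t = t, xi_m = l, t_p = p[1],
                                          xi_n = p[2])
        q_seen <- c(q_seen, k)
      }
      t <- p[1]; l <- p[2]
    }
    chains[[length(chains) + 1L]] <- data.frame(t = ts, label = ls)
  }
  list(chains = chains, q_records = do.call(rbind, q))
}

#' Factor overlapping chains into mother and daughter tracks
#'
#' Chains sharing a common ancestor overlap on a contiguous prefix; the
#' shared prefix becomes the mother track and the distinct suffixes become
#' daughters (parent = mother id), applied recursively so nested divisions
#' yield the full lineage tree.
#'
#' @param chains As produced by \code{\link{build_tracks}}.
#' @return List of tracks: each a list with \code{id}, \code{states}
#'   (data.frame t, label) and \code{parent} (0 = none).
#' @export
split_overlapping_tracks <- function(chains) {
  tracks <- list()
  next_id <- 0L
  emit <- function(states, parent) {
    next_id <<- next_id + 1L
    tracks[[next_id]] <<- list(id = next_id, states = states, parent = parent)
    next_id
  }
  keys <- lapply(chains, function(ch) state_key(ch$t, ch$label))
  process <- function(idx, offset, parent) {
    if (length(idx) == 1L) {
      ch <- chains[[idx]]
      emit(ch[(offset + 1L):nrow(ch), , drop = FALSE], parent)
      return(invisible(NULL))
    }
    # longest common prefix beyond offset
    lens <- vapply(idx, function(i) length(keys[[i]]), 0L)
    p <- offset
    repeat {
      if (any(lens <= p)) break
      kk <- vapply(idx, function(i) keys[[i]][p + 1L], "")
      if (length(unique(kk)) > 1L) break
      p <- p + 1L
    }
    if (p == offset) stop("overlapping chains without a common prefix")
    mother <- emit(chains[[idx[1]]][(offset + 1L):p, , drop = FALSE], parent)
    firsts <- vapply(idx, function(i)
      if (length(keys[[i]]) > p) keys[[i]][p + 1L] else NA_character_, "")
    live <- idx[!is.na(firsts)]
    for (g in unique(firsts[!is.na(firsts)]))
      process(live[firsts[!is.na(firsts)] == g], p, mother)
    invisible(NULL)
  }
  firsts <- vapply(keys, `[`, "", 1L)
  for (g in unique(firsts)) {
    grp <- which(firsts == g)
    if (length(grp) == 1L) emit(chains[[grp]], 0L) else process(grp, 0L, 0L)
  }
  # sanity: each state in exactly one track
  all_states <- unlist(lapply(tracks, function(tr) state_key(tr$states$t, tr$states$label)))
  if (any(duplicated(all_states))) stop("overlap that is not a prefix: state in two tracks")
  tracks
}

#' Build the acyclic oriented lineage graph from tracks
#'
#' Vertices are cell states; migration edges connect consecutive states of
#' a track, division edges connect a mother's last state to each
#' daughter's first state. Edges always advance in time, so the graph is
#' acyclic; this is asserted.
#'
#' @param tracks From \code{\link{split_overlapping_tracks}}.
#' @param masks Optional list of per-frame label matrices (frame labels,
#'   used by the evaluation measures for node matching).
#' @return A \code{lineage_graph}: list with \code{states} (t, label,
#'   track), \code{edges} (t1, l1, t2, l2, type) and \code{masks}.
#' @export
build_lineage_graph <- function(tracks, masks = NULL) {
  states <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(t = tr$states$t, label = tr$states$label, track = tr$id)))
  edges <- list()
  by_id <- stats::setNames(tracks, vapply(tracks, function(tr) tr$id, 0L))
  for (tr in tracks) {
    st <- tr$states
    if (nrow(st) > 1)
      edges[[length(edges) + 1L]] <- data.frame(
        t1 = st$t[-nrow(st)], l1 = st$label[-nrow(st)],
        t2 = st$t[-1], l2 = st$label[-1], type = "migration")
    if (tr$parent > 0) {
      mom <- by_id[[as.character(tr$parent)]]
      last <- mom$states[nrow(mom$states), ]
      edges[[length(edges) + 1L]] <- data.frame(
        t1 = last$t, l1 = last$label, t2 = st$t[1], l2 = st$label[1],
        type = "division")
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(t1 = integer(), l1 = integer(), t2 = integer(),
               l2 = integer(), type = character())
  if (nrow(edges) > 0 && any(edges$t2 <= edges$t1))
    stop("cycle detected: edge not advancing in time")
  indeg <- table(state_key(edges$t2, edges$l2))
  if (length(indeg) > 0 && max(indeg) > 1)
    stop("vertex with in-degree > 1")
  structure(list(states = states, edges = edges, masks = masks,
                 tracks = tracks), class = "lineage_graph")
}

#' Convert tracks to "L B E P" track records
#' @param tracks From \code{\link{split_overlapping_tracks}}.
#' @return data.frame with columns label, begin, end, parent (track ids).
#' @export
tracks_to_records <- function(tracks) {
  do.call(rbind, lapply(tracks, function(tr) data.frame(
    label = tr$id, begin = min(tr$states$t), end = max(tr$states$t),
    parent = tr$parent)))
}

#' Relabel per-frame masks by track id
#'
#' Gives every cell state the label of its track, producing the mask
#' convention used by the "L B E P" track files (a track keeps one label
#' over its whole life; daughters get fresh labels).
#'
#' @param masks List of frame-label matrices.
#' @param tracks Tracks over those frame labels.
#' @return List of relabelled integer matrices.
#' @export
relabel_masks_by_track <- function(masks, tracks) {
  out <- lapply(masks, function(m) matrix(0L, nrow(m), ncol(m)))
  for (tr in tracks) {
    for (i in seq_len(nrow(tr$states))) {
      t <- tr$states$t[i]; l <- tr$states$label[i]
      out[[t + 1L]][masks[[t + 1L]] == l] <- tr$id
    }
  }
  out
}

#' Lineage graph of reference masks and a track file
#'
#' Builds the \code{lineage_graph} of a tracking result stored in the mask
#' + "L B E P" convention (as written by \code{\link{write_track_file}}).
#'
#' @param masks List of label matrices whose values are track labels.
#' @param records Track records data.frame (label, begin, end, parent).
#' @return A \code{lineage_graph}.
#' @export
graph_from_masks <- function(masks, records) {
  states <- list(); edges <- list()
  for (i in seq_len(nrow(records))) {
    L <- records$label[i]; B <- records$begin[i]; E <- records$end[i]
    P <- records$parent[i]
    fr <- B:E
    present <- fr[vapply(fr, function(t) any(masks[[t + 1L]] == L), TRUE)]
    if (length(present) == 0) next
    states[[i]] <- data.frame(t = present, label = L, track = L)
    if (length(present) > 1)
      edges[[length(edges) + 1L]] <- data.frame(
        t1 = present[-length(present)], l1 = L, t2 = present[-1], l2 = L,
        type = "migration")
    if (P > 0) {
      pend <- records$end[records$label == P]
      edges[[length(edges) + 1L]] <- data.frame(
        t1 = pend, l1 = P, t2 = present[1], l2 = L, type = "division")
    }
  }
  if (length(states) == 0)
    states <- list(data.frame(t = integer(), label = integer(),
                              track = integer()))
  structure(list(states = do.call(rbind, states),
                 edges = if (length(edges)) do.call(rbind, edges) else
                   data.frame(t1 = integer(), l1 = integer(), t2 = integer(),
                              l2 = integer(), type = character()),
                 masks = masks, tracks = NULL),
            class = "lineage_graph")
}
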