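## Evaluation measures. Pixel-overlap measures (Jaccard, Dice, SEG) and
## the acyclic-oriented-graph matching measures DET and TRA: the computed
## lineage graph is transformed into the reference graph by weighted node
## operations (split merged nodes, delete false positives, add missed
## nodes) and edge operations (delete redundant, add missing, fix
## semantics), and the normalized cost gives
##   DET = 1 - min(AOGMD, AOGMD0) / AOGMD0   (node operations only)
##   TRA = 1 - min(AOGM,  AOGM0)  / AOGM0    (node + edge operations)
## where the 0-subscripted costs build the reference from scratch.

#' Jaccard index of two pixel sets
#' @param a,b Integer vectors of pixel indices (or logical masks).
#' @return |a n b| / |a u b|; 1 when both are empty.
#' @export
jaccard <- function(a, b) {
  if (is.logical(a)) a <- which(a)
  if (is.logical(b)) b <- which(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Dice similarity coefficient of two pixel sets
#' @inheritParams jaccard
#' @return 2|a n b| / (|a| + |b|); 1 when both are empty.
#' @export
dsc <- function(a, b) {
  if (is.logical(a)) a <- which(a)
  if (is.logical(b)) b <- which(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' SEG measure over a sequence of label masks
#'
#' For every reference cell, the matching result region is the one whose
#' intersection with it exceeds half the reference area (at most one can
#' exist); the cell scores the Jaccard index with that region, or 0 when
#' no region qualifies. SEG is the mean over all reference cells.
#'
#' @param result,reference Lists of integer label matrices (same length).
#' @return SEG in [0, 1] (NA when the reference has no cells).
#' @export
seg_measure <- function(result, reference) {
  if (length(result) != length(reference)) stop("frame-count mismatch")
  scores <- numeric(0)
  for (t in seq_along(reference)) {
    ref <- reference[[t]]; res <- result[[t]]
    for (l in setdiff(sort(unique(as.vector(ref))), 0L)) {
      ridx <- which(ref == l)
      cand <- res[ridx]; cand <- cand[cand > 0]
      score <- 0
      if (length(cand) > 0) {
        tb <- sort(table(cand), decreasing = TRUE)
        if (as.integer(tb[1]) > 0.5 * length(ridx)) {
          m <- as.integer(names(tb)[1])
          score <- jaccard(ridx, which(res == m))
        }
      }
      scores <- c(scores, score)
    }
  }
  if (length(scores) == 0) return(NA_real_)
  mean(scores)
}

#' AOGM operation weights
#'
#' The published challenge weights: node split (NS) 5, false negative (FN)
#' 10, false positive (FP) 1, redundant-edge delete (ED) 1, missing-edge
#' add (EA) 1.5, edge-semantics change (EC) 1.
#' @export
aogm_weights <- function(ns = 5, fn = 10, fp = 1, ed = 1, ea = 1.5, ec = 1) {
  list(ns = ns, fn = fn, fp = fp, ed = ed, ea = ea, ec = ec)
}

# Node matching by the detection test: a result node detects a reference
# node when their overlap exceeds half the reference area. Returns, per
# reference state, the matching result label (NA if none), and per result
# state, the number of reference nodes it detects.
match_graph_nodes <- function(res_graph, ref_graph) {
  ref_states <- ref_graph$states
  det_label <- rep(NA_integer_, nrow(ref_states))
  res_states <- res_graph$states
  n_res <- if (is.null(res_states)) 0L else nrow(res_states)
  res_key <- if (n_res > 0) state_key(res_states$t, res_states$label) else character(0)
  n_detected <- stats::setNames(rep(0L, n_res), res_key)
  for (i in seq_len(nrow(ref_states))) {
    t <- ref_states$t[i]; l <- ref_states$label[i]
    ridx <- which(ref_graph$masks[[t + 1L]] == l)
    cand <- res_graph$masks[[t + 1L]][ridx]; cand <- cand[cand > 0]
    if (length(cand) == 0) next
    tb <- sort(table(cand), decreasing = TRUE)
    if (as.integer(tb[1]) > 0.5 * length(ridx)) {
      m <- as.integer(names(tb)[1])
      k <- state_key(t, m)
      if (k %in% res_key) {
        det_label[i] <- m
        n_detected[k] <- n_detected[k] + 1L
      }
    }
  }
  list(det_label = det_label, n_detected = n_detected)
}

aogm_costs <- function(res_graph, ref_graph, weights = aogm_weights()) {
  mm <- match_graph_nodes(res_graph, ref_graph)
  ref_states <- ref_graph$states; res_states <- res_graph$states
  fn <- sum(is.na(mm$det_label))
  fp <- sum(mm$n_detected == 0L)
  ns <- sum(pmax(mm$n_detected - 1L, 0L))

  # reference state -> detecting result state key
  det_of <- stats::setNames(
    ifelse(is.na(mm$det_label), NA_character_,
           state_key(ref_states$t, mm$det_label)),
    state_key(ref_states$t, ref_states$label))

  ref_e <- ref_graph$edges; res_e <- res_graph$edges
  res_edge_key <- if (nrow(res_e)) paste(state_key(res_e$t1, res_e$l1),
                                         state_key(res_e$t2, res_e$l2)) else character(0)
  ea <- 0L; ec <- 0L
  used <- rep(FALSE, length(res_edge_key))
  if (nrow(ref_e)) {
    for (i in seq_len(nrow(ref_e))) {
      a <- det_of[[state_key(ref_e$t1[i], ref_e$l1[i])]]
      b <- det_of[[state_key(ref_e$t2[i], ref_e$l2[i])]]
      if (is.na(a) || is.na(b)) { ea <- ea + 1L; next }
      j <- match(paste(a, b), res_edge_key)
      if (is.na(j)) { ea <- ea + 1L; next }
      used[j] <- TRUE
      if (res_e$type[j] != ref_e$type[i]) ec <- ec + 1L
    }
  }
  ed <- sum(!used)
  n_ref_nodes <- nrow(ref_states); n_ref_edges <- nrow(ref_e)
  list(fn = fn, fp = fp, ns = ns, ea = ea, ec = ec, ed = ed,
       aogmd = weights$fn * fn + weights$fp * fp + weights$ns * ns,
       aogmd0 = weights$fn * n_ref_nodes,
       aogm = weights$fn * fn + weights$fp * fp + weights$ns * ns +
         weights$ea * ea + weights$ec * ec + weights$ed * ed,
       aogm0 = weights$fn * n_ref_nodes + weights$ea * n_ref_edges)
}

#' DET measure (normalized node-matching cost)
#' @param res_graph,ref_graph \code{lineage_graph} objects carrying masks.
#' @param weights \code{\link{aogm_weights}}.
#' @return DET in [0, 1].
#' @export
det_measure <- function(res_graph, ref_graph, weights = aogm_weights()) {
  co <- aogm_costs(res_graph, ref_graph, weights)
  if (co$aogmd0 == 0) return(NA_real_)
  1 - min(co$aogmd, co$aogmd0) / co$aogmd0
}

#' TRA measure (normalized acyclic-oriented-graph matching cost)
#' @inheritParams det_measure
#' @return TRA in [0, 1].
#' @export
tra_measure <- function(res_graph, ref_graph, weights = aogm_weights()) {
  co <- aogm_costs(res_graph, ref_graph, weights)
  if (co$aogm0 == 0) return(NA_real_)
  1 - min(co$aogm, co$aogm0) / co$aogm0
}

#' Full evaluation report for a tracked sequence
#'
#' @param res_masks,ref_masks Lists of track-labelled masks.
#' @param res_records,ref_records "L B E P" track records.
#' @param weights \code{\link{aogm_weights}}.
#' @return List with SEG, DET, TRA, mean Jaccard and mean DSC of the
#'   binary foregrounds, and the AOGM cost decomposition.
#' @export
evaluate_tracking <- function(res_masks, ref_masks, res_records, ref_records,
                              weights = aogm_weights()) {
  res_g <- graph_from_masks(res_masks, res_records)
  ref_g <- graph_from_masks(ref_masks, ref_records)
  co <- aogm_costs(res_g, ref_g, weights)
  jac <- mean(mapply(function(a, b) jaccard(a > 0, b > 0), res_masks, ref_masks))
  dice <- mean(mapply(function(a, b) dsc(a > 0, b > 0), res_masks, ref_masks))
  list(SEG = seg_measure(res_masks, ref_masks),
       DET = if (co$aogmd0 > 0) 1 - min(co$aogmd, co$aogmd0) / co$aogmd0 else NA_real_,
       TRA = if (co$aogm0 > 0) 1 - min(co$aogm, co$aogm0) / co$aogm0 else NA_real_,
       jaccard = jac, dsc = dice, costs = co)
}
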