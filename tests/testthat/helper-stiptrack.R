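# Shared fixtures and independent oracles for the test suite.

# Wrap a list of frame matrices as a sequence handle.
mkseq <- function(frames) {
  structure(list(frames = frames, frame_ids = seq_along(frames) - 1L,
                 dim = dim(frames[[1]])),
            class = "sequence_handle")
}

seq_from_sim <- function(sim) mkseq(sim$frames)

# Deterministic random slab/matrix builders.
rand_slab <- function(nr = 8, nc = 8, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(nr * nc * 3), c(nr, nc, 3))
}

# 2D Gaussian bump centred at (r0, c0).
gauss_bump <- function(nr, nc, r0, c0, sigma = 2, amp = 1) {
  outer(seq_len(nr), seq_len(nc),
        function(r, c) amp * exp(-((r - r0)^2 + (c - c0)^2) / (2 * sigma^2)))
}

disk_mask <- function(nr, nc, r0, c0, radius) {
  outer(seq_len(nr), seq_len(nc),
        function(r, c) (r - r0)^2 + (c - c0)^2 <= radius^2)
}

# --- independent oracles ----------------------------------------------

# Brute-force 3x3 determinant by cofactor expansion, elementwise over
# matrices m[[i]][[j]].
det3_cofactor <- function(m) {
  m[[1]][[1]] * (m[[2]][[2]] * m[[3]][[3]] - m[[2]][[3]] * m[[3]][[2]]) -
  m[[1]][[2]] * (m[[2]][[1]] * m[[3]][[3]] - m[[2]][[3]] * m[[3]][[1]]) +
  m[[1]][[3]] * (m[[2]][[1]] * m[[3]][[2]] - m[[2]][[2]] * m[[3]][[1]])
}

# Central differences identical to the implementation's convention but
# written independently (index arithmetic, replicate boundary).
oracle_dcol <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    out[r, c] <- (m[r, min(c + 1, nc)] - m[r, max(c - 1, 1)]) / 2
  out
}
oracle_drow <- function(m) t(oracle_dcol(t(m)))

# Direct O(n^2) Gaussian smoothing with replicate boundary (separable,
# loop-based), matching gauss_blur's kernel definition.
oracle_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  tmp <- matrix(0, nr, nc); out <- matrix(0, nr, nc)
  for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0
    for (i in seq_along(k)) acc <- acc + k[i] * m[min(max(rr + i - r - 1, 1), nr), cc]
    tmp[rr, cc] <- acc
  }
  for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0
    for (i in seq_along(k)) acc <- acc + k[i] * tmp[rr, min(max(cc + i - r - 1, 1), nc)]
    out[rr, cc] <- acc
  }
  out
}

# Per-pixel foreground F1 between two binary masks.
pixel_f1 <- function(res, ref) {
  tp <- sum(res & ref)
  if (2 * tp + sum(res & !ref) + sum(!res & ref) == 0) return(1)
  2 * tp / (2 * tp + sum(res & !ref) + sum(!res & ref))
}

n_regions <- function(m) length(setdiff(unique(as.vector(m)), 0L))
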