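## Synthetic time-lapse generator. Emulates the data challenges the
## pipeline is built for: elliptical cells of varying size and
## orientation, Brownian per-frame displacement, scheduled mitosis
## (mother replaced by two half-area daughters displaced along the
## elongation axis), additive Gaussian plus signal-dependent noise, and
## exact per-frame ground-truth label masks plus an "L B E P" lineage
## table and dense ground-truth motion fields. Fully deterministic per
## seed.

#' Simulation configuration
#'
#' @param shape Frame shape c(rows, cols).
#' @param T Number of frames.
#' @param n_cells Initial cell count.
#' @param radius_mean,radius_sd Cell equivalent radius (px).
#' @param contrast Cell-minus-background intensity in [0,1] units.
#' @param background Background intensity level.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param noise_gain Signal-dependent noise gain
#'   (\code{gain * sqrt(I) * N(0,1)}).
#' @param motion_sd Brownian step standard deviation per frame (px, per
#'   axis).
#' @param divisions List of \code{c(cell_id, frame)} mitosis events
#'   (frames >= 1).
#' @param elongation Major/minor axis ratio of the cell ellipses.
#' @param seed RNG seed.
#' @export
sim_config <- function(shape = c(128L, 128L), T = 20L, n_cells = 8L,
                       radius_mean = 5, radius_sd = 1, contrast = 0.5,
                       background = 0.1, noise_sd = 0.03, noise_gain = 0.02,
                       motion_sd = 1.0, divisions = list(), elongation = 1.4,
                       seed = 1L) {
  cfg <- list(shape = as.integer(shape), T = as.integer(T),
              n_cells = as.integer(n_cells), radius_mean = radius_mean,
              radius_sd = radius_sd, contrast = contrast,
              background = background, noise_sd = noise_sd,
              noise_gain = noise_gain, motion_sd = motion_sd,
              divisions = divisions, elongation = elongation,
              seed = as.integer(seed))
  if (cfg$T < 1 || cfg$n_cells < 1) stop("invalid configuration")
  if (cfg$radius_mean >= min(cfg$shape) / 2) stop("cells larger than frame")
  for (d in divisions) if (d[2] < 1) stop("divisions must be scheduled at frames >= 1")
  cfg
}

# Excluded volume: cells are solid bodies, so after a Brownian step any
# interpenetrating pair is pushed apart symmetrically along the line of
# centres until their (circle-equivalent) boundaries are min_gap apart.
# Cells may still touch; they never overlap.
resolve_overlaps <- function(cells, sh, margin, min_gap = 2, passes = 5L) {
  n <- nrow(cells)
  if (n < 2) return(cells)
  r_eq <- sqrt(cells$a * cells$b)
  for (p in seq_len(passes)) {
    moved <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dr <- cells$row[j] - cells$row[i]; dc <- cells$col[j] - cells$col[i]
      d <- sqrt(dr^2 + dc^2)
      need <- r_eq[i] + r_eq[j] + min_gap
      if (d < need) {
        if (d < 1e-6) { dr <- 1; dc <- 0; d <- 1 }
        push <- (need - d) / 2
        cells$row[i] <- cells$row[i] - push * dr / d
        cells$col[i] <- cells$col[i] - push * dc / d
        cells$row[j] <- cells$row[j] + push * dr / d
        cells$col[j] <- cells$col[j] + push * dc / d
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  cells$row <- pmin(pmax(cells$row, margin), sh[1] - margin)
  cells$col <- pmin(pmax(cells$col, margin), sh[2] - margin)
  cells
}

render_cells <- function(cells, shape) {
  # label map: each pixel gets the cell with the smallest scaled ellipse
  # distance <= 1, so touching cells split along the equidistance line
  lab <- matrix(0L, shape[1], shape[2])
  best <- matrix(Inf, shape[1], shape[2])
  for (i in seq_len(nrow(cells))) {
    a <- cells$a[i]; b <- cells$b[i]; th <- cells$theta[i]
    rad <- ceiling(max(a, b)) + 1L
    rr <- max(1, floor(cells$row[i] - rad)):min(shape[1], ceiling(cells$row[i] + rad))
    cc <- max(1, floor(cells$col[i] - rad)):min(shape[2], ceiling(cells$col[i] + rad))
    if (length(rr) == 0 || length(cc) == 0) next
    dy <- matrix(rr - cells$row[i], length(rr), length(cc))
    dx <- matrix(cc - cells$col[i], length(rr), length(cc), byrow = TRUE)
    xr <- dx * cos(th) + dy * sin(th)
    yr <- -dx * sin(th) + dy * cos(th)
    dist2 <- (xr / a)^2 + (yr / b)^2
    sub_b <- best[rr, cc]; sub_l <- lab[rr, cc]
    take <- dist2 <= 1 & dist2 < sub_b
    sub_b[take] <- dist2[take]; sub_l[take] <- cells$id[i]
    best[rr, cc] <- sub_b; lab[rr, cc] <- sub_l
  }
  lab
}

#' Simulate a time-lapse sequence with ground truth
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{frames} (noisy intensity matrices),
#'   \code{masks} (integer label matrices, labels = track labels),
#'   \code{lineage} ("L B E P" data.frame), \code{motion} (list of T-1
#'   ground-truth \code{motion_field}s), \code{centers} (per-frame cell
#'   centre table) and \code{cfg}.
#' @export
simulate_sequence <- function(cfg) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  sh <- cfg$shape
  margin <- cfg$radius_mean * sqrt(cfg$elongation) + 2
  # initial non-overlapping placement by rejection sampling
  cells <- NULL
  for (i in seq_len(cfg$n_cells)) {
    r0 <- max(2, stats::rnorm(1, cfg$radius_mean, cfg$radius_sd))
    a <- r0 * sqrt(cfg$elongation); b <- r0 / sqrt(cfg$elongation)
    for (try in 1:500) {
      row <- stats::runif(1, margin, sh[1] - margin)
      col <- stats::runif(1, margin, sh[2] - margin)
      ok <- is.null(cells) ||
        all(sqrt((cells$row - row)^2 + (cells$col - col)^2) >
              (cells$a + a + 2))
      if (ok) break
    }
    if (!ok) stop("could not place cells: infeasible geometry")
    cells <- rbind(cells, data.frame(
      id = i, row = row, col = col, a = a, b = b,
      theta = stats::runif(1, 0, pi), parent = 0L, birth = 0L))
  }
  next_id <- cfg$n_cells
  div_by_frame <- list()
  for (d in cfg$divisions)
    div_by_frame[[as.character(d[2])]] <- c(div_by_frame[[as.character(d[2])]], d[1])

  masks <- vector("list", cfg$T)
  frames <- vector("list", cfg$T)
  motion <- vector("list", max(cfg$T - 1, 0))
  centers <- list()
  lineage <- data.frame(label = cells$id, begin = 0L, end = 0L,
                        parent = cells$parent)
  for (t in seq_len(cfg$T) - 1L) {
    if (t > 0) {
      # Brownian step, reflected at the margins
      cells$row <- cells$row + stats::rnorm(nrow(cells), 0, cfg$motion_sd)
      cells$col <- cells$col + stats::rnorm(nrow(cells), 0, cfg$motion_sd)
      cells$row <- pmin(pmax(cells$row, margin), sh[1] - margin)
      cells$col <- pmin(pmax(cells$col, margin), sh[2] - margin)
      cells <- resolve_overlaps(cells, sh, margin)
      # scheduled mitosis: mother replaced by two half-area daughters
      for (mid in div_by_frame[[as.character(t)]]) {
        i <- which(cells$id == mid)
        if (length(i) == 0) next
        m <- cells[i, ]
        a2 <- m$a / sqrt(2); b2 <- m$b / sqrt(2)
        # cleavage-furrow gap: daughters are born separated, not touching
        off <- a2 * 1.25
        dir <- c(sin(m$theta), cos(m$theta))  # (row, col) unit along major axis
        kids <- data.frame(
          id = next_id + 1:2,
          row = m$row + c(off, -off) * dir[1],
          col = m$col + c(off, -off) * dir[2],
          a = a2, b = b2, theta = m$theta, parent = m$id, birth = t)
        next_id <- next_id + 2L
        cells <- rbind(cells[-i, ], kids)
        lineage <- rbind(lineage,
                         data.frame(label = kids$id, begin = t, end = t,
                                    parent = m$id))
      }
    }
    masks[[t + 1L]] <- render_cells(cells, sh)
    lineage$end[lineage$label %in% cells$id] <- t
    clean <- cfg$background + cfg$contrast * (masks[[t + 1L]] > 0)
    clean <- gauss_blur(clean, 1)
    noisy <- clean + stats::rnorm(length(clean), 0, cfg$noise_sd) +
      cfg$noise_gain * sqrt(pmax(clean, 0)) * stats::rnorm(length(clean))
    frames[[t + 1L]] <- matrix(noisy, sh[1], sh[2])
    centers[[t + 1L]] <- data.frame(t = t, id = cells$id, row = cells$row,
                                    col = cells$col)
  }
  # dense ground-truth motion fields (prior -> current displacement)
  for (t in seq_len(cfg$T - 1)) {
    u <- matrix(0, sh[1], sh[2]); v <- matrix(0, sh[1], sh[2])
    prev <- centers[[t]]; nxt <- centers[[t + 1]]
    for (i in seq_len(nrow(prev))) {
      j <- which(nxt$id == prev$id[i])
      if (length(j) == 0) next
      sel <- masks[[t]] == prev$id[i]
      u[sel] <- nxt$col[j] - prev$col[i]
      v[sel] <- nxt$row[j] - prev$row[i]
    }
    motion[[t]] <- structure(list(u = u, v = v), class = "motion_field")
  }
  list(frames = frames, masks = masks,
       lineage = lineage[order(lineage$label), ],
       motion = motion, centers = do.call(rbind, centers), cfg = cfg)
}

#' Default two-sequence benchmark fixture
#'
#' Two 128 x 128, 20-frame sequences with 8 initial cells and 2 scheduled
#' divisions each, moderate noise, distinct seeds -- sequence "01" for
#' training and "02" for testing. Optionally written to \code{dir} in the
#' Cell Tracking Challenge layout (\code{01/t000.tif},
#' \code{01_GT/TRA/man_track000.tif}, \code{01_GT/TRA/man_track.txt}, ...).
#'
#' @param dir Optional output directory.
#' @param noise_sd,noise_gain Noise level (set both 0 for the noise-free
#'   variant).
#' @param seeds Two RNG seeds.
#' @return List with simulations \code{s01} and \code{s02}.
#' @export
default_fixture <- function(dir = NULL, noise_sd = 0.03, noise_gain = 0.02,
                            seeds = c(101L, 202L)) {
  mk <- function(seed) simulate_sequence(sim_config(
    shape = c(128L, 128L), T = 20L, n_cells = 8L, noise_sd = noise_sd,
    noise_gain = noise_gain,
    divisions = list(c(1L, 8L), c(2L, 12L)), seed = seed))
  fx <- list(s01 = mk(seeds[1]), s02 = mk(seeds[2]))
  if (!is.null(dir)) {
    for (nm in c("01", "02")) {
      sim <- if (nm == "01") fx$s01 else fx$s02
      write_simulation(sim, dir, nm)
    }
  }
  fx
}

#' Wrap a simulation's frames as a sequence handle
#'
#' Convenience equivalent of writing the simulation to disk with
#' \code{\link{write_simulation}} and reading it back with
#' \code{\link{read_sequence}} (up to 16-bit quantization).
#' @param sim From \code{\link{simulate_sequence}}.
#' @export
as_sequence <- function(sim) {
  structure(list(frames = sim$frames, frame_ids = seq_along(sim$frames) - 1L,
                 dim = dim(sim$frames[[1]])), class = "sequence_handle")
}

#' Write a simulation in the Cell Tracking Challenge layout
#' @param sim From \code{\link{simulate_sequence}}.
#' @param dir Root directory.
#' @param name Sequence name ("01", "02").
#' @export
write_simulation <- function(sim, dir, name = "01") {
  seq_dir <- file.path(dir, name)
  tra_dir <- file.path(dir, paste0(name, "_GT"), "TRA")
  dir.create(seq_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(tra_dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(sim$frames)) {
    img <- pmin(pmax(sim$frames[[t]], 0), 1)
    tiff::writeTIFF(round(img * 65535) / 65535,
                    file.path(seq_dir, sprintf("t%03d.tif", t - 1L)),
                    bits.per.sample = 16)
  }
  write_label_masks(sim$masks, tra_dir, prefix = "man_track")
  write_track_file(sim$lineage, file.path(tra_dir, "man_track.txt"))
  invisible(NULL)
}

#' Contrast-to-noise ratio of a simulated sequence
#'
#' Mean over frames of (mean cell intensity - mean background) divided by
#' the background standard deviation.
#' @param sim From \code{\link{simulate_sequence}}.
#' @export
measure_cnr <- function(sim) {
  mean(mapply(function(f, m) {
    fg <- f[m > 0]; bg <- f[m == 0]
    (mean(fg) - mean(bg)) / stats::sd(bg)
  }, sim$frames, sim$masks))
}
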