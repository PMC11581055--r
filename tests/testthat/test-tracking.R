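zero_field <- function(d) stiptrack:::zero_motion_field(d)

test_that("match likelihood is motion-compensated IoU", {
  expect_equal(match_likelihood(1:10, 1:10), 1)
  expect_equal(match_likelihood(1:10, 11:20), 0)
  expect_equal(match_likelihood(1:10, 6:15), 5 / 15)
})

test_that("cell matching links, rejects, and encodes division", {
  m <- matrix(0L, 20, 20); m[3:6, 3:6] <- 1L; m[12:15, 12:15] <- 2L
  id <- match_cells(m, m, zero_field(c(20, 20)))
  expect_equal(id$prior_label, c(1L, 2L))
  expect_true(all(id$likelihood == 1))

  cur <- m; cur[17:19, 2:4] <- 3L   # extra disjoint cell -> appearance
  mm <- match_cells(cur, m, zero_field(c(20, 20)), expected_radius = 1)
  expect_true(is.na(mm$prior_label[mm$cur_label == 3]))

  # a prior cell overlapped by two daughters: both match it
  prior <- matrix(0L, 20, 20); prior[5:12, 8:11] <- 1L
  daughters <- matrix(0L, 20, 20)
  daughters[5:8, 8:11] <- 1L; daughters[10:13, 8:11] <- 2L
  dm <- match_cells(daughters, prior, zero_field(c(20, 20)))
  expect_equal(dm$prior_label, c(1L, 1L))
  # exhaustive likelihood table confirms the argmax
  for (k in 1:2) {
    cur_px <- which(daughters == k)
    lik <- match_likelihood(cur_px, which(prior == 1L))
    expect_equal(dm$likelihood[k], lik)
  }
  expect_error(match_cells(m, matrix(0L, 4, 4), zero_field(c(20, 20))), "shape")
})

test_that("division arity is capped at max_daughters", {
  prior <- matrix(0L, 30, 10); prior[2:28, 3:8] <- 1L
  cur <- matrix(0L, 30, 10)
  cur[2:9, 3:8] <- 1L; cur[11:19, 3:8] <- 2L; cur[21:28, 3:8] <- 3L
  mm <- match_cells(cur, prior, zero_field(c(30, 10)), expected_radius = 0.1)
  expect_equal(sum(!is.na(mm$prior_label)), 2)  # third claim becomes "new"
})

test_that("track construction follows the linked lists in reverse", {
  # two non-interacting cells over 5 frames
  match_id <- data.frame(cur_label = c(1L, 2L), prior_label = c(1L, 2L),
                         likelihood = 1)
  bt <- build_tracks(replicate(4, match_id, simplify = FALSE),
                     replicate(5, c(1L, 2L), simplify = FALSE))
  expect_length(bt$chains, 2)
  expect_true(all(vapply(bt$chains, nrow, 0L) == 5))
  expect_equal(nrow(bt$q_records), 10)   # one record per state
  expect_equal(sum(is.na(bt$q_records$xi_n)), 2)  # one appearance per cell

  # appearance at frame 3 of 5
  matches <- list(
    data.frame(cur_label = 1L, prior_label = 1L, likelihood = 1),
    data.frame(cur_label = 1L, prior_label = 1L, likelihood = 1),
    data.frame(cur_label = c(1L, 9L), prior_label = c(1L, NA), likelihood = c(1, 0)),
    data.frame(cur_label = c(1L, 9L), prior_label = c(1L, 9L), likelihood = 1))
  cells <- list(1L, 1L, 1L, c(1L, 9L), c(1L, 9L))
  bt2 <- build_tracks(matches, cells)
  lens <- sort(vapply(bt2$chains, nrow, 0L))
  expect_equal(lens, c(2L, 5L))
  first9 <- bt2$q_records[bt2$q_records$xi_m == 9L & bt2$q_records$t == 3, ]
  expect_true(is.na(first9$xi_n))
})

test_that("overlapping chains factor into mother and daughters; nested divisions recurse", {
  # one division at frame 3 of 6: chains share frames 0-2
  matches <- list(
    data.frame(cur_label = 1L, prior_label = 1L, likelihood = 1),
    data.frame(cur_label = 1L, prior_label = 1L, likelihood = 1),
    data.frame(cur_label = c(2L, 3L), prior_label = c(1L, 1L), likelihood = 0.5),
    data.frame(cur_label = c(2L, 3L), prior_label = c(2L, 3L), likelihood = 1),
    data.frame(cur_label = c(2L, 3L), prior_label = c(2L, 3L), likelihood = 1))
  cells <- list(1L, 1L, 1L, c(2L, 3L), c(2L, 3L), c(2L, 3L))
  bt <- build_tracks(matches, cells)
  expect_length(bt$chains, 2)
  expect_true(all(vapply(bt$chains, nrow, 0L) == 6))   # overlapping prefixes

  tracks <- split_overlapping_tracks(bt$chains)
  expect_length(tracks, 3)
  lens <- sort(vapply(tracks, function(tr) nrow(tr$states), 0L))
  expect_equal(lens, c(3L, 3L, 3L))
  parents <- vapply(tracks, function(tr) tr$parent, 0L)
  expect_equal(sum(parents == 0), 1)  # one mother
  expect_equal(sum(parents > 0), 2)   # two daughters

  # disjoint tracks pass through unchanged
  plain <- list(data.frame(t = 0:3, label = 1L), data.frame(t = 0:3, label = 2L))
  tr2 <- split_overlapping_tracks(plain)
  expect_length(tr2, 2)
  expect_true(all(vapply(tr2, function(tr) tr$parent, 0L) == 0))
})

test_that("a nested double division yields the full 7-track family tree", {
  # grandmother frames 0-1, divides; mothers frames 2-3, both divide;
  # four leaves frames 4-5 -> 4 chains of length 6
  key <- function(labs) lapply(seq_along(labs), function(i)
    data.frame(t = 0:5, label = c(1L, 1L, labs[[i]][1], labs[[i]][1],
                                  labs[[i]][2], labs[[i]][2])))
  chains <- key(list(c(2L, 4L), c(2L, 5L), c(3L, 6L), c(3L, 7L)))
  tracks <- split_overlapping_tracks(chains)
  expect_length(tracks, 7)
  parents <- vapply(tracks, function(tr) tr$parent, 0L)
  expect_equal(sum(parents == 0), 1)                   # grandmother
  gm <- tracks[[which(parents == 0)]]$id
  expect_equal(sum(parents == gm), 2)                  # two mothers
  mothers <- vapply(tracks, function(tr) tr$id, 0L)[parents == gm]
  expect_equal(sum(parents %in% mothers), 4)           # four leaves
})

test_that("the lineage graph is acyclic with migration and division edges", {
  tracks <- list(list(id = 1L, states = data.frame(t = 0:2, label = 1L),
                      parent = 0L))
  g <- build_lineage_graph(tracks)
  expect_equal(nrow(g$edges), 2)
  expect_true(all(g$edges$type == "migration"))

  tracks <- list(
    list(id = 1L, states = data.frame(t = 0:2, label = 1L), parent = 0L),
    list(id = 2L, states = data.frame(t = 3:4, label = 2L), parent = 1L),
    list(id = 3L, states = data.frame(t = 3:4, label = 3L), parent = 1L))
  g2 <- build_lineage_graph(tracks)
  div <- g2$edges[g2$edges$type == "division", ]
  expect_equal(nrow(div), 2)
  expect_true(all(div$t1 == 2 & div$l1 == 1))
  expect_true(all(g2$edges$t2 > g2$edges$t1))          # acyclic by time ordering
})

test_that("track records round-trip through the track file preserving topology", {
  sim <- simulate_sequence(sim_config(shape = c(96, 96), T = 10, n_cells = 5,
                                      divisions = list(c(1L, 4L)), seed = 55))
  seq <- seq_from_sim(sim)
  tr <- track_sequence(seq, sim$masks, flows = sim$motion)
  path <- withr::local_tempfile()
  write_track_file(tr$records, path)
  back <- read_track_file(path)
  expect_equal(back, tr$records[order(tr$records$label), ], ignore_attr = TRUE)

  # conservation: every segmented cell belongs to exactly one track
  n_states <- sum(vapply(tr$tracks, function(t) nrow(t$states), 0L))
  expect_equal(n_states, sum(vapply(sim$masks, n_regions, 0L)))
})

test_that("tracking ground-truth masks with ground-truth motion recovers the lineage", {
  sim <- simulate_sequence(sim_config(shape = c(96, 96), T = 10, n_cells = 4,
                                      divisions = list(c(2L, 5L)), seed = 56))
  seq <- seq_from_sim(sim)
  tr <- track_sequence(seq, sim$masks, flows = sim$motion)
  res_g <- tr$graph
  ref_g <- graph_from_masks(sim$masks, sim$lineage)
  expect_equal(nrow(res_g$states), nrow(ref_g$states))
  expect_equal(nrow(res_g$edges), nrow(ref_g$edges))
  expect_equal(sum(res_g$edges$type == "division"), 2)
  expect_equal(tra_measure(res_g, ref_g), 1)
})
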