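mask_from <- function(nr, nc, regions) {
  m <- matrix(0L, nr, nc)
  for (l in names(regions)) m[regions[[l]]] <- as.integer(l)
  m
}

test_that("Jaccard and Dice follow their closed forms and the DSC identity", {
  expect_equal(jaccard(1:10, 1:10), 1)
  expect_equal(jaccard(1:10, 11:20), 0)
  expect_equal(jaccard(1:10, 6:15), 1 / 3)
  expect_equal(dsc(1:10, 1:10), 1)
  expect_equal(dsc(1:10, 11:20), 0)
  expect_equal(dsc(1:10, 6:15), 0.5)
  expect_equal(jaccard(integer(0), integer(0)), 1)
  expect_equal(dsc(integer(0), integer(0)), 1)

  set.seed(61)
  for (i in 1:1000) {
    n <- sample(1:60, 1)
    a <- sample(1:80, n); b <- sample(1:80, sample(1:60, 1))
    J <- jaccard(a, b); D <- dsc(a, b)
    expect_equal(D, 2 * J / (1 + J), tolerance = 1e-12)
    expect_gte(D, J)
  }
})

test_that("SEG scores cells by matched Jaccard with the majority-overlap rule", {
  ref <- mask_from(10, 10, list(`1` = 1:10))
  expect_equal(seg_measure(list(ref), list(ref)), 1)

  # best overlap exactly half the reference: scored zero
  res_half <- mask_from(10, 10, list(`7` = 1:5))
  expect_equal(seg_measure(list(res_half), list(ref)), 0)

  # two reference cells, one matched perfectly (J = 1), one with overlap 6
  # of 10 and 14 extra pixels (J = 6/24): SEG is their mean
  ref2 <- mask_from(10, 10, list(`1` = 1:10, `2` = 21:30))
  res2 <- mask_from(10, 10, list(`5` = 1:10, `6` = c(21:26, 31:44)))
  expect_equal(seg_measure(list(res2), list(ref2)), mean(c(1, 6 / 24)))
  expect_error(seg_measure(list(ref), list(ref, ref)), "mismatch")
})

test_that("DET matches the hand-computed node-operation costs", {
  # 10 reference cells in one frame, disjoint 2x2 squares
  ref <- matrix(0L, 10, 40)
  regs <- list()
  for (i in 1:10) {
    rr <- 2:3; cc <- (4 * (i - 1) + 1):(4 * (i - 1) + 2)
    ref[rr, cc] <- i
  }
  rec <- data.frame(label = 1:10, begin = 0L, end = 0L, parent = 0L)
  ref_g <- graph_from_masks(list(ref), rec)

  expect_equal(det_measure(graph_from_masks(list(ref), rec), ref_g), 1)

  empty <- matrix(0L, 10, 40)
  g_empty <- graph_from_masks(list(empty), rec[0, ])
  expect_equal(det_measure(g_empty, ref_g), 0)   # AOGMD = AOGMD0

  miss1 <- ref; miss1[ref == 10L] <- 0L
  g_miss <- graph_from_masks(list(miss1), rec[1:9, ])
  expect_equal(det_measure(g_miss, ref_g), 1 - (10 * 1) / (10 * 10))  # = 0.9
})

test_that("TRA agrees with exhaustive operation enumeration on micro-cases", {
  # 2 cells x 3 frames, no events
  mk <- function(l1, l2) mask_from(8, 8, stats::setNames(list(1:4, 33:36), c(l1, l2)))
  ref_masks <- list(mk(1, 2), mk(1, 2), mk(1, 2))
  rec <- data.frame(label = 1:2, begin = 0L, end = 2L, parent = 0L)
  ref_g <- graph_from_masks(ref_masks, rec)
  expect_equal(tra_measure(ref_g, ref_g), 1)

  g_empty <- graph_from_masks(list(matrix(0L, 8, 8), matrix(0L, 8, 8),
                                   matrix(0L, 8, 8)), rec[0, ])
  expect_equal(tra_measure(g_empty, ref_g), 0)

  # perfect nodes, one missing migration edge: result splits track 1 into
  # two single-frame... construct: result track 1 exists frames 0-1, track 3
  # appears at frame 2 in track 1's place -> edge (1,t1->t2) replaced by
  # nothing between matched nodes: one EA operation.
  res_masks <- list(mk(1, 2), mk(1, 2), mk(3, 2))
  res_rec <- data.frame(label = c(1L, 2L, 3L), begin = c(0L, 0L, 2L),
                        end = c(1L, 2L, 2L), parent = c(0L, 0L, 0L))
  res_g <- graph_from_masks(res_masks, res_rec)
  # enumeration: nodes all detected (FN=FP=NS=0); ref edges: 1:(0-1),(1-2),
  # 2:(0-1),(1-2); result edges 1:(0-1), 2:(0-1),(1-2); missing: ref edge
  # (1, t1->t2): EA=1, no deletions, no semantics changes.
  # AOGM = 1.5; AOGM0 = 10*6 + 1.5*4 = 66
  expect_equal(tra_measure(res_g, ref_g), 1 - 1.5 / 66)

  # wrong semantics: result declares a division where the reference migrates
  res2 <- list(mk(1, 2), mk(1, 2), mk(3, 2))
  rec2 <- data.frame(label = c(1L, 2L, 3L), begin = c(0L, 0L, 2L),
                     end = c(1L, 2L, 2L), parent = c(0L, 0L, 1L))
  res2_g <- graph_from_masks(res2, rec2)
  # the division edge connects the same matched nodes as ref migration edge
  # (1,1)->(1,2): semantics wrong: EC=1. AOGM = 1; TRA = 1 - 1/66
  expect_equal(tra_measure(res2_g, ref_g), 1 - 1 / 66)
})

test_that("adding false positives never increases SEG, DET or TRA", {
  sim <- simulate_sequence(sim_config(shape = c(64, 64), T = 4, n_cells = 4,
                                      seed = 62))
  rec <- sim$lineage
  g_ref <- graph_from_masks(sim$masks, rec)
  base <- evaluate_tracking(sim$masks, sim$masks, rec, rec)
  noisy_masks <- lapply(sim$masks, function(m) {
    m2 <- m; m2[1:3, 1:3] <- max(m) + 50L; m2
  })
  rec_fp <- rbind(rec, data.frame(label = max(rec$label) + 50L, begin = 0L,
                                  end = 3L, parent = 0L))
  with_fp <- evaluate_tracking(noisy_masks, sim$masks, rec_fp, rec)
  expect_equal(base$SEG, 1); expect_equal(base$DET, 1); expect_equal(base$TRA, 1)
  expect_lte(with_fp$SEG, base$SEG)
  expect_lt(with_fp$DET, base$DET)
  expect_lt(with_fp$TRA, base$TRA)
})
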