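test_that("structure tensor response matches a brute-force cofactor oracle", {
  slab <- rand_slab(8, 8, seed = 11)
  sigma_i <- 1.5
  got <- structure_tensor_response(slab, sigma_i = sigma_i, tau_i = 1,
                                   kappa = 0.005)$S
  # oracle: form all six smoothed products explicitly, cofactor determinant
  Lx <- oracle_dcol(slab[, , 2]); Ly <- oracle_drow(slab[, , 2])
  Lz <- (slab[, , 3] - slab[, , 1]) / 2
  sm <- function(m) oracle_blur(m, sigma_i)
  M <- list(list(sm(Lx * Lx), sm(Lx * Ly), sm(Lx * Lz)),
            list(sm(Lx * Ly), sm(Ly * Ly), sm(Ly * Lz)),
            list(sm(Lx * Lz), sm(Ly * Lz), sm(Lz * Lz)))
  S_oracle <- det3_cofactor(M) -
    0.005 * (M[[1]][[1]] + M[[2]][[2]] + M[[3]][[3]])^3
  expect_lt(max(abs(got - S_oracle)), 1e-10)
})

test_that("spatio-temporal Hessian response matches oracles and closed forms", {
  slab <- rand_slab(8, 8, seed = 12)
  got <- hessian_st_response(slab)$S
  d2col <- function(m) oracle_dcol(oracle_dcol(m))
  d2row <- function(m) oracle_drow(oracle_drow(m))
  mid <- slab[, , 2]
  H <- list(list(d2col(mid), oracle_drow(oracle_dcol(mid)),
                 oracle_dcol((slab[, , 3] - slab[, , 1]) / 2)),
            list(oracle_drow(oracle_dcol(mid)), d2row(mid),
                 oracle_drow((slab[, , 3] - slab[, , 1]) / 2)),
            list(oracle_dcol((slab[, , 3] - slab[, , 1]) / 2),
                 oracle_drow((slab[, , 3] - slab[, , 1]) / 2),
                 slab[, , 3] - 2 * mid + slab[, , 1]))
  expect_lt(max(abs(got - abs(det3_cofactor(H)))), 1e-10)

  # separable quadratic a x^2 + b y^2 + c z^2 -> |det H| = |8abc|
  a <- 0.7; b <- -0.4; cc <- 0.9
  xs <- seq_len(16); z <- c(-1, 0, 1)
  quad <- array(0, c(16, 16, 3))
  for (k in 1:3) quad[, , k] <- outer(xs, xs, function(r, c) a * c^2 + b * r^2) +
    cc * z[k]^2
  S <- hessian_st_response(quad)$S
  expect_equal(max(abs(S[4:13, 4:13] - abs(8 * a * b * cc))), 0,
               tolerance = 1e-9)
})

test_that("temporal-derivative Hessian responds to moving structure only", {
  const <- array(0.3, c(8, 8, 3))
  expect_equal(hessian_temporal_response(const)$S, matrix(0, 8, 8))

  # frame t+1 equal to frame t-1: central temporal difference vanishes
  sym <- rand_slab(8, 8, seed = 13); sym[, , 3] <- sym[, , 1]
  expect_equal(hessian_temporal_response(sym)$S, matrix(0, 8, 8))

  # Lt equal to a Gaussian bump: |det Hessian| maximal at the bump centre
  bump <- gauss_bump(21, 21, 11, 11, sigma = 3)
  slab <- array(0, c(21, 21, 3)); slab[, , 3] <- 2 * bump  # Lt = bump
  S <- hessian_temporal_response(slab)$S
  expect_equal(as.vector(which(S == max(S), arr.ind = TRUE)), c(11, 11))
  expect_error(hessian_temporal_response(array(0, c(4, 4, 2))), "3 temporal")
})

test_that("responses are shift-invariant and follow the intensity power laws", {
  slab <- rand_slab(10, 10, seed = 14)
  for (f in list(function(s) structure_tensor_response(s)$S,
                 function(s) hessian_st_response(s)$S,
                 function(s) hessian_temporal_response(s)$S)) {
    expect_equal(f(slab + 5), f(slab), tolerance = 1e-8)
  }
  c0 <- 1.7
  expect_equal(structure_tensor_response(c0 * slab)$S,
               c0^6 * structure_tensor_response(slab)$S, tolerance = 1e-8)
  expect_equal(hessian_st_response(c0 * slab)$S,
               c0^3 * hessian_st_response(slab)$S, tolerance = 1e-8)
  expect_equal(hessian_temporal_response(c0 * slab)$S,
               c0^2 * hessian_temporal_response(slab)$S, tolerance = 1e-8)
})

test_that("variation along one axis gives non-positive Harris strength", {
  slab <- array(0, c(12, 12, 3))
  for (k in 1:3) slab[, , k] <- matrix(rep(sin(seq_len(12)), each = 12), 12, 12)
  S <- structure_tensor_response(slab, kappa = 0.01)$S
  expect_lte(max(S), 1e-12)  # rank-1 tensor: det = 0, S = -kappa trace^3
})

test_that("regional maxima find peaks, respect thresholds and reduce plateaus", {
  bump <- gauss_bump(20, 20, 7, 12, sigma = 2)
  ips <- regional_maxima(bump, min_strength = 0.1)
  expect_equal(ips$n, 1)
  expect_equal(c(ips$points$row, ips$points$col), c(7, 12))

  # constant map: excluded by the positive threshold contract
  expect_equal(regional_maxima(matrix(0.5, 10, 10), min_strength = 0.6)$n, 0)

  two <- gauss_bump(24, 24, 12, 6, sigma = 1.5) + gauss_bump(24, 24, 12, 16, sigma = 1.5)
  ips2 <- regional_maxima(two, min_strength = 0.1)
  expect_equal(ips2$n, 2)
  # oracle: exhaustive neighbour comparison
  or <- 0
  for (r in 2:23) for (c in 2:23) {
    nb <- two[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (two[r, c] > 0.1 && two[r, c] >= max(nb)) or <- or + 1
  }
  expect_equal(ips2$n, or)

  # a flat plateau contributes exactly one locus near its centroid
  plat <- matrix(0, 15, 15); plat[6:9, 6:9] <- 1
  ipp <- regional_maxima(plat, min_strength = 0.5)
  expect_equal(ipp$n, 1)
  expect_true(ipp$points$row %in% 7:8 && ipp$points$col %in% 7:8)
})
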