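test_that("golden-angle radial geometry is correct, nested and in bounds", {
  tr <- golden_angle_radial_trajectory(3L, 16L)
  az <- atan2(tr$coords[seq(16, 48, by = 16), 2],
              tr$coords[seq(16, 48, by = 16), 1]) * 180 / pi
  expect_equal((az %% 360), c(0, 111.246, 222.492) %% 360, tolerance = 1e-3)
  ## center-out: every spoke starts at k = 0
  starts <- tr$coords[seq(1, 48, by = 16), ]
  expect_true(all(starts == 0))
  ## bounds
  expect_true(all(abs(tr$coords) <= 0.5 + 1e-12))
  ## nesting: first m spokes of a larger set equal the m-spoke set
  big <- golden_angle_radial_trajectory(13L, 16L)
  small <- golden_angle_radial_trajectory(5L, 16L)
  expect_identical(big$coords[seq_len(5L * 16L), ], small$coords)
  sub <- subset_spokes(big, 5 / 13)
  expect_identical(sub$coords, small$coords)
})

test_that("ramp-up readout is quadratic then linear, continuous in slope", {
  r0 <- psgre:::radial_ramp_profile(33L, 0)
  expect_equal(diff(r0), rep(diff(r0)[1], 32L))   # pure linear readout
  expect_equal(r0[33], 0.5)
  f <- 0.4
  r <- psgre:::radial_ramp_profile(101L, f)
  t <- (0:100) / 100
  ramp <- t <= f
  ## quadratic prefix: second differences constant
  expect_equal(diff(diff(r[ramp])), rep(diff(diff(r[ramp]))[1], sum(ramp) - 2L),
               tolerance = 1e-12)
  ## linear tail: first differences constant
  expect_equal(diff(r[!ramp]), rep(diff(r[!ramp])[1], sum(!ramp) - 1L),
               tolerance = 1e-12)
  ## continuity of slope at the junction: adjacent steps differ by at
  ## most the quadratic prefix's per-step slope increment
  i <- max(which(ramp))
  expect_lt(abs((r[i + 1] - r[i]) - (r[i] - r[i - 1])),
            1.5 * abs((r[3] - r[2]) - (r[2] - r[1])))
  expect_equal(r[101], 0.5)
})

test_that("3D golden-means directions cover the sphere and nest", {
  tr <- golden_angle_radial_trajectory(200L, 8L, ndim = 3L)
  ends <- tr$coords[seq(8, 1600, by = 8), ]
  d <- ends / sqrt(rowSums(ends^2))
  ## rough uniformity: octant occupancy all positive
  oc <- table(paste(d[, 1] > 0, d[, 2] > 0, d[, 3] > 0))
  expect_length(oc, 8L)
  small <- golden_angle_radial_trajectory(50L, 8L, ndim = 3L)
  expect_identical(tr$coords[seq_len(400L), ], small$coords)
})

test_that("Cartesian forward matches the brute-force DFT", {
  set.seed(21)
  u <- matrix(random_complex(32 * 32), 32, 32)
  tr <- cartesian_trajectory(c(32L, 32L))
  pl <- nufft_plan(tr, c(32L, 32L))
  y <- nufft_forward(u, pl)
  oracle <- ndft_oracle(u, tr$coords)
  expect_lt(max(Mod(y - oracle)) / max(Mod(oracle)), 1e-10)
  ## unitary round trip
  back <- nufft_adjoint(y, pl) / (32 * 32)
  expect_lt(max(Mod(back - u)) / max(Mod(u)), 1e-10)
})

test_that("radial gridded transform matches the brute-force NDFT", {
  set.seed(22)
  u <- matrix(random_complex(32 * 32), 32, 32)
  tr <- golden_angle_radial_trajectory(10L, 20L, ramp_fraction = 0.3)
  pl <- nufft_plan(tr, c(32L, 32L))
  y <- nufft_forward(u, pl)
  oracle <- ndft_oracle(u, tr$coords)
  expect_lt(max(Mod(y - oracle)) / max(Mod(oracle)), 1e-6)
  ## delta image at the FOV center has a flat spectrum
  dl <- matrix(0 + 0i, 32, 32); dl[17, 17] <- 1
  yd <- nufft_forward(dl, pl)
  expect_lt(max(Mod(yd - 1)), 1e-6)
  ## zero image gives zero samples
  expect_true(all(nufft_forward(matrix(0 + 0i, 32, 32), pl) == 0))
})

test_that("adjoint identity holds for every mode, dimension and coil count", {
  set.seed(23)
  cases <- list(
    list(traj = cartesian_trajectory(c(32L, 32L)), shape = c(32L, 32L), nc = 1L),
    list(traj = golden_angle_radial_trajectory(8L, 16L), shape = c(32L, 32L), nc = 4L),
    list(traj = golden_angle_radial_trajectory(20L, 8L, ndim = 3L),
         shape = c(32L, 32L, 32L), nc = 2L))
  for (cs in cases) {
    pl <- nufft_plan(cs$traj, cs$shape)
    cm <- make_coil_maps(cs$shape, cs$nc, seed = 31L,
                         mode = if (cs$nc == 1L) "uniform" else "gaussian")
    u <- array(random_complex(prod(cs$shape)), cs$shape)
    y <- matrix(random_complex(pl$m * cs$nc), pl$m, cs$nc)
    Au <- encode_forward(u, cm, pl)
    Ahy <- encode_adjoint(y, cm, pl)
    lhs <- sum(Conj(Au) * y)
    rhs <- sum(Conj(u) * Ahy)
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
    ## normal operator is positive semidefinite
    q <- Re(sum(Conj(u) * encode_adjoint(Au, cm, pl)))
    expect_gte(q, 0)
  }
})

test_that("density-compensated adjoint previews a disk phantom faithfully", {
  shape <- c(64L, 64L)
  ax <- seq(-1, 1, length.out = 65L)[-1L] - 1 / 64
  disk <- outer(ax, ax, function(x, y) as.numeric(x^2 + y^2 < 0.4)) + 0i
  tr <- golden_angle_radial_trajectory(201L, 64L)   # 2x angular oversampling
  pl <- nufft_plan(tr, shape)
  cm <- make_coil_maps(shape, 1L, mode = "uniform")
  y <- encode_forward(disk, cm, pl)
  prev <- gridding_preview(y, cm, pl, tr)
  expect_gt(cor(c(Re(prev)), c(Re(disk))), 0.95)
})

test_that("forward rejects mismatched grids", {
  tr <- golden_angle_radial_trajectory(4L, 8L)
  pl <- nufft_plan(tr, c(32L, 32L))
  expect_error(nufft_forward(matrix(0 + 0i, 16, 16), pl))
  cm <- make_coil_maps(c(64L, 64L), 2L)
  expect_error(encode_forward(matrix(0 + 0i, 32, 32), cm, pl))
})
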