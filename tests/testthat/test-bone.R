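test_that("echo subtraction suppresses long-T2 and keeps short-T2 signal", {
  x <- array(random_complex(64, seed = 61), c(8, 8))
  expect_equal(echo_subtraction(x, x), array(0, c(8, 8)))
  expect_equal(echo_subtraction(x, array(0 + 0i, c(8, 8))), Mod(x))
  sp <- seq_params()
  bone <- quiet_epg(sp, tissue_params(t1 = 240, t2 = 0.38, pd = 0.2))
  csf <- quiet_epg(sp, tissue_params(t1 = 4000, t2 = 2000))
  db <- Mod(bone$s_ute) - Mod(bone$s_cte)
  dc <- Mod(csf$s_ute) - Mod(csf$s_cte)
  expect_gt(db, 0)
  expect_lt(abs(dc), 0.01 * Mod(csf$s_ute))
})

test_that("direct normalized subtraction equals the tanh oracle for any theta", {
  dte <- 2.38 - 0.08
  for (th in c(0, 1.5, 4, 117)) {
    sp <- seq_params(theta = th)
    for (t2 in c(0.38, 80)) {
      s <- quiet_epg(sp, tissue_params(t1 = 1000, t2 = t2))
      xu <- array(s$s_ute, c(2, 2)); xc <- array(s$s_cte, c(2, 2))
      bi <- normalized_subtraction_direct(xu, xc)
      expect_equal(bi$xs[1, 1], tanh(dte / (2 * t2)), tolerance = 1e-6,
                   label = sprintf("xs (theta=%g, T2=%g)", th, t2))
    }
  }
  ## reference values: near 1 for bone, near 0 for soft tissue
  expect_equal(tanh(dte / (2 * 0.38)), 0.995, tolerance = 1e-3)
  expect_equal(tanh(dte / (2 * 80)), 0.0144, tolerance = 5e-3)
})

test_that("the normalized ratio is exactly proton-density independent and monotone in T2", {
  sp <- seq_params()
  s1 <- quiet_epg(sp, tissue_params(t1 = 800, t2 = 5, pd = 0.5))
  s2 <- quiet_epg(sp, tissue_params(t1 = 800, t2 = 5, pd = 1.0))
  r <- function(s) normalized_subtraction_direct(
    array(s$s_ute, c(1, 1)), array(s$s_cte, c(1, 1)))$xs[1]
  expect_identical(r(s1), r(s2))
  t2s <- c(0.2, 0.5, 2, 10, 50, 300)
  vals <- vapply(t2s, function(t2)
    r(quiet_epg(sp, tissue_params(t1 = 1000, t2 = t2))), numeric(1))
  expect_true(all(diff(vals) < 0))
  ## all-zero input is flagged
  expect_warning(normalized_subtraction_direct(array(0 + 0i, c(2, 2)),
                                               array(0 + 0i, c(2, 2))),
                 "all-zero")
})

test_that("weight maps highlight true short-T2 signal change", {
  z <- array(0 + 0i, c(16, 16))
  w0 <- build_weights(z, z)
  expect_true(all(w0$w == 0))
  ## a delta-like subtraction reproduces the separable kernel shape
  d <- z; d[8, 8] <- 1
  wd <- build_weights(d, z, kernel_width = 5L)
  k <- 0.5 * (1 - cos(2 * pi * 1:5 / 6)); k <- k / sum(k)
  expect_equal(wd$w[6:10, 8], k / max(outer(k, k)) * k[3],
               tolerance = 1e-12)
  expect_equal(wd$w, t(wd$w), tolerance = 1e-12)   # separable symmetry
  ## phantom: bone neighborhoods outweigh air
  st <- default_ideal()
  tm <- default_phantom()
  W <- build_weights(attr(st, "truth_ute"), attr(st, "truth_cte"))
  expect_gt(mean(W$w[tm$class_id == 3L]), mean(W$w[tm$class_id == 1L]))
  expect_error(build_weights(z, z, kernel_width = 4L), "odd")
})

test_that("weighted least-squares converges to the ratio where weighted signal is strong", {
  ## unweighted scalar problem with many iterations equals the direct ratio
  xu <- array(3 + 0i, c(2, 2)); xc <- array(1 + 0i, c(2, 2))
  w1 <- structure(list(w = array(1, c(2, 2)), kernel_width = 3L),
                  class = "weight_map")
  b <- normalized_subtraction_wls(xu, xc, w1, n_iters = 50L)
  expect_equal(b$xs, array(0.5, c(2, 2)), tolerance = 1e-6)
  ## zero iterations returns the zero initialization
  b0 <- normalized_subtraction_wls(xu, xc, w1, n_iters = 0L)
  expect_true(all(b0$xs == 0))
  ## monotone weighted objective
  st <- default_ideal()
  bw <- normalized_subtraction_wls(attr(st, "truth_ute"),
                                   attr(st, "truth_cte"), n_iters = 10L)
  expect_false(bw$diverged)
  expect_true(all(diff(bw$resid) <= 1e-8))
})

test_that("under noise the WLS bone image is quieter in air than the direct ratio", {
  st <- default_ideal()
  tm <- default_phantom()
  set.seed(63)
  sigma <- 0.005 * max(Mod(attr(st, "truth_ute")))
  xu <- attr(st, "truth_ute") +
    array(random_complex(prod(tm$shape)) * sigma, tm$shape)
  xc <- attr(st, "truth_cte") +
    array(random_complex(prod(tm$shape)) * sigma, tm$shape)
  air <- tm$class_id == 1L
  bd <- normalized_subtraction_direct(xu, xc)
  bw <- normalized_subtraction_wls(xu, xc, n_iters = 10L)
  expect_lte(mean(abs(bw$xs[air])), mean(abs(bd$xs[air])))
  ## and bone stays bright
  expect_gt(mean(bw$xs[tm$class_id == 3L]), 0.8)
})
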