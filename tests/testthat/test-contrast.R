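test_that("background phase is recovered from the two passes", {
  ## scalar forward construction: x = 2 (real), phi = 0.3
  xp <- array(2 * exp(0.3i), c(4, 4))
  xm <- array(2 * exp(0.3i), c(4, 4))   # x real: conj(x) = x
  est <- estimate_background_phase(xp, xm)
  expect_equal(est$phi, array(0.3, c(4, 4)), tolerance = 1e-12)
  ## phi = 0 with any real image estimates zero
  xr <- array(runif(16) + 1, c(4, 4))
  est0 <- estimate_background_phase(xr + 0i, xr + 0i)
  expect_equal(est0$phi, array(0, c(4, 4)), tolerance = 1e-12)
  ## round trip on the synthetic stack
  st <- default_ideal()
  truth_phi <- attr(st, "phase")
  supp <- Mod(attr(st, "truth_cte")) > 0
  est2 <- estimate_background_phase(st$cte_pos, st$cte_neg)
  expect_lt(max(abs(est2$phi - truth_phi)[supp]), 1e-10)
  ## near-zero voxels are masked and counted
  expect_equal(est2$n_masked, sum(!supp))
  expect_true(all(est2$phi[!est2$mask] == 0))
})

test_that("pass combination recovers the multi-contrast image", {
  st <- default_ideal()
  truth <- attr(st, "truth_cte")
  supp <- Mod(truth) > 0
  est <- estimate_background_phase(st$cte_pos, st$cte_neg)
  comb <- combine_passes(st$cte_pos, st$cte_neg, est)
  ## equality up to the half-angle sign: compare extraction-invariant forms
  expect_lt(max(Mod(Mod(comb$x) - Mod(truth))[supp]), 1e-10)
  for (psi in c(0, 37, 122)) {
    e1 <- extract_contrast(comb, psi)$image
    e2 <- extract_contrast(truth, psi)$image
    expect_lt(max(abs(e1 - e2)[supp]), 1e-10)
  }
  ## conjugate-pair passes with zero phase reproduce x itself
  ph0 <- estimate_background_phase(truth, Conj(truth))
  comb0 <- combine_passes(truth, Conj(truth), ph0)
  expect_lt(max(Mod(Mod(comb0$x) - Mod(truth))[supp]), 1e-12)
})

test_that("pass averaging halves independent noise variance", {
  set.seed(51)
  n <- 20000L
  x <- 1.3 * exp(0.4i)             # true multi-contrast value
  phi <- 0.7
  sigma <- 0.05
  xp <- array(exp(1i * phi) * x + random_complex(n) * sigma, c(n, 1))
  xm <- array(exp(1i * phi) * Conj(x) + random_complex(n) * sigma, c(n, 1))
  truth_ph <- structure(list(phi = array(phi, c(n, 1)), shape = c(n, 1L)),
                        class = "phase_map")
  comb <- combine_passes(xp, xm, truth_ph)
  v <- stats::var(c(Re(comb$x))) + stats::var(c(Im(comb$x)))
  expect_equal(v, sigma^2, tolerance = 0.05)   # half of the 2 sigma^2 single-pass
})

test_that("contrast extraction projects, rectifies and is pi-periodic", {
  one <- array(1 + 0i, c(2, 2))
  expect_equal(extract_contrast(one, 0)$image, array(1, c(2, 2)))
  expect_equal(extract_contrast(one, 90)$image, array(0, c(2, 2)),
               tolerance = 1e-12)
  set.seed(52)
  x <- array(random_complex(64), c(8, 8))
  for (psi in runif(20, -360, 720)) {
    a <- extract_contrast(x, psi)$image
    b <- extract_contrast(x, psi + 180)$image
    expect_equal(a, b, tolerance = 1e-12)
  }
  ## invariance to the half-angle sign ambiguity
  psi <- 33
  expect_equal(extract_contrast(-x, psi)$image,
               extract_contrast(x, psi)$image, tolerance = 1e-12)
})

test_that("a psi sweep produces a continuous image sequence", {
  st <- default_ideal()
  x <- attr(st, "truth_cte")
  psis <- seq(0, 180, by = 1)
  prev <- extract_contrast(x, 0)$image
  max_jump <- 0
  for (p in psis[-1]) {
    cur <- extract_contrast(x, p)$image
    max_jump <- max(max_jump, max(abs(cur - prev)))
    prev <- cur
  }
  ## |d x_psi / d psi| <= |x| so one-degree steps move at most |x| * pi/180
  expect_lt(max_jump, max(Mod(x)) * pi / 180 + 1e-12)
})

test_that("extracted contrasts order tissues as the detected intervals predict", {
  sp <- seq_params()
  tis <- default_tissue_classes()[c("wm", "gm", "csf")]
  iv <- suppressWarnings(weighting_intervals(sp, tis, echo = "cte"))
  sig <- vapply(tis, function(ts) quiet_epg(sp, ts)$s_cte, complex(1))
  psi_t2 <- mean(iv$t2w)
  v2 <- abs(Re(sig * exp(1i * psi_t2 * pi / 180)))
  expect_true(v2[["csf"]] > v2[["gm"]] && v2[["gm"]] > v2[["wm"]])
  psi_t1 <- mean(iv$t1w)
  v1 <- abs(Re(sig * exp(1i * psi_t1 * pi / 180)))
  expect_true(v1[["wm"]] > v1[["gm"]] && v1[["gm"]] > v1[["csf"]])
})
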