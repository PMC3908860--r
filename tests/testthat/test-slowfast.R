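test_that("fast-subsystem equilibria satisfy stationarity to 1e-10", {
  p <- neuron_params(theta_K2 = -0.0075, theta_h = 0.038)
  fb <- fast_equilibria(p, m_K2 = seq(0, 0.4, length.out = 41))
  expect_gt(nrow(fb$points), 40)
  res <- mapply(function(V, m) abs(burstwave:::fast_current(V, m, p)),
                fb$points$V, fb$points$m_K2)
  expect_lt(max(res), 1e-10)
})

test_that("slow gate fully on forces a single hyperpolarized rest state", {
  p <- neuron_params(theta_K2 = -0.0075, theta_h = 0.038)
  fb <- fast_equilibria(p, m_K2 = 1)
  expect_equal(nrow(fb$points), 1)
  expect_lt(fb$points$V, -0.05)
  expect_true(fb$points$stable)
})

test_that("fold of the rest branch matches a brute-force root-count scan", {
  p <- neuron_params(theta_K2 = -0.0075, theta_h = 0.038)
  fb <- fast_equilibria(p, m_K2 = seq(0.05, 0.3, length.out = 26))
  expect_gte(nrow(fb$folds), 1)
  mf <- fb$folds$m_K2[1]
  ## oracle: root counts on either side of the fold at 1e-6 resolution
  count <- function(m) {
    V <- seq(-0.07, 0.02, length.out = 4000)
    f <- burstwave:::fast_current(V, m, p)
    sum(f[-length(f)] * f[-1] <= 0 & f[-length(f)] != 0)
  }
  expect_true(count(mf - 1e-6) != count(mf + 1e-6))
})

test_that("fast orbits close and vary continuously along the branch", {
  p <- neuron_params(theta_h = 0.0415)
  ms <- seq(0.08, 0.26, by = 0.02)
  orbs <- lapply(ms, function(m) fast_orbit(p, m))
  ok <- !vapply(orbs, is.null, TRUE)
  expect_gt(sum(ok), 6)
  cl <- vapply(orbs[ok], `[[`, 1, "closure")
  expect_lt(max(cl), 1e-6)
  vmax <- vapply(orbs[ok], `[[`, 1, "V_max")
  expect_lt(max(abs(diff(vmax))), 1e-2)  # continuity along the sweep
  ## beyond the fold of the spiking manifold: flagged non-oscillatory
  expect_null(fast_orbit(p, 0.6))
})

test_that("trapezoidal orbit averages agree with quadrature refinement", {
  p <- neuron_params()
  ## constant and sinusoidal synthetic "orbits"
  tt <- seq(0, 1, length.out = 2001)
  orb <- structure(list(m_K2 = 0.1, period = 1,
                        samples = tibble::tibble(time = tt, V = -0.02,
                                                 h_Na = 0.5, m_h = 0.1),
                        V_max = -0.02, V_min = -0.02, closure = 0),
                   class = "fast_orbit")
  av <- orbit_averages(orb, p)
  expect_equal(av[["V_mean"]], -0.02, tolerance = 1e-12)
  orb$samples$V <- -0.02 + 0.01 * sin(2 * pi * tt)
  av2 <- orbit_averages(orb, p)
  expect_equal(av2[["V_mean"]], -0.02, tolerance = 1e-10)
  ## real orbit: trapezoid vs 10x-refined Riemann sum oracle
  ob <- fast_orbit(p, 0.15)
  av3 <- orbit_averages(ob, p)
  s <- ob$samples
  tfine <- seq(min(s$time), max(s$time), length.out = 10 * nrow(s))
  Vfine <- stats::approx(s$time, s$V, tfine)$y
  expect_equal(av3[["V_mean"]], mean(Vfine), tolerance = 1e-4)
})

test_that("saddle-node of equilibria reproduces the anchor fold values", {
  p <- neuron_params()
  sn10 <- locate_sn_equilibria(p, -0.010)
  expect_equal(sn10$theta_h, 0.0413523801025906, tolerance = 1e-6)
  expect_lt(sn10$residual, 1e-9)
  sn9 <- locate_sn_equilibria(p, -0.009)
  expect_equal(sn9$theta_h, 0.0413430845706376, tolerance = 1e-6)
  ## scan oracle: root count changes across the located fold
  count <- function(th) {
    pp <- neuron_params(theta_K2 = -0.010, theta_h = th)
    V <- seq(-0.068, -0.02, length.out = 3000)
    f <- steady_state_current(V, pp)
    sum(f[-3000] * f[-1] <= 0 & f[-3000] != 0)
  }
  expect_true(count(sn10$theta_h - 1e-6) != count(sn10$theta_h + 1e-6))
})

test_that("orbit-averaging and dynamical fold-of-orbits estimates agree", {
  p <- neuron_params()
  sn <- locate_sn_orbits(p, theta_h = 0.0415, method = "both",
                         agree_tol = 1e-4)
  expect_equal(sn$method, "both")
  expect_lt(abs(sn$theta_K2 - sn$theta_K2_dynamical), 1e-4)
  ## the boundary magnitude is near 0.0105 and nearly theta_h-independent
  expect_equal(abs(sn$theta_K2), 0.0105, tolerance = 0.01)
})

test_that("codimension-2 point sits at the printed organizing center", {
  p <- neuron_params()
  cp <- locate_codim2(p,
                      theta_K2_pts = seq(-0.0105, -0.009, length.out = 4),
                      theta_h_pts = seq(0.0414, 0.0417, length.out = 3),
                      sn_orbit_method = "averaging")
  expect_equal(cp$theta_h, 0.041356538, tolerance = 2e-5)
  expect_equal(cp$theta_K2, -0.010505, tolerance = 0.02)
  ## the equilibria fold curve is nearly horizontal across the window
  dr <- diff(range(cp$sn_equilibria$theta_h))
  expect_lt(dr / diff(range(cp$sn_equilibria$theta_K2)), 0.02)
})

test_that("the bursting trajectory rides the spiking manifold envelope", {
  p <- neuron_params()
  tr <- colD_trace()
  sp <- detect_spikes(tr)
  seg <- segment_bursts(sp, record_start = 0, record_end = max(tr$time))
  b <- seg[seg$complete, ][1, ]
  mid <- tr[tr$time > b$t_first + 0.5 & tr$time < b$t_last - 0.5, ]
  qs <- stats::quantile(mid$m_K2, c(0.25, 0.5, 0.75))
  orbs <- lapply(qs, function(m) fast_orbit(p, m))
  expect_false(any(vapply(orbs, is.null, TRUE)))
  band_hi <- max(vapply(orbs, `[[`, 1, "V_max"))
  band_lo <- min(vapply(orbs, `[[`, 1, "V_min"))
  inb <- mid[mid$m_K2 >= qs[1] & mid$m_K2 <= qs[3], ]
  expect_lt(max(inb$V), band_hi + 0.002)
  expect_gt(min(inb$V), band_lo - 0.002)
})
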