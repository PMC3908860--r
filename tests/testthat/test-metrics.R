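test_that("a constructed two-burst train yields the textbook statistics", {
  sp <- c(0, 0.1, 0.2, 5.0, 5.1, 5.2)
  seg <- segment_bursts(sp, isi_gap = 1)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$t_last - seg$t_first, c(0.2, 0.2))
  st <- temporal_stats(seg)
  expect_true(st$available)
  expect_equal(st$burst_duration, 0.2)
  expect_equal(st$interburst_interval, 4.8)
  expect_equal(st$period, 5.0)
  expect_equal(st$duty, 4)
})

test_that("a tonic train forms a single burst and stats are unavailable", {
  seg <- segment_bursts(seq(0, 10, by = 0.2), isi_gap = 1)
  expect_equal(nrow(seg), 1)
  expect_false(temporal_stats(seg)$available)
})

test_that("period equals burst duration plus interburst interval per cycle", {
  set.seed(11)
  ## irregular bursting train: jittered onsets and durations
  t <- 0; sp <- c()
  for (k in 1:8) {
    bd <- stats::runif(1, 0.5, 2); nsp <- sample(3:9, 1)
    sp <- c(sp, t + seq(0, bd, length.out = nsp))
    t <- t + bd + stats::runif(1, 2, 6)
  }
  st <- temporal_stats(segment_bursts(sp, isi_gap = 1))
  expect_equal(st$cycles$period,
               st$cycles$burst_duration + st$cycles$interburst_interval)
})

test_that("segmentation is idempotent and duty is rescale-invariant", {
  fx <- generate_spike_fixture(n_bursts = 4, spikes_per_burst = 6,
                               burst_duration = 1.2,
                               interburst_interval = 6.8)
  seg <- segment_bursts(fx$spikes, isi_gap = 1)
  seg2 <- segment_bursts(fx$spikes$time, isi_gap = 1)
  expect_identical(seg$t_first, seg2$t_first)
  st <- temporal_stats(seg)
  expect_equal(st$duty, fx$duty)
  ## uniform time rescaling leaves duty unchanged
  st3 <- temporal_stats(segment_bursts(fx$spikes$time * 3, isi_gap = 3))
  expect_equal(st3$duty, st$duty)
  expect_equal(st3$period, 3 * st$period)
})

test_that("spike detection recovers fixture spike times and thresholds", {
  fx <- generate_spike_fixture(n_bursts = 3, spikes_per_burst = 4,
                               burst_duration = 0.9,
                               interburst_interval = 5.1, trace = TRUE)
  sp <- detect_spikes(fx$trace, threshold = -0.01)
  expect_equal(nrow(sp), nrow(fx$spikes))
  expect_lt(max(abs(sp$time - fx$spikes$time)), 0.011)
  flat <- tibble::tibble(time = seq(0, 1, 1e-3), V = -0.05)
  expect_equal(nrow(detect_spikes(flat)), 0)
})

test_that("refractory filtering drops crossings that are too close", {
  tt <- seq(0, 1, by = 1e-3)
  V <- -0.05 + 0.08 * (sin(2 * pi * 50 * tt) > 0.95)  # 50 Hz bursts
  sp <- detect_spikes(tibble::tibble(time = tt, V = V),
                      refractory = 0.05)
  expect_true(all(diff(sp$time) >= 0.05))
})

test_that("latency and pulse-burst duration read correctly off a trace", {
  fx <- generate_spike_fixture(n_bursts = 1, spikes_per_burst = 5,
                               burst_duration = 2, interburst_interval = 10,
                               t0 = 3, trace = TRUE)
  pu <- pulse_spec(onset = 1, duration = 0.03, amplitude = -0.1)
  expect_equal(latency_to_spike(fx$trace, pu), 3 - 1.03, tolerance = 1e-2)
  expect_equal(pulse_burst_duration(fx$trace, pu), 2, tolerance = 1e-2)
  quiet <- tibble::tibble(time = seq(0, 5, 1e-3), V = -0.05)
  expect_warning(res <- pulse_burst_duration(quiet, pu), "no spikes")
  expect_true(is.na(res))
})

test_that("wave statistics: symmetry, modular arithmetic, ordering", {
  mk <- function(shift) {
    fx <- generate_spike_fixture(n_bursts = 6, spikes_per_burst = 4,
                                 burst_duration = 1,
                                 interburst_interval = 9, t0 = 2)
    fx$spikes$time + shift
  }
  ## identical cells: all lags zero, wave trivially "formed" unordered
  same <- list(`3` = mk(0), `4` = mk(0), `5` = mk(0))
  ws <- wave_stats(same)
  expect_true(all(abs(ws$pairs$phase) < 1e-9) || !ws$formed)
  ## posterior-leading wave with 13% lags
  lag <- 1.3
  wave <- list(`3` = mk(4 * lag), `4` = mk(3 * lag), `5` = mk(2 * lag),
               `6` = mk(lag), `7` = mk(0))
  ws2 <- wave_stats(wave)
  expect_true(ws2$formed)
  expect_equal(ws2$mean_phase, 13, tolerance = 1e-6)
  expect_equal(ws2$formation_cycles, 0L)
  ## shifting one cell by exactly one period leaves its phase unchanged
  wave3 <- wave
  wave3[["5"]] <- wave3[["5"]] + 10
  ws3 <- wave_stats(wave3)
  expect_equal(ws3$mean_phase, ws2$mean_phase, tolerance = 1e-6)
})

test_that("spikes-per-burst line is recovered from clean and noisy data", {
  slope <- 1.31; intercept <- 2.0
  d <- tibble::tibble(period = seq(15, 85, length.out = 10),
                      spikes = slope * period + intercept)
  fit <- suppressWarnings(spikes_per_burst_fit(d))  # exact fit
  expect_equal(fit$slope, slope, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  set.seed(3)
  dn <- d; dn$spikes <- dn$spikes + stats::rnorm(10, sd = 2)
  fitn <- spikes_per_burst_fit(dn)
  se <- 2 / (stats::sd(d$period) * sqrt(10))  # rough slope s.e. bound
  expect_lt(abs(fitn$slope - slope), 3 * se * 2)
  expect_error(spikes_per_burst_fit(
    tibble::tibble(period = c(5, 5, 5), spikes = 1:3)), "degenerate")
})
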