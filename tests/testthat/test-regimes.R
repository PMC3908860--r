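test_that("law fits recover exact synthetic coefficients", {
  d <- generate_law_fixture("BD_law", a = 0.97, b = -8.5, c_bif = 0.0105,
                            noise_sd = 0)
  fit <- fit_bd_law(d[, c("theta", "duration")])
  cf <- fit$coefficients
  expect_equal(cf[["a"]], 0.97, tolerance = 1e-5)
  expect_equal(cf[["b"]], -8.5, tolerance = 1e-4)
  expect_equal(cf[["c"]], 0.0105, tolerance = 1e-7)
  expect_lt(fit$residual_norm, 1e-5)

  di <- generate_law_fixture("IBI_law", a = 0.0071, b = 14.5,
                             c_bif = 0.041358, noise_sd = 0)
  fiti <- fit_ibi_law(di[, c("theta", "duration")], theta_bif = 0.041358)
  expect_equal(fiti$coefficients[["a"]], 0.0071, tolerance = 1e-6)
  expect_equal(fiti$coefficients[["b"]], 14.5, tolerance = 1e-6)
})

test_that("law fits recover coefficients within 5% at 1% noise", {
  d <- generate_law_fixture("BD_law", a = 0.97, b = -8.5, c_bif = 0.0105,
                            offsets = 10^seq(-6, -3.5, length.out = 20),
                            noise_sd = 0.01, seed = 21)
  cf <- fit_bd_law(d[, c("theta", "duration")])$coefficients
  expect_lt(abs(cf[["a"]] / 0.97 - 1), 0.05)
  expect_lt(abs(cf[["c"]] / 0.0105 - 1), 0.05)

  di <- generate_law_fixture("IBI_law", a = 0.0071, b = 14.5,
                             c_bif = 0.041358,
                             offsets = 10^seq(-9, -6.5, length.out = 20),
                             noise_sd = 0.01, seed = 22)
  cfi <- fit_ibi_law(di[, c("theta", "duration")],
                     theta_bif = 0.041358)$coefficients
  expect_lt(abs(cfi[["a"]] / 0.0071 - 1), 0.05)
  expect_lt(abs(cfi[["b"]] / 14.5 - 1), 0.05)
})

test_that("exact law data give scaling exponent -1/2", {
  d <- generate_law_fixture("BD_law", a = 0.5, b = 3, c_bif = 0.01,
                            offsets = 10^seq(-6, -3, length.out = 12))
  expo <- estimate_scaling_exponent(d$offset, d$duration, baseline = 3)
  expect_equal(expo, -0.5, tolerance = 0.02)
  expect_error(estimate_scaling_exponent(c(1, 2, 3, 4, 5),
                                         c(1, 1, 1, 1, 1)), "decades")
})

test_that("tidy, glance and autoplot work on law fits", {
  d <- generate_law_fixture("BD_law")
  fit <- fit_bd_law(d[, c("theta", "duration")])
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("a", "b", "c"))
  gl <- generics::glance(fit)
  expect_equal(gl$form, "BD_law")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("classification labels the four cardinal regimes", {
  sv <- solver_config()
  bur <- classify_regime(neuron_params(-0.0075, 0.038), sv,
                         t_transient = 60, t_record = 40)
  expect_equal(bur$label, "bursting")
  expect_true(bur$duty > 0 && bur$duty < 100)
  sil <- classify_regime(neuron_params(-0.0077, 0.0415), sv,
                         t_transient = 60, t_record = 40)
  expect_equal(sil$label, "silence")
  ton <- classify_regime(neuron_params(-0.0107, 0.04134), sv,
                         t_transient = 60, t_record = 40)
  expect_equal(ton$label, "tonic")
  bis <- classify_regime(neuron_params(-0.0115, 0.0415), sv,
                         t_transient = 60, t_record = 40)
  expect_equal(bis$label, "bistable_tonic_silence")
})

test_that("a single-point regime map agrees with direct classification", {
  g <- map_regimes(theta_K2 = -0.0075, theta_h = 0.038,
                   t_transient = 60, t_record = 40)
  expect_equal(nrow(g), 1)
  expect_equal(g$label, "bursting")
})

test_that("bisection finds the bursting-silence boundary near the fold", {
  ## the boundary in theta_h at theta_K2 = -0.010 is the saddle-node of
  ## equilibria; the fold solver provides the independent expected value
  fold <- locate_sn_equilibria(neuron_params(), -0.010)$theta_h
  b <- find_boundary("theta_h", lower = 0.0413, upper = 0.0414,
                     params_base = neuron_params(theta_K2 = -0.010),
                     tol = 2e-5, t_transient = 60, t_record = 40)
  expect_lt(abs(b$value - fold), 5e-5)
  expect_setequal(c(b$lower_label, b$upper_label),
                  c("bursting", "silence"))
})

test_that("the isoline solver inverts a closed-form burst generator", {
  ## stub generator with known inverse: BD = 50 (tk - 0.001),
  ## IBI = 400 (0.042 - th)
  stub <- function(tk, th) c(50 * (tk - 0.001), 400 * (0.042 - th))
  path <- find_duty_isoline(target_duty = 4, periods = c(10, 20),
                            tolerance = 0.01, measure_fn = stub,
                            start = c(0.005, 0.030), max_iter = 30,
                            step_max = c(0.02, 0.02))
  expect_true(all(path$converged))
  expect_equal(path$theta_K2, 0.001 + c(0.4, 0.8) / 50, tolerance = 1e-3)
  expect_equal(path$duty, c(4, 4), tolerance = 0.01)
  expect_equal(path$period, c(10, 20), tolerance = 0.1)
})
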