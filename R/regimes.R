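## Regime mapping over the (theta_K2, theta_h) plane and the
## inverse-square-root temporal laws near its saddle-node boundaries.

rest_like_state <- function() neuron_state(V = -0.0425, h_Na = 1,
                                           m_K2 = 0.01, m_h = 0.2)
spiking_like_state <- function() neuron_state(V = 0, h_Na = 0.8,
                                              m_K2 = 0.1, m_h = 0)

## classify one settled recording: "silence", "tonic", "bursting" or
## "transient" (spiking that dies out within the record)
classify_record <- function(trace, isi_gap, threshold = -0.01) {
  sp <- detect_spikes(trace, threshold)
  if (nrow(sp) == 0) return("silence")
  t_end <- max(trace$time)
  if (max(sp$time) < t_end - 2 * isi_gap &&
      utils::tail(trace$V, 1) < threshold) return("transient")
  seg <- segment_bursts(sp, isi_gap, record_start = min(trace$time),
                        record_end = t_end)
  if (nrow(seg) >= 2) "bursting" else "tonic"
}

#' Classify the regime of activity at one parameter point
#'
#' Integrates the model twice, once from a rest-like and once from a
#' spiking-like initial state, and labels the point `"silence"`,
#' `"tonic"`, `"bursting"`, `"bistable_tonic_silence"` or `"undecided"`.
#' The recording window is auto-extended (doubling, up to the solver's
#' `t_limit`) while the two runs disagree in a way compatible with a long
#' transient.
#'
#' @param params a [neuron_params()].
#' @param solver a [solver_config()].
#' @param t_transient settling time, s.
#' @param t_record initial recording window, s.
#' @param isi_gap burst segmentation gap, s.
#' @return A list: `label`, `duty` (percent, `NA` unless bursting),
#'   `stats` (the bursting [temporal_stats()] or `NULL`).
#' @export
classify_regime <- function(params, solver = solver_config(),
                            t_transient = 100, t_record = 60,
                            isi_gap = 1) {
  run1 <- function(y0, t_rec) run_to_attractor(params, y0, t_transient,
                                               t_rec, solver)
  t_rec <- t_record
  repeat {
    tr_rest <- run1(rest_like_state(), t_rec)
    tr_spk <- run1(spiking_like_state(), t_rec)
    lab_rest <- classify_record(tr_rest, isi_gap)
    lab_spk <- classify_record(tr_spk, isi_gap)
    labs <- c(lab_rest, lab_spk)
    if ("bursting" %in% labs) {
      tr <- if (lab_rest == "bursting") tr_rest else tr_spk
      st <- trace_stats(tr, isi_gap = isi_gap)
      if (!st$available && t_transient + 2 * t_rec < solver$t_limit) {
        t_rec <- 2 * t_rec
        next
      }
      return(list(label = "bursting", duty = st$duty, stats = st))
    }
    if (all(labs == "silence") || all(labs == "transient") ||
        setequal(labs, c("silence", "transient")))
      return(list(label = "silence", duty = NA_real_, stats = NULL))
    if (all(labs == "tonic"))
      return(list(label = "tonic", duty = NA_real_, stats = NULL))
    if (setequal(labs, c("tonic", "silence")) ||
        setequal(labs, c("tonic", "transient")))
      return(list(label = "bistable_tonic_silence", duty = NA_real_,
                  stats = NULL))
    if (t_transient + 2 * t_rec >= solver$t_limit)
      return(list(label = "undecided", duty = NA_real_, stats = NULL))
    t_rec <- 2 * t_rec
  }
}

#' Map regimes over a grid in the two half-activation voltages
#'
#' @param theta_K2,theta_h strictly increasing axis values, V.
#' @param params_base template [neuron_params()] supplying every other
#'   constant.
#' @inheritParams classify_regime
#' @return A tibble with one row per grid cell: `theta_K2`, `theta_h`,
#'   `label`, `duty`.
#' @export
map_regimes <- function(theta_K2, theta_h, params_base = neuron_params(),
                        solver = solver_config(), t_transient = 100,
                        t_record = 60, isi_gap = 1) {
  stopifnot(!is.unsorted(theta_K2, strictly = TRUE) || length(theta_K2) == 1,
            !is.unsorted(theta_h, strictly = TRUE) || length(theta_h) == 1)
  grid <- tidyr::expand_grid(theta_K2 = theta_K2, theta_h = theta_h)
  res <- purrr::pmap(grid, function(theta_K2, theta_h) {
    p <- modify_params(params_base, theta_K2 = theta_K2, theta_h = theta_h)
    cl <- classify_regime(p, solver, t_transient, t_record, isi_gap)
    tibble::tibble(label = cl$label, duty = cl$duty)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

## params with some fields replaced (gates rebuilt)
modify_params <- function(params, ...) {
  new <- utils::modifyList(params[setdiff(names(params), "gates")],
                           list(...))
  do.call(neuron_params, new)
}

#' Locate a regime boundary by bisection
#'
#' Bisects one of the two half-activation voltages, holding the other
#' fixed, until the classification changes, to a parameter tolerance.
#'
#' @param axis `"theta_K2"` or `"theta_h"`: the swept parameter.
#' @param lower,upper bracket for the swept parameter, V; the labels at
#'   the two ends must differ.
#' @param params_base template [neuron_params()] (its value on `axis` is
#'   ignored).
#' @param tol bisection tolerance, V.
#' @inheritParams classify_regime
#' @return A list: `value` (V), `lower_label`, `upper_label`.
#' @export
find_boundary <- function(axis = c("theta_K2", "theta_h"), lower, upper,
                          params_base = neuron_params(),
                          solver = solver_config(), tol = 1e-7,
                          t_transient = 100, t_record = 60, isi_gap = 1) {
  axis <- match.arg(axis)
  lab <- function(x) {
    p <- do.call(modify_params,
                 c(list(params_base), stats::setNames(list(x), axis)))
    classify_regime(p, solver, t_transient, t_record, isi_gap)$label
  }
  lab_lo <- lab(lower)
  lab_hi <- lab(upper)
  if (lab_lo == lab_hi)
    stop("no bracket: both ends classify as ", lab_lo)
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (lab(mid) == lab_lo) lo <- mid else hi <- mid
  }
  list(value = (lo + hi) / 2, lower_label = lab_lo, upper_label = lab_hi)
}

#' Inverse-square-root law for burst duration
#'
#' Evaluates `T(theta) = a / sqrt(c - |theta|) + b`, the temporal law of
#' burst duration as the slow-potassium half-activation approaches the
#' saddle-node bifurcation for periodic orbits at magnitude `c`.
#'
#' @param theta the swept half-activation voltage, V (vectorized).
#' @param a,b,c law coefficients (s sqrt(V); s; V).
#' @return Duration(s), s.
#' @export
bd_law <- function(theta, a, b, c) a / sqrt(c - abs(theta)) + b

#' Inverse-square-root law for interburst interval / latency
#'
#' Evaluates `T(theta) = a / sqrt(theta_bif - theta) + b`, the temporal
#' law of the interburst interval (and of latency to spiking) as the
#' hyperpolarization-activated gate's half-activation approaches the
#' saddle-node bifurcation for equilibria at `theta_bif`.
#'
#' @inheritParams bd_law
#' @param theta_bif bifurcation value, V.
#' @return Duration(s), s.
#' @export
ibi_law <- function(theta, a, b, theta_bif) a / sqrt(theta_bif - theta) + b

new_isr_fit <- function(form, coefs, data, resid) {
  structure(list(form = form, coefficients = coefs, data = data,
                 residual_norm = sqrt(sum(resid^2)), n = nrow(data)),
            class = "isr_fit")
}

#' Fit the burst-duration law
#'
#' Trust-region (Levenberg-Marquardt) least squares of
#' `T = a / sqrt(c - |theta|) + b` with `a`, `b`, `c` all free.
#'
#' @param data a data frame with columns `theta` (V) and `duration` (s).
#' @param start optional named start values `c(a =, b =, c =)`.
#' @return An `isr_fit` object (supports [generics::tidy()],
#'   [generics::glance()] and `autoplot()`); coefficient `c` is the
#'   fitted bifurcation magnitude, V.
#' @export
fit_bd_law <- function(data, start = NULL) {
  stopifnot(nrow(data) >= 4)
  th <- abs(data$theta); Td <- data$duration
  if (is.null(start)) {
    c0 <- max(th) + 0.1 * diff(range(th)) + 1e-6
    x0 <- 1 / sqrt(c0 - th)
    ab <- stats::coef(stats::lm(Td ~ x0))
    start <- c(a = max(ab[[2]], 1e-8), b = ab[[1]], c = c0)
  }
  res_fn <- function(p) bd_law(th, p[["a"]], p[["b"]], p[["c"]]) - Td
  fit <- minpack.lm::nls.lm(
    par = start, fn = res_fn,
    lower = c(a = 1e-12, b = -Inf, c = max(th) + 1e-12),
    control = minpack.lm::nls.lm.control(ftol = 1e-9, ptol = 1e-9,
                                         maxiter = 500))
  if (fit$info %in% c(0, 9))
    stop("burst-duration law fit did not converge: ", fit$message)
  new_isr_fit("BD_law", fit$par, data, fit$fvec)
}

#' Fit the interburst-interval law
#'
#' Trust-region least squares of `T = a / sqrt(theta_bif - theta) + b`
#' with `a` and `b` free and `theta_bif` fixed (determined separately
#' from the saddle-node of equilibria).
#'
#' @inheritParams fit_bd_law
#' @param theta_bif fixed bifurcation value, V; must exceed all `theta`.
#' @return An `isr_fit` object.
#' @export
fit_ibi_law <- function(data, theta_bif, start = NULL) {
  stopifnot(nrow(data) >= 3, theta_bif > max(data$theta))
  th <- data$theta; Td <- data$duration
  if (is.null(start)) {
    x0 <- 1 / sqrt(theta_bif - th)
    ab <- stats::coef(stats::lm(Td ~ x0))
    start <- c(a = max(ab[[2]], 1e-10), b = ab[[1]])
  }
  res_fn <- function(p) ibi_law(th, p[["a"]], p[["b"]], theta_bif) - Td
  fit <- minpack.lm::nls.lm(
    par = start, fn = res_fn, lower = c(a = 1e-14, b = -Inf),
    control = minpack.lm::nls.lm.control(ftol = 1e-9, ptol = 1e-9,
                                         maxiter = 500))
  if (fit$info %in% c(0, 9))
    stop("interburst-interval law fit did not converge: ", fit$message)
  coefs <- c(fit$par, theta_bif = theta_bif)
  new_isr_fit("IBI_law", coefs, data, fit$fvec)
}

#' @export
print.isr_fit <- function(x, ...) {
  cat("<isr_fit:", x$form, "> ",
      paste(names(x$coefficients),
            format(x$coefficients, digits = 8), sep = " = ",
            collapse = ", "),
      "\n  residual norm", format(x$residual_norm, digits = 4),
      "on", x$n, "points\n")
  invisible(x)
}

#' Scaling exponent of a temporal law near a bifurcation
#'
#' Log-log regression of `duration - baseline` against the parameter
#' offset from the bifurcation; an inverse-square-root law gives slope
#' -1/2.
#'
#' @param offset positive parameter distances to the bifurcation, V.
#' @param duration measured durations, s.
#' @param baseline the additive constant `b` of the law, s.
#' @return The regression slope (dimensionless).
#' @export
estimate_scaling_exponent <- function(offset, duration, baseline = 0) {
  stopifnot(length(offset) >= 5, all(offset > 0))
  if (max(offset) / min(offset) < 100)
    stop("offsets must span at least two decades")
  y <- duration - baseline
  if (any(y <= 0)) stop("durations must exceed the baseline")
  stats::coef(stats::lm(log(y) ~ log(offset)))[[2]]
}

#' Duty-cycle-preserving coregulation path
#'
#' For each target period, finds a parameter pair (theta_K2, theta_h)
#' whose bursting attractor has the target duty cycle (within tolerance)
#' and the target period, by quasi-Newton (Broyden secant) refinement on
#' measured burst statistics.
#'
#' @param target_duty target duty cycle, percent.
#' @param periods vector of target cycle periods, s.
#' @param tolerance acceptable deviation of duty, percentage points.
#' @param measure_fn function `(theta_K2, theta_h) ->
#'   c(burst_duration, interburst_interval)`; defaults to simulating the
#'   model and measuring [trace_stats()].  Swappable for closed-loop
#'   testing.
#' @param start initial `c(theta_K2, theta_h)` guess for the first
#'   period; later periods start from the previous solution.
#' @param step_max per-iteration step caps for the two parameters, V.
#' @param params_base,solver model context for the default `measure_fn`.
#' @param max_iter Broyden iteration cap per target.
#' @return A tibble (class `coregulation_path`): `period_target`,
#'   `theta_K2`, `theta_h`, `period`, `duty`, `converged`.
#' @export
find_duty_isoline <- function(target_duty = 10, periods,
                              tolerance = 0.1, measure_fn = NULL,
                              start = c(0.006, 0.0407),
                              params_base = neuron_params(),
                              solver = solver_config(), max_iter = 12,
                              step_max = c(2e-3, 2e-4)) {
  if (is.null(measure_fn)) {
    measure_fn <- function(theta_K2, theta_h) {
      p <- modify_params(params_base, theta_K2 = theta_K2,
                         theta_h = theta_h)
      tr <- run_to_attractor(p, rest_like_state(), t_transient = 60,
                             t_record = 150, solver = solver)
      st <- trace_stats(tr)
      if (!st$available) return(c(NA_real_, NA_real_))
      c(st$burst_duration, st$interburst_interval)
    }
  }
  x <- start
  rows <- purrr::map(periods, function(P) {
    target <- c(target_duty / 100 * P, (1 - target_duty / 100) * P)
    f <- function(x) measure_fn(x[1], x[2]) - target
    ## finite-difference Jacobian once, then Broyden updates
    fx <- f(x)
    h <- c(2e-4, 2e-5)
    J <- cbind((f(x + c(h[1], 0)) - fx) / h[1],
               (f(x + c(0, h[2])) - fx) / h[2])
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      if (any(is.na(fx))) break
      bd <- fx[1] + target[1]; per <- sum(fx + target)
      duty <- 100 * bd / per
      if (abs(duty - target_duty) <= tolerance &&
          abs(per - P) <= 0.005 * P) { conv <- TRUE; break }
      dx <- tryCatch(-solve(J, fx), error = function(e) NULL)
      if (is.null(dx)) break
      dx <- pmin(pmax(dx, -step_max), step_max)
      xn <- x + dx
      fn <- f(xn)
      if (!any(is.na(fn)))
        J <- J + ((fn - fx - J %*% dx) %*% t(dx)) / sum(dx^2)
      x <<- xn; fx <- fn
    }
    meas <- fx + target
    tibble::tibble(period_target = P, theta_K2 = x[1], theta_h = x[2],
                   period = sum(meas), duty = 100 * meas[1] / sum(meas),
                   converged = conv)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("coregulation_path", class(out))
  out
}
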