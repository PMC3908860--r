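#' Solver configuration
#'
#' Settings for the adaptive high-order integrator (deSolve's `lsoda`),
#' used for every simulation in the package.
#'
#' @param rtol relative tolerance.
#' @param atol absolute tolerance (applied to every state).
#' @param dt output sampling interval, s.  Spike times are recovered from
#'   the sampled trace by linear interpolation, so `dt` bounds the spike
#'   timing resolution; 1 ms resolves the ~10 ms spikes of the model well.
#' @param hmax maximal internal step, s.
#' @param t_limit hard cap on simulated model time for auto-extending
#'   protocols, s.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(rtol = 1e-9, atol = 1e-12, dt = 1e-3,
                          hmax = 0.25, t_limit = 2000) {
  stopifnot(rtol > 0, atol > 0, dt > 0, hmax > 0, t_limit > 0)
  structure(list(rtol = rtol, atol = atol, dt = dt, hmax = hmax,
                 t_limit = t_limit),
            class = "solver_config")
}

#' Rectangular current-pulse specification
#'
#' @param onset pulse onset time, s (relative to the start of the recorded
#'   window in [pulse_protocol()]).
#' @param duration pulse duration, s.
#' @param amplitude signed pulse amplitude, nA; hyperpolarizing pulses are
#'   negative.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(onset = 1, duration = 0.03, amplitude = -0.1) {
  stopifnot(duration > 0)
  structure(list(onset = onset, duration = duration, amplitude = amplitude),
            class = "pulse_spec")
}

new_trace <- function(df, params, solver, protocol = "integrate") {
  tibble::new_tibble(df, params = params, solver = solver,
                     protocol = protocol, class = "bw_trace")
}

assert_trace_ok <- function(trace) {
  if (!all(is.finite(trace$V)))
    stop("integration produced non-finite state; last valid time ",
         format(max(trace$time[is.finite(trace$V)])), " s")
  invisible(trace)
}

#' Integrate the single-neuron model
#'
#' Solves the four-dimensional membrane model with the compiled
#' right-hand side and an adaptive integrator.
#'
#' @param params a [neuron_params()].
#' @param state0 initial [neuron_state()].
#' @param t_span total integration time, s (output from 0 to `t_span`).
#' @param solver a [solver_config()].
#' @param pulse optional [pulse_spec()] applied as an additive injected
#'   current.
#' @param freeze_mK2 if `TRUE`, the slow gate is held constant (used for
#'   fast-subsystem analysis).
#' @return A `bw_trace` tibble with columns `time`, `V`, `h_Na`, `m_K2`,
#'   `m_h`.
#' @export
integrate_neuron <- function(params, state0 = neuron_state(),
                             t_span = 100, solver = solver_config(),
                             pulse = NULL, freeze_mK2 = FALSE) {
  stopifnot(inherits(params, "neuron_params"), all(is.finite(state0)))
  run_piece <- function(y, times) {
    deSolve::ode(
      y = y, times = times, func = "bw_neuron_derivs",
      parms = pack_neuron_parms(params, pulse, freeze_mK2),
      dllname = "burstwave", initfunc = "bw_neuron_init",
      method = "lsoda", rtol = solver$rtol, atol = solver$atol,
      hmax = solver$hmax, maxsteps = 1e6)
  }
  grid <- seq(0, t_span, by = solver$dt)
  ## restart the integrator at the pulse edges so the adaptive stepper
  ## cannot stride across a brief rectangular pulse
  brk <- if (!is.null(pulse))
    c(pulse$onset, pulse$onset + pulse$duration) else numeric()
  brk <- brk[brk > 0 & brk < t_span]
  edges <- c(0, brk, t_span)
  pieces <- list()
  y <- state0
  for (k in seq_len(length(edges) - 1)) {
    tt <- unique(c(edges[k], grid[grid > edges[k] & grid < edges[k + 1]],
                   edges[k + 1]))
    ## nudge the first interior evaluation inside the pulse window
    out <- run_piece(y, tt)
    y <- out[nrow(out), -1]
    keep <- if (k < length(edges) - 1) -nrow(out) else TRUE
    pieces[[k]] <- out[keep, , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  df <- tibble::as_tibble(as.data.frame(out))
  names(df) <- c("time", "V", "h_Na", "m_K2", "m_h")
  assert_trace_ok(new_trace(df, params, solver,
                            if (is.null(pulse)) "integrate" else "pulse"))
}

#' Integrate past the transient and record the attractor
#'
#' Runs the model for `t_transient` seconds, discards that window, and
#' returns the following `t_record` seconds re-based to time zero.
#'
#' @inheritParams integrate_neuron
#' @param t_transient discarded settling time, s.
#' @param t_record recorded time, s.
#' @return A `bw_trace` tibble; the discarded interval is stored in the
#'   `t_transient` attribute.
#' @export
run_to_attractor <- function(params, state0 = neuron_state(),
                             t_transient = 200, t_record = 100,
                             solver = solver_config()) {
  stopifnot(t_transient > 0, t_record > 0)
  full <- integrate_neuron(params, state0, t_transient + t_record, solver)
  rec <- full[full$time >= t_transient, ]
  rec$time <- rec$time - rec$time[1]
  out <- new_trace(rec, params, solver, "run_to_attractor")
  attr(out, "t_transient") <- t_transient
  out
}

## last row of a trace as a state vector
trace_end_state <- function(trace) {
  n <- nrow(trace)
  neuron_state(V = trace$V[n], h_Na = trace$h_Na[n],
               m_K2 = pmin(pmax(trace$m_K2[n], 0), 1),
               m_h = pmin(pmax(trace$m_h[n], 0), 1))
}

## rest state found by settling; NULL if the cell fires during the check
settle_to_rest <- function(params, solver, t_settle = 200) {
  tr <- integrate_neuron(params, neuron_state(V = -0.0425, h_Na = 1,
                                              m_K2 = 0.01, m_h = 0.2),
                         t_settle, solver)
  y <- trace_end_state(tr)
  if (max(abs(neuron_rhs(y, params))) > 1e-6) return(NULL)
  y
}

#' Pulse-response protocol
#'
#' Settles the model onto its attracting regime (rest for `regime =
#' "silent"`, the periodic spiking orbit for `regime = "spiking"`), applies
#' a rectangular current pulse, and records until the model has returned to
#' the attractor (rest: `||rhs|| < 1e-8` sustained for 5 s; spiking: five
#' consecutive interspike intervals within 0.1 % of the attractor period)
#' or until the solver's hard time limit.
#'
#' In the spiking regime the pulse onset is locked to a spike peak plus
#' half the interspike interval, a phase at which a brief hyperpolarizing
#' pulse reliably dislodges the orbit; the lock keeps latencies
#' reproducible.
#'
#' @inheritParams integrate_neuron
#' @param regime `"silent"` or `"spiking"`: which attractor the parameters
#'   are expected to support.
#' @param pulse a [pulse_spec()]; `pulse$onset` is the delay from the start
#'   of the recorded window (silent regime) or from the phase-locking spike
#'   (spiking regime).
#' @param t_settle settling time before the recorded window, s.
#' @return A `bw_trace` tibble covering the recorded window (pulse onset at
#'   `attr(trace, "pulse")$onset`); `attr(trace, "returned")` reports
#'   whether the attractor was reached again.
#' @export
pulse_protocol <- function(params, regime = c("silent", "spiking"),
                           pulse = pulse_spec(), solver = solver_config(),
                           t_settle = 200) {
  regime <- match.arg(regime)
  if (regime == "silent") {
    y <- settle_to_rest(params, solver, t_settle)
    if (is.null(y))
      stop("parameters do not settle to rest; is this the silent regime?")
    ponset <- pulse$onset
  } else {
    tr <- run_to_attractor(params, neuron_state(V = 0, h_Na = 0.8,
                                                m_K2 = 0.1, m_h = 0),
                           t_transient = t_settle, t_record = 50,
                           solver = solver)
    sp <- detect_spikes(tr)
    if (nrow(sp) < 6) stop("no periodic spiking found; check parameters")
    y <- trace_end_state(tr)
    ## lock the pulse to a spike peak plus half the spiking period:
    ## mid-interspike pulses reliably dislodge the orbit onto the slow
    ## equilibrium manifold, and the lock keeps latencies reproducible
    period <- stats::median(diff(sp$time))
    tail_gap <- max(tr$time) - max(sp$time)
    ponset <- (period - tail_gap) + 0.5 * period
  }
  run_pulse <- pulse_spec(onset = ponset, duration = pulse$duration,
                          amplitude = pulse$amplitude)
  t_chunk <- 100
  total <- 0
  pieces <- list()
  state <- y
  returned <- FALSE
  ref_period <- if (regime == "spiking") period else NA_real_
  while (total < solver$t_limit && !returned) {
    pu <- if (total == 0) run_pulse else NULL
    tr <- integrate_neuron(params, state, t_chunk, solver, pulse = pu)
    tr$time <- tr$time + total
    state <- trace_end_state(tr)
    pieces[[length(pieces) + 1L]] <- tr
    total <- total + t_chunk
    if (regime == "silent") {
      ## returned to rest: flat, quiescent tail of >= 5 s
      tail5 <- tr[tr$time > max(tr$time) - 5, ]
      if (max(abs(neuron_rhs(trace_end_state(tr), params))) < 1e-8 &&
          max(tail5$V) < -0.02 && diff(range(tail5$V)) < 1e-6)
        returned <- TRUE
    } else {
      sp <- detect_spikes(tr)
      isi <- diff(sp$time)
      if (length(isi) >= 5 &&
          all(abs(utils::tail(isi, 5) / ref_period - 1) < 1e-3))
        returned <- TRUE
    }
  }
  df <- dplyr::bind_rows(pieces)
  out <- new_trace(df, params, solver, paste0("pulse_", regime))
  attr(out, "pulse") <- run_pulse
  attr(out, "returned") <- returned
  attr(out, "ref_period") <- ref_period
  out
}
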