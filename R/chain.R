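#' Inhibitory synapse specification
#'
#' First-order graded inhibitory synapse: the presynaptic activation `s`
#' relaxes to a steep sigmoid of presynaptic voltage,
#' `s_inf(V) = 1 / (1 + exp(-slope (V - threshold)))`, with time constant
#' `tau`; the postsynaptic current is `w s (V_post - E_syn)`.
#'
#' @param E_syn synaptic reversal potential, V.
#' @param slope activation slope, 1/V.
#' @param threshold activation threshold, V.
#' @param tau activation time constant, s.
#' @return An object of class `synapse_spec`.
#' @export
synapse_spec <- function(E_syn = -0.0625, slope = 1000,
                         threshold = -0.0305, tau = 0.02) {
  stopifnot(tau > 0, slope > 0)
  structure(list(E_syn = E_syn, slope = slope, threshold = threshold,
                 tau = tau), class = "synapse_spec")
}

#' Build an inhibitory chain of bursting neurons
#'
#' Cells are numbered by body segment, anterior to posterior (default
#' segments 3 to 7).  Synaptic weights follow a posterior-dominant
#' scheme: cell `i` receives input `g_post * rho^(j - i - 1)` from every
#' posterior cell `j > i` (so its nearest posterior neighbor is the
#' strongest input) and a weak input `ant_frac * g_post` from its
#' immediate anterior neighbor.  A custom weight matrix may be supplied
#' instead; it must satisfy the same ordering invariants.
#'
#' @param params shared [neuron_params()] of every cell.
#' @param segments integer cell labels, anterior to posterior.
#' @param g_post strongest posterior coupling conductance, nS.
#' @param rho geometric decay of posterior inputs with distance.
#' @param ant_frac anterior weight as a fraction of `g_post`; must stay
#'   below the weakest posterior input.
#' @param weights optional custom weight matrix `w[i, j]` (from cell j
#'   onto cell i, nS), overriding the scheme.
#' @param synapse a [synapse_spec()].
#' @return An object of class `chain_spec`.
#' @export
build_chain <- function(params = neuron_params(), segments = 3:7,
                        g_post = 5, rho = 0.5, ant_frac = 0.02,
                        weights = NULL, synapse = synapse_spec()) {
  n <- length(segments)
  stopifnot(n >= 2, inherits(params, "neuron_params"),
            inherits(synapse, "synapse_spec"))
  if (is.null(weights)) {
    weights <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j > i) weights[i, j] <- g_post * rho^(j - i - 1)
        if (j == i - 1) weights[i, j] <- ant_frac * g_post
      }
    }
  }
  stopifnot(is.matrix(weights), nrow(weights) == n, ncol(weights) == n)
  if (any(weights < 0)) stop("synaptic weights must be nonnegative")
  if (any(diag(weights) != 0)) stop("self-coupling is not allowed")
  for (i in seq_len(n)) {
    post <- weights[i, seq_len(n) > i]
    if (length(post) > 0 && any(post > 0)) {
      if (weights[i, i + 1] < max(weights[i, ]))
        stop("nearest posterior input must be the strongest onto cell ",
             segments[i])
      if (i > 1 && weights[i, i - 1] >= min(post[post > 0]))
        stop("anterior input must be weaker than every posterior input ",
             "onto cell ", segments[i])
    }
  }
  structure(list(params = params, segments = segments, weights = weights,
                 synapse = synapse), class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat("<chain_spec>", length(x$segments), "cells (segments",
      paste(range(x$segments), collapse = ".."), ") | max weight",
      max(x$weights), "nS, E_syn", x$synapse$E_syn, "V\n")
  invisible(x)
}

pack_chain_parms <- function(chain) {
  n <- length(chain$segments)
  nmax <- 16L  # fixed block size expected by the compiled model
  if (n > nmax) stop("at most ", nmax, " cells are supported")
  p <- chain$params
  s <- chain$synapse
  base <- c(n,
            p$theta_K2, p$theta_h, p$I_pol, p$tau_mh, p$tau_K2,
            p$tau_hNa, p$C, p$g_Na, p$g_K2, p$g_h, p$g_leak,
            p$E_Na, p$E_K, p$E_h, p$E_leak,
            s$E_syn, s$slope, s$threshold, s$tau)
  w <- matrix(0, nmax, nmax)
  w[seq_len(n), seq_len(n)] <- chain$weights
  ## w[i*nmax + j] (0-based) = weights[i+1, j+1]: row-major by target cell
  c(base, as.numeric(t(w)))
}

#' Near-synchronous initial conditions for a chain
#'
#' Every cell starts at the state of the single-cell bursting attractor
#' at the voltage minimum between the second and third spike of a burst;
#' odd-numbered segments are then perturbed in voltage by `perturbation`
#' volts to break exact synchrony.
#'
#' @param chain a [build_chain()].
#' @param solver a [solver_config()].
#' @param perturbation voltage perturbation of odd segments, V.
#' @param t_transient settling time for the reference attractor, s.
#' @return A list: `states` (matrix, one row per cell: V, h_Na, m_K2,
#'   m_h, s), `reference` (the single-cell trace used), `period` and
#'   `stats` of the reference attractor.
#' @export
make_initial_conditions <- function(chain, solver = solver_config(),
                                    perturbation = 1e-4,
                                    t_transient = 100) {
  tr <- run_to_attractor(chain$params, rest_like_state(), t_transient,
                         t_record = 120, solver)
  st <- trace_stats(tr)
  if (!st$available) stop("single-cell attractor is not bursting")
  sp <- detect_spikes(tr)
  seg <- segment_bursts(sp, record_start = min(tr$time),
                        record_end = max(tr$time))
  seg <- seg[seg$complete & seg$n_spikes >= 3, ]
  if (nrow(seg) == 0) stop("no complete burst with at least 3 spikes")
  b <- seg[1, ]
  burst_spikes <- sp$time[sp$time >= b$t_first & sp$time <= b$t_last]
  w <- tr$time > burst_spikes[2] & tr$time < burst_spikes[3]
  idx <- which(w)[which.min(tr$V[w])]
  y0 <- c(V = tr$V[idx], h_Na = tr$h_Na[idx], m_K2 = tr$m_K2[idx],
          m_h = tr$m_h[idx])
  sinf <- 1 / (1 + exp(-chain$synapse$slope *
                       (y0[["V"]] - chain$synapse$threshold)))
  n <- length(chain$segments)
  states <- matrix(rep(c(y0, s = sinf), n), nrow = n, byrow = TRUE,
                   dimnames = list(chain$segments,
                                   c("V", "h_Na", "m_K2", "m_h", "s")))
  odd <- chain$segments %% 2 == 1
  states[odd, "V"] <- states[odd, "V"] + perturbation
  list(states = states, reference = tr, period = st$period, stats = st)
}

#' Integrate a chain network
#'
#' @param chain a [build_chain()].
#' @param states0 initial state matrix (one row per cell: V, h_Na,
#'   m_K2, m_h, s), e.g. from [make_initial_conditions()].
#' @param t_span integration time, s.
#' @param solver a [solver_config()].
#' @return A long tibble: `time`, `segment`, `V`, `h_Na`, `m_K2`, `m_h`,
#'   `s`.
#' @export
integrate_chain <- function(chain, states0, t_span,
                            solver = solver_config()) {
  n <- length(chain$segments)
  stopifnot(is.matrix(states0), nrow(states0) == n, ncol(states0) == 5)
  y0 <- as.numeric(t(states0))
  times <- seq(0, t_span, by = solver$dt)
  out <- deSolve::ode(
    y = y0, times = times, func = "bw_chain_derivs",
    parms = pack_chain_parms(chain), dllname = "burstwave",
    initfunc = "bw_chain_init", method = "lsoda",
    rtol = solver$rtol, atol = solver$atol, hmax = solver$hmax,
    maxsteps = 1e6)
  vars <- c("V", "h_Na", "m_K2", "m_h", "s")
  df <- purrr::map(seq_len(n), function(i) {
    cols <- 1 + (i - 1) * 5 + seq_len(5)
    d <- tibble::as_tibble(as.data.frame(out[, c(1, cols)]))
    names(d) <- c("time", vars)
    d$segment <- chain$segments[i]
    d
  })
  df <- dplyr::bind_rows(df)[, c("time", "segment", vars)]
  if (!all(is.finite(df$V))) stop("network integration blew up")
  df
}

#' Run a metachronal-wave experiment
#'
#' Builds near-synchronous initial conditions, integrates the chain for
#' `n_cycles` of the single-cell period, and summarizes the wave.
#'
#' @param chain a [build_chain()].
#' @param n_cycles recorded duration in single-cell periods.
#' @param solver a [solver_config()].
#' @param perturbation forwarded to [make_initial_conditions()].
#' @return A list of class `wave_experiment`: `wave` ([wave_stats()]),
#'   `trace` (the long network tibble), `cell_period`, `cell_stats` (the
#'   isolated reference cell), `chain`.
#' @export
run_metachronal_experiment <- function(chain, n_cycles = 10,
                                       solver = solver_config(),
                                       perturbation = 1e-4) {
  ic <- make_initial_conditions(chain, solver, perturbation)
  t_span <- ic$period * (n_cycles + 0.5)
  tr <- integrate_chain(chain, ic$states, t_span, solver)
  trains <- lapply(split(tr[, c("time", "V")], tr$segment),
                   detect_spikes)
  ## order anterior -> posterior (split() sorts labels numerically here)
  ord <- as.character(chain$segments)
  trains <- trains[ord]
  ws <- wave_stats(trains, reference = length(trains))
  structure(list(wave = ws, trace = tr, cell_period = ic$period,
                 cell_stats = ic$stats, chain = chain),
            class = "wave_experiment")
}

#' @export
print.wave_experiment <- function(x, ...) {
  print(x$wave)
  cat(sprintf("  isolated cell period %.3f s (network/cell diff %.3f%%)\n",
              x$cell_period,
              100 * abs(x$wave$period - x$cell_period) / x$cell_period))
  invisible(x)
}

#' Pattern-scaling sweep over a coregulation path
#'
#' Runs one metachronal-wave experiment per parameter pair and collects
#' period, duty-cycle and phase summaries, together with the isolated
#' single-cell statistics at the same parameters.
#'
#' @param path a data frame with columns `theta_K2` and `theta_h` (e.g.
#'   a [find_duty_isoline()] result or [coregulation_reference()]).
#' @param params_base template [neuron_params()].
#' @param n_cycles,solver,... forwarded to
#'   [run_metachronal_experiment()] and [build_chain()].
#' @return A tibble, one row per instantiation: `theta_K2`, `theta_h`,
#'   `cell_period`, `cell_duty`, `network_period`, `network_duty`,
#'   `mean_phase`, `formation_cycles`, `period_diff_pct`,
#'   `spikes_per_burst`, `failed`.
#' @export
scaling_sweep <- function(path, params_base = neuron_params(),
                          n_cycles = 10, solver = solver_config(), ...) {
  rows <- purrr::pmap(path[, c("theta_K2", "theta_h")],
                      function(theta_K2, theta_h) {
    res <- tryCatch({
      p <- modify_params(params_base, theta_K2 = theta_K2,
                         theta_h = theta_h)
      ch <- build_chain(params = p, ...)
      ex <- run_metachronal_experiment(ch, n_cycles, solver)
      seg7 <- ex$wave$cells[nrow(ex$wave$cells), ]
      tibble::tibble(
        theta_K2 = theta_K2, theta_h = theta_h,
        cell_period = ex$cell_period,
        cell_duty = ex$cell_stats$duty,
        network_period = ex$wave$period,
        network_duty = seg7$duty,
        mean_phase = ex$wave$mean_phase,
        formation_cycles = ex$wave$formation_cycles,
        period_diff_pct = 100 * abs(ex$wave$period - ex$cell_period) /
          ex$cell_period,
        spikes_per_burst = ex$cell_stats$spikes_per_burst,
        failed = !ex$wave$formed)
    }, error = function(e) tibble::tibble(
      theta_K2 = theta_K2, theta_h = theta_h, cell_period = NA_real_,
      cell_duty = NA_real_, network_period = NA_real_,
      network_duty = NA_real_, mean_phase = NA_real_,
      formation_cycles = NA_integer_, period_diff_pct = NA_real_,
      spikes_per_burst = NA_real_, failed = TRUE))
    res
  })
  dplyr::bind_rows(rows)
}

#' Reference coregulation table for the ten chain instantiations
#'
#' The ten (theta_K2, theta_h) pairs of the duty-cycle-preserving
#' coregulation path used for the metachronal-wave study, with their
#' published single-cell and network periods (s) and duty cycles
#' (percent).  These pairs hold the single-cell duty cycle at 10 % while
#' the period spans roughly a five-fold range.
#'
#' @return A tibble with columns `theta_K2`, `theta_h`, `period_cell`,
#'   `period_network`, `duty_cell`, `duty_network`.
#' @export
coregulation_reference <- function() {
  tibble::tribble(
    ~theta_K2, ~theta_h, ~period_cell, ~period_network, ~duty_cell,
    ~duty_network,
     0.0059, 0.040736, 15.1, 15.1, 10.0,  9.9,
     0.0019, 0.041048, 21.0, 21.0, 10.0, 11.0,
    -0.0001, 0.041145, 27.4, 27.4,  9.9,  9.9,
    -0.0011, 0.041183, 31.8, 31.8,  9.9,  9.8,
    -0.0031, 0.041244, 39.5, 39.5, 10.0, 10.4,
    -0.0041, 0.041268, 48.0, 48.0, 10.0,  9.9,
    -0.0057, 0.041298, 61.8, 61.8, 10.0, 10.3,
    -0.0061, 0.041306, 68.2, 68.1, 10.0, 10.3,
    -0.0069, 0.041318, 82.3, 82.1, 10.0, 10.0,
    -0.0070, 0.041319, 85.3, 85.1,  9.9,  9.9)
}
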