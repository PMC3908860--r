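#' Gate specification
#'
#' Describes one Boltzmann-type gating variable of the membrane model: its
#' steady-state activation curve, its kinetics and the power with which it
#' enters the current.  The steady state is
#' \deqn{x_\infty(V) = \frac{1}{1 + e^{-o\,k\,(V + \theta)}}}
#' with slope \eqn{k > 0} (1/V), half-activation offset \eqn{\theta} (V) and
#' orientation \eqn{o = +1} (activates with depolarization) or \eqn{o = -1}
#' (activates with hyperpolarization).  The hyperpolarization-activated gate
#' of the default model uses a double-exponential steady state instead (see
#' `form = "double_exp"`), with the same midpoint-offset convention.
#'
#' @param slope positive slope of the Boltzmann exponent, 1/V.
#' @param half_offset offset \eqn{\theta} added to V inside the exponent, V.
#' @param power integer power (1, 2 or 3) of the gate in its current.
#' @param tau time constant in seconds (a single positive number), or `NA`
#'   for an instantaneous gate.
#' @param orientation `+1` or `-1`.
#' @param form `"boltzmann"` (default) or `"double_exp"` for the
#'   hyperpolarization-activated steady state
#'   \eqn{1 / (1 + 2 e^{180 (V+\theta)} + e^{500 (V+\theta)})}.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(slope, half_offset, power = 1L, tau = NA_real_,
                      orientation = 1L, form = c("boltzmann", "double_exp")) {
  form <- match.arg(form)
  stopifnot(is.numeric(slope), length(slope) == 1L, slope > 0,
            is.numeric(half_offset), length(half_offset) == 1L,
            power %in% 1:3,
            is.na(tau) || tau > 0,
            orientation %in% c(-1L, 1L))
  structure(
    list(slope = as.numeric(slope), half_offset = as.numeric(half_offset),
         power = as.integer(power), tau = as.numeric(tau),
         orientation = as.integer(orientation), form = form),
    class = "gate_spec")
}

#' Steady-state activation of a gate
#'
#' @param V membrane voltage, V (vectorized).
#' @param spec a [gate_spec()].
#' @return Activation in (0, 1), same length as `V`.
#' @examples
#' sp <- gate_spec(slope = 83, half_offset = 0.0075)
#' gate_steady_state(-0.0075, sp)  # midpoint: 0.5
#' @export
gate_steady_state <- function(V, spec) {
  stopifnot(inherits(spec, "gate_spec"))
  x <- V + spec$half_offset
  if (spec$form == "double_exp") {
    1 / (1 + 2 * exp(180 * x) + exp(500 * x))
  } else {
    1 / (1 + exp(-spec$orientation * spec$slope * x))
  }
}

#' Biophysical parameter set of the bursting neuron
#'
#' Builds the full parameterization of the four-dimensional membrane model:
#' a fast sodium current \eqn{I_{Na}} with instantaneous cubic activation and
#' inactivation gate \eqn{h_{Na}}, a slow non-inactivating potassium current
#' \eqn{I_{K2}} with squared activation \eqn{m_{K2}} (the slow variable, time
#' constant 2 s), a hyperpolarization-activated current \eqn{I_h} with
#' squared activation \eqn{m_h}, an ohmic leak, and a constant polarizing
#' current.  The two half-activation voltages `theta_K2` and `theta_h` are
#' the regulated (bifurcation) parameters; they enter the gate exponents as
#' `V + theta`.
#'
#' The voltage equation is
#' \deqn{C \dot V = -I_{Na} - I_{K2} - I_h - I_{leak} + I_{pol} + I_{ext}.}
#'
#' @param theta_K2 half-activation offset of the slow potassium gate, V.
#' @param theta_h half-activation offset of the hyperpolarization-activated
#'   gate, V.
#' @param g_Na,g_K2,g_h,g_leak maximal conductances, nS.
#' @param E_Na,E_K,E_h,E_leak reversal potentials, V.
#' @param C membrane capacitance, nF.
#' @param I_pol constant polarizing current, nA.
#' @param tau_mh time constant of the hyperpolarization-activated gate, s.
#' @param tau_K2 time constant of the slow potassium gate, s.
#' @param tau_hNa time constant of sodium inactivation, s.
#' @return An object of class `neuron_params`: a validated list with the
#'   numeric constants and a `gates` sub-list of [gate_spec()] objects
#'   (`m_Na`, `h_Na`, `m_K2`, `m_h`).
#' @export
neuron_params <- function(theta_K2 = -0.0075, theta_h = 0.038,
                          g_Na = 105, g_K2 = 30, g_h = 4, g_leak = 8,
                          E_Na = 0.045, E_K = -0.07, E_h = -0.021,
                          E_leak = -0.046, C = 0.5, I_pol = -0.006,
                          tau_mh = 0.12, tau_K2 = 2, tau_hNa = 0.0405) {
  stopifnot(g_Na >= 0, g_K2 >= 0, g_h >= 0, g_leak >= 0, C > 0,
            tau_mh > 0, tau_K2 > 0, tau_hNa > 0)
  if (!(E_K < E_leak && E_leak < E_h && E_h < E_Na))
    stop("reversal potentials must be ordered E_K < E_leak < E_h < E_Na")
  p <- list(
    theta_K2 = theta_K2, theta_h = theta_h,
    g_Na = g_Na, g_K2 = g_K2, g_h = g_h, g_leak = g_leak,
    E_Na = E_Na, E_K = E_K, E_h = E_h, E_leak = E_leak,
    C = C, I_pol = I_pol,
    tau_mh = tau_mh, tau_K2 = tau_K2, tau_hNa = tau_hNa,
    gates = list(
      m_Na = gate_spec(150, 0.0305, power = 3L, tau = NA, orientation = 1L),
      h_Na = gate_spec(500, 0.0325, power = 1L, tau = tau_hNa,
                       orientation = -1L),
      m_K2 = gate_spec(83, theta_K2, power = 2L, tau = tau_K2,
                       orientation = 1L),
      m_h  = gate_spec(180, theta_h, power = 2L, tau = tau_mh,
                       orientation = -1L, form = "double_exp")))
  class(p) <- "neuron_params"
  p
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>  theta_K2 =", format(x$theta_K2),
      "V, theta_h =", format(x$theta_h), "V\n")
  cat("  g (nS): Na", x$g_Na, " K2", x$g_K2, " h", x$g_h, " leak", x$g_leak,
      " | C =", x$C, "nF, I_pol =", x$I_pol, "nA\n")
  invisible(x)
}

#' Neuron state constructor
#'
#' @param V membrane voltage, V.
#' @param h_Na,m_K2,m_h gate values in `[0, 1]`.
#' @return Named numeric vector of length 4.
#' @export
neuron_state <- function(V = -0.045, h_Na = 0.99, m_K2 = 0.05, m_h = 0.1) {
  g <- c(h_Na, m_K2, m_h)
  if (any(g < -1e-9 | g > 1 + 1e-9))
    stop("gate values must lie in [0, 1]")
  c(V = V, h_Na = h_Na, m_K2 = m_K2, m_h = m_h)
}

all_gate_inf <- function(V, params) {
  c(m_Na = gate_steady_state(V, params$gates$m_Na),
    h_Na = gate_steady_state(V, params$gates$h_Na),
    m_K2 = gate_steady_state(V, params$gates$m_K2),
    m_h  = gate_steady_state(V, params$gates$m_h))
}

#' Instantaneous ionic currents
#'
#' Evaluates every membrane current at a given state, together with the
#' resulting voltage derivative.
#'
#' @param state a [neuron_state()] (named numeric vector).
#' @param params a [neuron_params()].
#' @param I_ext external injected current, nA.
#' @return A one-row tibble with columns `I_Na`, `I_K2`, `I_h`, `I_leak`,
#'   `I_ext` (nA) and `dVdt` (V/s), where
#'   `dVdt = (-I_Na - I_K2 - I_h - I_leak + I_pol + I_ext) / C`.
#' @export
ionic_currents <- function(state, params, I_ext = 0) {
  V <- state[["V"]]
  m_Na <- gate_steady_state(V, params$gates$m_Na)
  I_Na <- params$g_Na * m_Na^3 * state[["h_Na"]] * (V - params$E_Na)
  I_K2 <- params$g_K2 * state[["m_K2"]]^2 * (V - params$E_K)
  I_h  <- params$g_h * state[["m_h"]]^2 * (V - params$E_h)
  I_leak <- params$g_leak * (V - params$E_leak)
  tibble::tibble(
    I_Na = I_Na, I_K2 = I_K2, I_h = I_h, I_leak = I_leak, I_ext = I_ext,
    dVdt = (-I_Na - I_K2 - I_h - I_leak + params$I_pol + I_ext) / params$C)
}

#' Vector field of the single neuron
#'
#' Pure-R reference implementation of the model's right-hand side (the
#' compiled version in `src/` is used for integration; this one backs
#' equilibrium analysis and tests).
#'
#' @inheritParams ionic_currents
#' @return Named numeric vector `(V, h_Na, m_K2, m_h)` of time derivatives.
#' @export
neuron_rhs <- function(state, params, I_ext = 0) {
  if (!all(is.finite(state))) stop("non-finite state (integration blow-up?)")
  V <- state[["V"]]
  cur <- ionic_currents(state, params, I_ext)
  inf <- all_gate_inf(V, params)
  c(V = cur$dVdt,
    h_Na = (inf[["h_Na"]] - state[["h_Na"]]) / params$tau_hNa,
    m_K2 = (inf[["m_K2"]] - state[["m_K2"]]) / params$tau_K2,
    m_h  = (inf[["m_h"]] - state[["m_h"]]) / params$tau_mh)
}

#' Total membrane current on the equilibrium manifold
#'
#' Collapses the model onto the manifold where every gate sits at its
#' steady state for the instantaneous voltage, and returns the net voltage
#' drive `C * dV/dt` there (nA).  Zeros of this function are equilibria of
#' the full system; a simultaneous zero of its V-derivative marks a
#' saddle-node bifurcation for equilibria.
#'
#' @param V membrane voltage, V (vectorized).
#' @param params a [neuron_params()].
#' @return Net current, nA (positive depolarizes).
#' @export
steady_state_current <- function(V, params) {
  m_Na <- gate_steady_state(V, params$gates$m_Na)
  h_Na <- gate_steady_state(V, params$gates$h_Na)
  m_K2 <- gate_steady_state(V, params$gates$m_K2)
  m_h  <- gate_steady_state(V, params$gates$m_h)
  -(params$g_Na * m_Na^3 * h_Na * (V - params$E_Na) +
    params$g_K2 * m_K2^2 * (V - params$E_K) +
    params$g_h * m_h^2 * (V - params$E_h) +
    params$g_leak * (V - params$E_leak)) + params$I_pol
}

## packed parameter vector for the compiled right-hand side
pack_neuron_parms <- function(params, pulse = NULL, freeze_mK2 = FALSE) {
  pu <- if (is.null(pulse)) c(1e300, 1e300, 0)
        else c(pulse$onset, pulse$onset + pulse$duration, pulse$amplitude)
  c(params$theta_K2, params$theta_h, params$I_pol, params$tau_mh,
    params$tau_K2, params$tau_hNa, params$C,
    params$g_Na, params$g_K2, params$g_h, params$g_leak,
    params$E_Na, params$E_K, params$E_h, params$E_leak,
    pu, as.numeric(freeze_mK2))
}
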