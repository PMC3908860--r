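## Slow-fast decomposition: the slow potassium activation m_K2 is treated
## as a parameter of the fast subsystem (V, h_Na, m_h); manifolds of slow
## motion are its equilibria and limit cycles, and full-system saddle-node
## bifurcations are located from them (orbit averaging) or from the full
## dynamics directly.

## net fast-subsystem current with m_K2 frozen and the other gates at
## steady state (equilibria of the fast subsystem satisfy this = 0)
fast_current <- function(V, m_K2, params) {
  m_Na <- gate_steady_state(V, params$gates$m_Na)
  h_Na <- gate_steady_state(V, params$gates$h_Na)
  m_h <- gate_steady_state(V, params$gates$m_h)
  -(params$g_Na * m_Na^3 * h_Na * (V - params$E_Na) +
    params$g_K2 * m_K2^2 * (V - params$E_K) +
    params$g_h * m_h^2 * (V - params$E_h) +
    params$g_leak * (V - params$E_leak)) + params$I_pol
}

## roots of f on a grid-bracketed scan, refined by uniroot
scan_roots <- function(f, lower, upper, n = 2000, tol = 1e-13) {
  v <- seq(lower, upper, length.out = n)
  fv <- vapply(v, f, 1)
  i <- which(fv[-n] * fv[-1] <= 0 & fv[-n] != 0)
  vapply(i, function(k)
    stats::uniroot(f, c(v[k], v[k + 1]), tol = tol)$root, 1)
}

## eigenvalues of the 3-D fast subsystem at an equilibrium
fast_jacobian_eigs <- function(V, m_K2, params) {
  rhs3 <- function(y) {
    st <- c(V = y[1], h_Na = y[2], m_K2 = m_K2, m_h = y[3])
    full <- neuron_rhs(st, params)
    full[c("V", "h_Na", "m_h")]
  }
  hstep <- 1e-8
  mh <- gate_steady_state(V, params$gates$m_h)
  hNa <- gate_steady_state(V, params$gates$h_Na)
  y0 <- c(V, hNa, mh)
  f0 <- rhs3(y0)
  J <- vapply(1:3, function(j) {
    y <- y0; y[j] <- y[j] + hstep
    (rhs3(y) - f0) / hstep
  }, numeric(3))
  eigen(J, only.values = TRUE)$values
}

#' Equilibrium branch of the fast subsystem
#'
#' With the slow gate frozen at each value of `m_K2`, finds every
#' equilibrium voltage of the fast subsystem (current balance with
#' `h_Na` and `m_h` at steady state), its stability, and the fold values
#' of `m_K2` where the number of equilibria changes.
#'
#' @param params a [neuron_params()].
#' @param m_K2 vector of slow-gate values in `[0, 1]` (treated as the
#'   branch parameter).
#' @param V_window voltage window scanned for roots, V.
#' @return A list of class `fast_branch`: tibble `points` (`m_K2`, `V`,
#'   `stable`), and tibble `folds` (`m_K2` refined to ~1e-10, `V`).
#' @export
fast_equilibria <- function(params, m_K2 = seq(0, 0.5, length.out = 201),
                            V_window = c(-0.07, 0.02)) {
  stopifnot(all(m_K2 >= 0 & m_K2 <= 1))
  roots_at <- function(m) scan_roots(function(V) fast_current(V, m, params),
                                     V_window[1], V_window[2])
  pts <- purrr::map(m_K2, function(m) {
    V <- roots_at(m)
    if (length(V) == 0) return(NULL)
    stable <- vapply(V, function(v)
      all(Re(fast_jacobian_eigs(v, m, params)) < 0), TRUE)
    tibble::tibble(m_K2 = m, V = V, stable = stable)
  })
  points <- dplyr::bind_rows(pts)
  counts <- vapply(m_K2, function(m)
    length(points$V[points$m_K2 == m]), 1L)
  folds <- list()
  for (k in seq_along(m_K2)[-1]) {
    if (counts[k] != counts[k - 1]) {
      lo <- m_K2[k - 1]; hi <- m_K2[k]; nlo <- counts[k - 1]
      for (i in 1:40) {
        mid <- (lo + hi) / 2
        if (length(roots_at(mid)) == nlo) lo <- mid else hi <- mid
      }
      mf <- (lo + hi) / 2
      Vs <- roots_at(mf)
      dV <- if (length(Vs) >= 2) Vs[which.min(abs(diff(Vs)))] else Vs[1]
      folds[[length(folds) + 1L]] <- tibble::tibble(m_K2 = mf, V = dV)
    }
  }
  structure(list(points = points,
                 folds = dplyr::bind_rows(folds)),
            class = "fast_branch")
}

#' Limit cycle of the fast subsystem at a frozen slow-gate value
#'
#' Settles the three-dimensional fast subsystem onto its spiking limit
#' cycle and returns exactly one period, sampled densely, delimited by a
#' Poincare section (`V = section`, upward).
#'
#' @param params a [neuron_params()].
#' @param m_K2 frozen slow-gate value.
#' @param solver a [solver_config()]; the orbit is sampled at `dt / 10`.
#' @param t_settle settling time before sections are collected, s.
#' @param section section voltage, V.
#' @return A list of class `fast_orbit`: `m_K2`, `period` (s), tibble
#'   `samples` (`time`, `V`, `h_Na`, `m_h` over one period), `V_max`,
#'   `V_min`, `closure` (state mismatch across the period), or `NULL`
#'   (with attribute) if the subsystem does not oscillate.
#' @export
fast_orbit <- function(params, m_K2, solver = solver_config(),
                       t_settle = 30, section = -0.03) {
  dt <- solver$dt / 10
  y0 <- neuron_state(V = 0, h_Na = 0.8, m_K2 = m_K2, m_h = 0)
  tr <- integrate_neuron(params, y0, t_settle, solver, freeze_mK2 = TRUE)
  y1 <- trace_end_state(tr)
  fine <- solver_config(rtol = solver$rtol, atol = solver$atol, dt = dt,
                        hmax = solver$hmax, t_limit = solver$t_limit)
  tr2 <- integrate_neuron(params, y1, 5, fine, freeze_mK2 = TRUE)
  V <- tr2$V; t <- tr2$time; n <- length(V)
  up <- which(V[-n] < section & V[-1] >= section)
  if (length(up) < 3) return(NULL)  # non-oscillatory: branch endpoint
  i0 <- up[length(up) - 1L]; i1 <- up[length(up)]
  frac0 <- (section - V[i0]) / (V[i0 + 1] - V[i0])
  frac1 <- (section - V[i1]) / (V[i1 + 1] - V[i1])
  t0 <- t[i0] + frac0 * dt; t1 <- t[i1] + frac1 * dt
  ## one period of samples, with interpolated endpoints at the section
  at <- function(x, tc) stats::approx(t, x, tc)$y
  inner <- tr2[t > t0 & t < t1, c("time", "V", "h_Na", "m_h")]
  ends <- tibble::tibble(
    time = c(t0, t1),
    V = c(section, section),
    h_Na = at(tr2$h_Na, c(t0, t1)),
    m_h = at(tr2$m_h, c(t0, t1)))
  seg <- dplyr::bind_rows(ends[1, ], inner, ends[2, ])
  seg$time <- seg$time - t0
  ## state mismatch across one period, at the interpolated section times
  closure <- max(abs(c(ends$h_Na[1] - ends$h_Na[2],
                       ends$m_h[1] - ends$m_h[2])))
  structure(list(m_K2 = m_K2, period = t1 - t0, samples = seg,
                 V_max = max(seg$V), V_min = min(seg$V),
                 closure = closure),
            class = "fast_orbit")
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                       utils::tail(y, -1)) / 2)

#' Orbit averages over one period
#'
#' Time averages of the voltage and of the slow gate's steady-state curve
#' along one fast-subsystem limit cycle, by the trapezoidal rule.  The
#' averaged slow nullcline value determines the slow drift: the full
#' system's spiking periodic orbit sits where the averaged steady state
#' equals the frozen slow-gate value.
#'
#' @param orbit a [fast_orbit()].
#' @param params a [neuron_params()] (supplies the slow gate's curve).
#' @return A named vector: `V_mean` and `mK2_inf_mean`.
#' @export
orbit_averages <- function(orbit, params) {
  s <- orbit$samples
  Tp <- orbit$period
  c(V_mean = trapz(s$time, s$V) / Tp,
    mK2_inf_mean = trapz(s$time,
                         gate_steady_state(s$V, params$gates$m_K2)) / Tp)
}

#' Saddle-node bifurcation for equilibria
#'
#' At fixed `theta_K2`, solves the fold system — steady-state membrane
#' current and its voltage derivative both zero — for the fold voltage
#' and the critical `theta_h`, by damped Newton iteration on the
#' two-equation system with a grid-scan bracket for the start.
#'
#' @param params a [neuron_params()] (its `theta_h` is ignored).
#' @param theta_K2 fixed slow-potassium half-activation, V.
#' @param theta_h_window search window for the critical value, V.
#' @param V_window voltage window containing the fold, V.
#' @param tol residual tolerance, nA (and nA/V for the derivative).
#' @return A list of class `bifurcation_point`: `type =
#'   "SN_equilibria"`, `theta_K2`, `theta_h`, `V`, `residual`.
#' @export
locate_sn_equilibria <- function(params, theta_K2 = params$theta_K2,
                                 theta_h_window = c(0.030, 0.055),
                                 V_window = c(-0.068, -0.02),
                                 tol = 1e-12) {
  F <- function(V, th) {
    p <- modify_params(params, theta_K2 = theta_K2, theta_h = th)
    steady_state_current(V, p)
  }
  dF <- function(V, th, h = 1e-7) (F(V + h, th) - F(V - h, th)) / (2 * h)
  ## bracket the fold in theta_h by the change in root count
  nroots <- function(th) {
    v <- seq(V_window[1], V_window[2], length.out = 1500)
    f <- F(v, th)
    sum(f[-1500] * f[-1] <= 0 & f[-1500] != 0)
  }
  lo <- theta_h_window[1]; hi <- theta_h_window[2]
  nlo <- nroots(lo); nhi <- nroots(hi)
  if (nlo == nhi) stop("no fold of equilibria inside theta_h_window")
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (nroots(mid) == nlo) lo <- mid else hi <- mid
  }
  th <- (lo + hi) / 2
  ## starting V: minimize |dF/dV| near the merging pair
  v <- seq(V_window[1], V_window[2], length.out = 3000)
  Va <- v[which.min(abs(dF(v, th)) + abs(F(v, th)) * 50)]
  x <- c(Va, th)
  for (it in 1:60) {
    r <- c(F(x[1], x[2]), dF(x[1], x[2]))
    if (max(abs(r)) < tol) break
    h1 <- 1e-8; h2 <- 1e-9
    J <- cbind(
      c((F(x[1] + h1, x[2]) - F(x[1] - h1, x[2])) / (2 * h1),
        (dF(x[1] + h1, x[2]) - dF(x[1] - h1, x[2])) / (2 * h1)),
      c((F(x[1], x[2] + h2) - F(x[1], x[2] - h2)) / (2 * h2),
        (dF(x[1], x[2] + h2) - dF(x[1], x[2] - h2)) / (2 * h2)))
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    ## damping to stay inside the windows
    lam <- 1
    while (lam > 1e-4 &&
           (x[1] + lam * step[1] < V_window[1] ||
            x[1] + lam * step[1] > V_window[2])) lam <- lam / 2
    x <- x + lam * step
  }
  res <- max(abs(c(F(x[1], x[2]), dF(x[1], x[2]))))
  if (res > 1e-9)
    warning("fold residual ", format(res), " above 1e-9")
  structure(list(type = "SN_equilibria", theta_K2 = theta_K2,
                 theta_h = x[2], V = x[1], residual = res),
            class = "bifurcation_point")
}

#' Saddle-node bifurcation for periodic orbits
#'
#' At fixed `theta_h`, locates the critical `theta_K2` where the tonic
#' spiking orbit of the full system disappears (the blue-sky / fold of
#' periodic orbits boundary), by either of two methods:
#' `"averaging"` — the averaged slow-nullcline value along the
#' fast-subsystem orbit branch becomes tangent to the identity (the
#' Pontryagin–Rodygin criterion); `"dynamical"` — bisection of the
#' qualitative outcome (sustained spiking versus burst termination) of
#' full-system runs continued from the spiking orbit.
#'
#' @param params a [neuron_params()] (its `theta_K2` is ignored).
#' @param theta_h fixed value, V.
#' @param method `"averaging"`, `"dynamical"`, or `"both"` (returns the
#'   averaging value and errors if the two disagree by more than
#'   `agree_tol`).
#' @param window search window for `theta_K2`, V.
#' @param m_grid slow-gate grid for the orbit branch (averaging method).
#' @param solver a [solver_config()].
#' @param tol bisection tolerance, V (dynamical method).
#' @param agree_tol maximal allowed disagreement between methods, V.
#' @return A list of class `bifurcation_point`: `type = "SN_orbits"`,
#'   `theta_K2`, `theta_h`, `method` (and `theta_K2_dynamical` when both
#'   methods run).
#' @export
locate_sn_orbits <- function(params, theta_h = params$theta_h,
                             method = c("averaging", "dynamical", "both"),
                             window = c(-0.0125, -0.0085),
                             m_grid = seq(0.05, 0.35, by = 0.02),
                             solver = solver_config(), tol = 1e-7,
                             agree_tol = 1e-4) {
  method <- match.arg(method)
  p0 <- modify_params(params, theta_h = theta_h)
  th_avg <- NA_real_
  if (method %in% c("averaging", "both")) {
    orbits <- purrr::map(m_grid, function(m)
      fast_orbit(p0, m, solver))
    keep <- !vapply(orbits, is.null, TRUE)
    if (sum(keep) < 4) stop("spiking manifold not found on m_grid")
    orbs <- orbits[keep]
    ms <- vapply(orbs, `[[`, 1, "m_K2")
    ## averaged m_K2 steady state along each orbit, as a function of
    ## theta_K2 (the orbit itself does not depend on theta_K2)
    avg_at <- function(theta_K2) {
      vapply(orbs, function(ob) {
        g <- 1 / (1 + exp(-83 * (ob$samples$V + theta_K2)))
        trapz(ob$samples$time, g) / ob$period
      }, 1)
    }
    gap <- function(theta_K2) min(avg_at(theta_K2) - ms)
    glo <- gap(window[1]); ghi <- gap(window[2])
    if (glo * ghi > 0)
      stop("averaging criterion does not change sign in the window")
    th_avg <- stats::uniroot(gap, window, tol = 1e-10)$root
    if (method == "averaging")
      return(structure(list(type = "SN_orbits", theta_K2 = th_avg,
                            theta_h = theta_h, method = "averaging"),
                       class = "bifurcation_point"))
  }
  ## dynamical bisection: does the tonic orbit persist, or does the burst
  ## terminate (an interspike gap >= 1 s appears)?  The observation window
  ## grows as the bracket narrows, because burst duration diverges like
  ## 1/sqrt(offset) on approach to the fold.
  tonic_persists <- function(theta_K2, y0, width) {
    t_end <- min(max(150, 3 / sqrt(width)), solver$t_limit)
    p <- modify_params(params, theta_K2 = theta_K2, theta_h = theta_h)
    tr <- integrate_neuron(p, y0, t_end, solver)
    sp <- detect_spikes(tr)
    ok <- nrow(sp) > 3 && max(sp$time) > t_end - 5 &&
      max(diff(sp$time)) < 1
    list(ok = ok, y = trace_end_state(tr))
  }
  y <- spiking_like_state()
  w0 <- (window[2] - window[1])
  r <- tonic_persists(window[1], y, w0)
  if (!r$ok) stop("no sustained tonic spiking at the left end of the window")
  lo <- window[1]; hi <- window[2]; y <- r$y
  r2 <- tonic_persists(hi, y, w0)
  if (r2$ok) stop("tonic spiking persists at the right end of the window")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    r <- tonic_persists(mid, y, hi - lo)
    if (r$ok) { lo <- mid; y <- r$y } else hi <- mid
  }
  th_dyn <- (lo + hi) / 2
  if (method == "dynamical")
    return(structure(list(type = "SN_orbits", theta_K2 = th_dyn,
                          theta_h = theta_h, method = "dynamical"),
                     class = "bifurcation_point"))
  if (abs(th_avg - th_dyn) > agree_tol)
    stop(sprintf(
      "averaging (%.7f) and dynamical (%.7f) estimates disagree beyond %g V",
      th_avg, th_dyn, agree_tol))
  structure(list(type = "SN_orbits", theta_K2 = th_avg,
                 theta_h = theta_h, method = "both",
                 theta_K2_dynamical = th_dyn),
            class = "bifurcation_point")
}

#' Codimension-2 intersection of the two saddle-node curves
#'
#' Traces the saddle-node-of-equilibria curve `theta_h*(theta_K2)` and the
#' saddle-node-of-periodic-orbits curve `theta_K2*(theta_h)` on a few
#' points each, fits each by a low-order polynomial, and intersects them.
#'
#' @param params a [neuron_params()].
#' @param theta_K2_pts points at which the equilibria fold is traced, V.
#' @param theta_h_pts points at which the orbit fold is traced, V.
#' @param sn_orbit_method method forwarded to [locate_sn_orbits()].
#' @param solver a [solver_config()].
#' @param degree polynomial degree for the local curve fits (max 2).
#' @return A list of class `bifurcation_point`: `type = "codim2"`,
#'   `theta_K2`, `theta_h`, plus the traced curves and fit residuals.
#' @export
locate_codim2 <- function(params,
                          theta_K2_pts = seq(-0.0107, -0.009,
                                             length.out = 5),
                          theta_h_pts = seq(0.0414, 0.0418,
                                            length.out = 5),
                          sn_orbit_method = "averaging",
                          solver = solver_config(), degree = 2) {
  stopifnot(degree <= 2, length(theta_K2_pts) >= 3,
            length(theta_h_pts) >= 3)
  sn_eq <- purrr::map_dbl(theta_K2_pts, function(tk)
    locate_sn_equilibria(params, tk)$theta_h)
  sn_orb <- purrr::map_dbl(theta_h_pts, function(th)
    locate_sn_orbits(params, th, method = sn_orbit_method,
                     solver = solver)$theta_K2)
  ## theta_h = f(theta_K2) and theta_K2 = g(theta_h)
  f <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE),
                 data = data.frame(x = theta_K2_pts, y = sn_eq))
  g <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE),
                 data = data.frame(x = theta_h_pts, y = sn_orb))
  hfun <- function(tk) stats::predict(f, data.frame(x = tk))
  kfun <- function(th) stats::predict(g, data.frame(x = th))
  ## solve tk = kfun(hfun(tk))
  root <- stats::uniroot(function(tk) kfun(hfun(tk)) - tk,
                         range(c(theta_K2_pts, sn_orb)) + c(-5e-4, 5e-4),
                         tol = 1e-12)
  tk <- root$root
  structure(list(type = "codim2", theta_K2 = tk,
                 theta_h = unname(hfun(tk)),
                 sn_equilibria = tibble::tibble(theta_K2 = theta_K2_pts,
                                                theta_h = sn_eq),
                 sn_orbits = tibble::tibble(theta_h = theta_h_pts,
                                            theta_K2 = sn_orb),
                 eq_fit_rms = sqrt(mean(stats::resid(f)^2)),
                 orb_fit_rms = sqrt(mean(stats::resid(g)^2))),
            class = "bifurcation_point")
}

#' @export
print.bifurcation_point <- function(x, ...) {
  cat("<bifurcation_point:", x$type, "> theta_K2 =",
      format(x$theta_K2, digits = 10), "V, theta_h =",
      format(x$theta_h, digits = 10), "V\n")
  invisible(x)
}
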