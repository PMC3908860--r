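---
title: "Model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`burstwave` simulates a four-dimensional conductance-based model of an
endogenously bursting neuron of the kind used to describe leech heart
interneurons after pharmacological reduction (Ca2+ currents and most K+
currents blocked).  The membrane carries four currents:

* a fast sodium current \(I_{Na} = \bar g_{Na}\, m_{\infty,Na}^3(V)\,
  h_{Na}\, (V - E_{Na})\) with instantaneous cubic activation and an
  inactivation gate \(h_{Na}\) (time constant 40.5 ms),
* a slow non-inactivating potassium current
  \(I_{K2} = \bar g_{K2}\, m_{K2}^2 (V - E_K)\) whose activation
  \(m_{K2}\) is **the slow variable** of the system (time constant 2 s),
* a hyperpolarization-activated inward current
  \(I_h = \bar g_h\, m_h^2 (V - E_h)\),
* an ohmic leak \(I_{leak} = g_{leak} (V - E_{leak})\),

plus a constant polarizing current \(I_{pol}\):

\[
C\,\dot V = -I_{Na} - I_{K2} - I_h - I_{leak} + I_{pol} + I_{ext},
\qquad
\dot x = \frac{x_\infty(V) - x}{\tau_x},\; x \in \{h_{Na}, m_{K2}, m_h\}.
\]

Units are volts, seconds, nS, nA and nF throughout (nS·V = nA;
nA/nF·s = V); voltages are kept in volts, never millivolts.

The two *regulated* parameters are the half-activation voltages
\(\theta_{K2}\) and \(\theta_h\) of the slow potassium gate and of the
hyperpolarization-activated gate.  They enter the steady-state curves as
`V + theta`:

\[
m_{\infty,K2}(V) = \frac{1}{1 + e^{-83 (V + \theta_{K2})}},
\qquad
m_{\infty,h}(V) = \frac{1}{1 + 2 e^{180 (V + \theta_h)} +
                          e^{500 (V + \theta_h)}}.
\]

The double-exponential form of \(m_{\infty,h}\) is the classical
description of the h-current activation in leech heart interneuron
models.  Note that with this sign convention the physiological
half-activation voltages are \(-\theta\): the bursting region lives at
\(\theta_{K2} \approx -0.0105\ldots+0.006\) V and
\(\theta_h \approx 0.0375\ldots0.0414\) V.

### Default constants

`neuron_params()` ships \(\bar g_{Na}, \bar g_{K2}, \bar g_h, g_{leak} =
105, 30, 4, 8\) nS, \(E_{Na}, E_K, E_h, E_{leak} = 0.045, -0.07, -0.021,
-0.046\) V, \(C = 0.5\) nF, \(I_{pol} = -0.006\) nA, and gate time
constants \(\tau_{hNa} = 0.0405\) s, \(\tau_{K2} = 2\) s, \(\tau_{mh} =
0.12\) s.  The gate slopes and offsets of the sodium current
(\(m_{\infty,Na}\): slope 150 V\(^{-1}\), offset 0.0305 V;
\(h_{\infty,Na}\): slope −500 V\(^{-1}\), offset 0.0325 V) are the
canonical values of the reduced leech interneuron model family.

Two of these constants were fixed by calibration rather than copied from
a predecessor model, and the calibration is worth documenting because it
is unusually sharp:

* **\(I_{pol}\)** is identified by the location of the saddle-node
  bifurcation of equilibria.  The fold condition involves only the
  steady-state current, so it pins static constants independently of any
  time constant.  Requiring the fold at \(\theta_{K2} = -0.010\) V to sit
  at \(\theta_h^* = 0.0413523801\) V yields \(I_{pol} = -0.006000\) nA —
  a round number that equals the canonical polarizing-current magnitude
  of the predecessor models — and then *predicts* the folds at
  \(\theta_{K2} = -0.0107, -0.009\) V and the codimension-2 ordinate to
  a few nanovolts with no remaining freedom.  We treat this as recovery
  of the intended constant, not a tuned stand-in.
* **\(\tau_{mh}\)** only affects dynamics.  It was set once at 0.12 s:
  brief (30 ms) hyperpolarizing pulses fail to trigger rebound bursts
  for \(\tau_{mh} \lesssim 0.115\) s, while the pulse-triggered burst
  duration, the bursting-region temporal statistics and the duty cycle
  of the coregulation reference points are all reproduced at 0.12 s.

## Regimes and the organizing codimension-2 bifurcation

Depending on \((\theta_{K2}, \theta_h)\) the model rests, spikes
tonically, bursts, or is bistable between tonic spiking and rest.  Two
codimension-1 curves organize the plane:

* the **saddle-node of equilibria**, nearly horizontal in \(\theta_h\):
  above it a stable rest state exists.  On the bursting side its ghost
  controls the interburst interval; crossing it with a stable rest on
  an invariant circle is a SNIC, so the quiescent phase diverges as
  \(1/\sqrt{\theta_h^* - \theta_h}\);
* the **saddle-node of periodic orbits** (fold of the tonic spiking
  orbit), nearly vertical in \(\theta_{K2}\): to its left tonic spiking
  exists.  On the bursting side its ghost controls the burst duration,
  which diverges as \(1/\sqrt{c - |\theta_{K2}|}\) (a blue-sky
  catastrophe: the long-period orbit reinjects through the spiking
  manifold).

Their intersection is the codimension-2 organizing center; the four
regime regions meet there.  `locate_sn_equilibria()` solves the
two-equation fold system (steady-state current and its voltage
derivative both zero) by damped Newton iteration with a root-count
bracket.  `locate_sn_orbits()` offers two independent routes, which the
test suite requires to agree within \(10^{-4}\) V:

1. *orbit averaging* (Pontryagin–Rodygin): freeze the slow gate, compute
   the fast-subsystem limit cycle at each \(m_{K2}\), average
   \(m_{\infty,K2}(V(t))\) over one period with the trapezoidal rule,
   and find the \(\theta_{K2}\) at which this averaged slow nullcline
   becomes tangent to the identity line — the fold of full-system
   orbits in the averaged slow dynamics;
2. *dynamical bisection* on the qualitative outcome (tonic spiking
   persists versus the burst terminates), with an observation window
   that grows like \(1/\sqrt{\text{bracket width}}\) because burst
   duration diverges at the fold.

`locate_codim2()` traces both curves on a few points, fits each with a
polynomial of degree at most two, and intersects them.

## Slow-fast decomposition

The fast subsystem is \((V, h_{Na}, m_h)\) with \(m_{K2}\) frozen as a
parameter.  `fast_equilibria()` scans the frozen current balance for
roots and classifies their stability from the numerical Jacobian;
`fast_orbit()` settles the fast subsystem on its limit cycle and
returns exactly one period delimited by a Poincaré section at
\(V = -0.03\) V (upward crossing; configurable), with endpoints
interpolated onto the section so that trapezoidal averages integrate
over exactly one period.  During a burst the full trajectory rides the
spiking manifold between the slow-nullcline crossing and the manifold's
fold; the test suite asserts this envelope property at 2 mV tolerance.

## Measurements

The metric definitions are the standard ones for bursting neurons:
spikes are upward threshold crossings (default −0.01 V, 10 ms
refractory, linear interpolation between samples); bursts are maximal
spike groups whose internal intervals stay below the ISI gap (default
1 s — intra-burst intervals are ~0.2 s here and the smallest interburst
interval of interest is ~1.9 s); **burst duration** is first-to-last
spike of a burst, **interburst interval** last-to-next-first, **cycle
period** first-to-next-first (so period = BD + IBI per cycle by
construction), **duty cycle** is 100·BD/period.  Bursts clipped by the
record edges are flagged and excluded from means.  Latency to spiking
is measured from pulse *offset* to the next spike; the 30 ms pulse
width is negligible at the precision of interest but the convention is
fixed here.

In the pulse protocol on a spiking cell the pulse is locked to a spike
peak plus **half the interspike interval**.  The response depends on
pulse phase: near the spike the orbit is not dislodged at the standard
amplitudes, while mid-interval pulses reliably transfer the phase point
onto the slow equilibrium manifold.  The phase lock makes latencies
reproducible; the mid-interval choice makes the protocol effective.

## The inhibitory chain

`build_chain()` assembles cells labelled by body segment (3–7, anterior
to posterior) with graded inhibitory synapses: first-order activation
\(s\) relaxing to a steep sigmoid of presynaptic voltage (slope
1000 V\(^{-1}\), threshold −0.0305 V, \(\tau_s = 20\) ms), reversal
\(E_{syn} = -0.0625\) V.  The weight scheme is posterior-dominant:
cell \(i\) receives \(g_p\,\rho^{\,j-i-1}\) from each posterior cell
\(j\) (\(\rho = 0.5\)) and a weak anterior input
\(0.02\,g_p\) from its immediate anterior neighbor.  Two magnitudes
were calibrated once and shipped as defaults:

* \(g_p = 5\) nS: strong enough that the metachronal wave forms within
  one or two reference-cell cycles from near-synchronous initial
  conditions (couplings in the 3.5–4.5 nS range fall into a different,
  non-wave attractor at the fastest reference point; weaker couplings
  lock too slowly to observe);
* anterior fraction 0.02: the most posterior cell's only input is the
  anterior feedback, so this weight alone sets the network-versus-cell
  period discrepancy; 0.02 keeps it below 0.1 % while preserving the
  ordering invariants (anterior weaker than every posterior input).

Initial conditions follow the reference protocol: every cell starts at
the single-cell attractor state at the voltage minimum between the
second and third spike of a burst; odd segments are perturbed by
\(+10^{-4}\) V (results are insensitive to a ten-fold larger
perturbation).  Wave statistics report per-cell period and duty,
per-neighbor-pair relative phase
\(100\,((t_i - t_{i+1}) \bmod P)/P\) with the most posterior cell as
reference, and the number of reference cycles before formation.  The
formation criterion (the written record says only that waves formed
within two cycles) is: the earliest reference cycle after which every
observed cycle has strictly posterior-to-anterior onsets and every
neighbor lag within ±20 % of its final-cycle value; trailing cycles
whose anterior onsets fall beyond the record are not judged.

## Numerical choices

* Integration uses deSolve's `lsoda` (adaptive, high order) with
  `rtol = 1e-9`, `atol = 1e-12`, maximal step 0.25 s and output
  sampling 1 ms.  Spike times are stable to <0.1 ms per 100 s under
  100× tolerance refinement (tested).  A high-order explicit
  Runge-Kutta pair would serve equally; the stiffness-switching
  integrator is convenient because quiescent stretches are cheap.
* Brief rectangular pulses are integrated piecewise (the integrator is
  restarted at the pulse edges) so the adaptive stepper cannot stride
  across a 30 ms pulse during quiescence.
* Law fits use Levenberg–Marquardt trust-region least squares
  (minpack.lm) with `ftol = ptol = 1e-9`; the burst-duration law
  \(a/\sqrt{c - |\theta|} + b\) frees \(a, b, c\) with the constraint
  \(c > \max|\theta|\); the interburst law
  \(a/\sqrt{\theta_{bif} - \theta} + b\) frees \(a, b\) with
  \(\theta_{bif}\) fixed from the fold solver.  Both recover generating
  coefficients within 5 % from 20 points at 1 % multiplicative noise
  (tested).
* The scaling-exponent check regresses \(\log(T - b)\) on the log of
  the parameter offset; it requires offsets spanning at least two
  decades.  The interburst law's asymptotic regime sits within
  ~\(10^{-6}\) V of the fold, so the sweep samples offsets
  \(10^{-9}\)–\(3\times10^{-7}\) V; the burst-duration law is sampled
  at \(10^{-5}\)–\(3\times10^{-3}\) V from the orbit fold.
* Regime classification runs the model from a rest-like and a
  spiking-like state; silence/tonic/bursting labels come from the
  settled records, disagreement (one silent, one tonic) is bistability,
  and windows auto-extend (doubling, capped at 2000 s of model time)
  near boundaries where periods diverge.  Bursting is labelled by
  segmentation, not periodicity, so weakly irregular bursting still
  counts as bursting.

## Problem sizes used by the shipped checks

The test suite and the acceptance script use: 200 s of recorded
attractor (≈26 cycles) for the reference bursting point; 12
reference-cell cycles for chain experiments with period measured over
the late 60 % of the record; six-point sweeps for each scaling law; and
coarse (≤5-point) brackets for boundary bisections.  These sizes keep
every quantity's measurement error well inside the tolerances asserted
for it.

## What the synthetic fixtures do and do not show

`generate_spike_fixture()` builds periodic spike trains (and optional
traces with stereotyped Gaussian spike waveforms) whose burst duration,
interburst interval, period and duty are exact by construction;
`generate_law_fixture()` samples the two temporal laws with
multiplicative Gaussian noise.  They validate the metric and fitting
pipelines independently of the integrator — passing those tests says
nothing about the biophysics, which is exercised separately against the
bifurcation anchors and temporal statistics above.  The fixtures do not
emulate intra-burst spike-frequency adaptation, cycle-to-cycle
irregularity, or measurement noise in voltage, so they cannot stand in
for recorded data.

## Known limitations

* Period-doubling cascades, chaotic large-amplitude regimes, homoclinic
  and saddle-saddle continuations are out of scope; no Floquet-based
  continuation is provided.
* The regime classifier can mislabel extremely close to boundaries
  where transients exceed the 2000 s cap; such points are flagged
  `undecided` rather than silently coerced.
* The duty-cycle isoline solver is a local quasi-Newton refinement; it
  needs a starting point in the bursting region and step caps tuned to
  the model's sensitivity (defaults provided).
* Cell count in the chain is arbitrary up to 16, but all calibrated
  defaults target the five-cell configuration.
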