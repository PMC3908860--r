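## Deterministic synthetic fixtures: spike trains, voltage traces and
## law samples with exactly known statistics, for testing the metrics
## and fitting machinery independently of the integrator.

#' Synthetic spike-train / trace fixture
#'
#' Builds a periodic bursting spike train with exactly the requested
#' burst duration, interburst interval and spikes per burst, and
#' optionally a voltage trace that places stereotyped spike waveforms on
#' a baseline (plus optional Gaussian noise).
#'
#' @param n_bursts number of bursts.
#' @param spikes_per_burst spikes in each burst.
#' @param burst_duration first-to-last spike time within a burst, s.
#' @param interburst_interval last-to-next-first spike gap, s.
#' @param t0 time of the first spike, s.
#' @param trace if `TRUE`, also return a sampled voltage trace.
#' @param dt trace sampling interval, s.
#' @param baseline baseline voltage of the trace, V.
#' @param spike_peak spike peak voltage, V.
#' @param spike_width spike half-width, s.
#' @param noise_sd Gaussian noise added to the trace, V.
#' @param seed integer seed; fixed seed gives identical output.
#' @return A list: `spikes` (tibble with `time`), `trace` (tibble with
#'   `time`, `V`, or `NULL`), and the exact `burst_duration`,
#'   `interburst_interval`, `period`, `duty` implied by the spec.
#' @export
generate_spike_fixture <- function(n_bursts = 3, spikes_per_burst = 5,
                                   burst_duration = 1,
                                   interburst_interval = 9, t0 = 1,
                                   trace = FALSE, dt = 1e-3,
                                   baseline = -0.045, spike_peak = 0.01,
                                   spike_width = 0.01, noise_sd = 0,
                                   seed = 1) {
  period <- burst_duration + interburst_interval
  if (burst_duration >= period || burst_duration <= 0)
    stop("inconsistent spec: need 0 < burst_duration < period")
  stopifnot(n_bursts >= 1, spikes_per_burst >= 2)
  within <- seq(0, burst_duration, length.out = spikes_per_burst)
  onsets <- t0 + period * (seq_len(n_bursts) - 1)
  spikes <- as.numeric(outer(within, onsets, `+`))
  spikes <- sort(spikes)
  tr <- NULL
  if (trace) {
    t_end <- max(spikes) + interburst_interval / 2
    tt <- seq(0, t_end, by = dt)
    V <- rep(baseline, length(tt))
    for (s in spikes) {
      V <- V + (spike_peak - baseline) * exp(-((tt - s) / spike_width)^2)
    }
    if (noise_sd > 0) {
      set.seed(seed)
      V <- V + stats::rnorm(length(tt), sd = noise_sd)
    }
    tr <- tibble::tibble(time = tt, V = V)
  }
  list(spikes = tibble::tibble(time = spikes), trace = tr,
       burst_duration = burst_duration,
       interburst_interval = interburst_interval,
       period = period, duty = 100 * burst_duration / period)
}

#' Synthetic samples from an inverse-square-root law
#'
#' Draws `(theta, duration)` samples from the burst-duration law
#' `a / sqrt(c - |theta|) + b` or the interburst-interval law
#' `a / sqrt(theta_bif - theta) + b`, with multiplicative Gaussian noise.
#'
#' @param form `"BD_law"` or `"IBI_law"`.
#' @param a,b law coefficients.
#' @param c_bif the bifurcation coefficient: `c` (magnitude) for the
#'   burst-duration law, `theta_bif` for the interburst law.
#' @param offsets positive distances of `|theta|` (BD) or `theta` (IBI)
#'   from the bifurcation value, V.
#' @param noise_sd multiplicative noise standard deviation (e.g. 0.01
#'   for 1 %).
#' @param seed integer seed.
#' @return A tibble: `theta`, `duration`, `offset`.
#' @export
generate_law_fixture <- function(form = c("BD_law", "IBI_law"),
                                 a = 0.97, b = -8.5, c_bif = 0.0105,
                                 offsets = 10^seq(-6, -3.5,
                                                  length.out = 20),
                                 noise_sd = 0, seed = 1) {
  form <- match.arg(form)
  stopifnot(all(offsets > 0))
  if (form == "BD_law") {
    theta <- -(c_bif - offsets)
    duration <- bd_law(theta, a, b, c_bif)
  } else {
    theta <- c_bif - offsets
    duration <- ibi_law(theta, a, b, c_bif)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    duration <- duration * (1 + stats::rnorm(length(offsets), sd = noise_sd))
  }
  tibble::tibble(theta = theta, duration = duration, offset = offsets)
}
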