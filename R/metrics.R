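#' Detect spikes in a voltage trace
#'
#' A spike is an upward crossing of the detection threshold; the crossing
#' time is linearly interpolated between samples.  Crossings closer than
#' the refractory interval to the previous accepted spike are ignored.
#'
#' @param trace a trace tibble with columns `time` and `V` (a single cell).
#' @param threshold detection threshold, V.
#' @param refractory minimal allowed interspike interval, s.
#' @return A `spike_train` tibble with column `time`; the threshold and
#'   refractory are kept as attributes.  May have zero rows.
#' @export
detect_spikes <- function(trace, threshold = -0.01, refractory = 0.01) {
  V <- trace$V
  t <- trace$time
  n <- length(V)
  i <- which(V[-n] < threshold & V[-1] >= threshold)
  times <- t[i] + (threshold - V[i]) / (V[i + 1] - V[i]) * (t[i + 1] - t[i])
  if (length(times) > 1) {
    keep <- rep(TRUE, length(times))
    last <- times[1]
    for (k in seq_along(times)[-1]) {
      if (times[k] - last < refractory) keep[k] <- FALSE
      else last <- times[k]
    }
    times <- times[keep]
  }
  tibble::new_tibble(tibble::tibble(time = times),
                     threshold = threshold, refractory = refractory,
                     class = "bw_spikes")
}

#' Group spikes into bursts
#'
#' Splits a spike train at interspike intervals of at least `isi_gap`
#' seconds.  The first and last bursts touch the record edges, so cycles
#' involving them are marked incomplete and excluded from averaged
#' statistics downstream.
#'
#' @param spikes a tibble with column `time` (as from [detect_spikes()]),
#'   or a numeric vector of spike times.
#' @param isi_gap minimal interburst interspike interval, s.
#' @param record_start,record_end bounds of the underlying record, used to
#'   flag bursts clipped at the edges.  With the default infinite bounds
#'   (appropriate for constructed spike trains) every burst is complete.
#' @return A `burst_segmentation` tibble, one row per burst: `burst`,
#'   `t_first`, `t_last`, `n_spikes`, `complete` (logical: a silent gap of
#'   at least `isi_gap` is observed on both sides of the burst inside the
#'   record, so the burst is not clipped).
#' @export
segment_bursts <- function(spikes, isi_gap = 1,
                           record_start = -Inf, record_end = Inf) {
  times <- if (is.numeric(spikes)) sort(spikes) else sort(spikes$time)
  if (length(times) == 0) {
    out <- tibble::tibble(burst = integer(), t_first = numeric(),
                          t_last = numeric(), n_spikes = integer(),
                          complete = logical())
  } else {
    idx <- cumsum(c(1L, as.integer(diff(times) >= isi_gap)))
    t_first <- as.numeric(tapply(times, idx, min))
    t_last <- as.numeric(tapply(times, idx, max))
    n_spikes <- as.integer(tapply(times, idx, length))
    nb <- length(t_first)
    complete <- rep(TRUE, nb)
    complete[1] <- t_first[1] - record_start >= isi_gap
    complete[nb] <- complete[nb] && record_end - t_last[nb] >= isi_gap
    out <- tibble::tibble(burst = seq_len(nb), t_first = t_first,
                          t_last = t_last, n_spikes = n_spikes,
                          complete = complete)
  }
  tibble::new_tibble(out, isi_gap = isi_gap, class = "bw_bursts")
}

#' Temporal statistics of bursting
#'
#' Per-cycle and mean burst duration (first to last spike of a burst),
#' interburst interval (last spike to next first spike), cycle period
#' (first spike to next first spike) and duty cycle (burst duration over
#' period, percent).  Only interior cycles are used: the identity
#' `period = BD + IBI` holds per cycle by construction.
#'
#' @param seg a [segment_bursts()] result.
#' @return A list of class `temporal_stats`: tibble `cycles` (columns
#'   `burst_duration`, `interburst_interval`, `period`, `duty`,
#'   `n_spikes`), and scalar means `burst_duration`, `interburst_interval`,
#'   `period`, `duty` (percent), `spikes_per_burst`, plus `n_cycles`.
#'   Fewer than two complete bursts give `available = FALSE` and NA means.
#' @export
temporal_stats <- function(seg) {
  ## a cycle runs from a complete burst to the next burst (any burst can
  ## close a cycle; edge-clipped bursts never open one)
  nb <- nrow(seg)
  open_ok <- which(seg$complete[-nb])
  if (nb < 2 || length(open_ok) < 1) {
    return(structure(list(available = FALSE, cycles = tibble::tibble(),
                          burst_duration = NA_real_,
                          interburst_interval = NA_real_,
                          period = NA_real_, duty = NA_real_,
                          spikes_per_burst = NA_real_, n_cycles = 0L),
                     class = "temporal_stats"))
  }
  k <- open_ok
  bd <- seg$t_last[k] - seg$t_first[k]
  period <- seg$t_first[k + 1L] - seg$t_first[k]
  ibi <- period - bd
  cycles <- tibble::tibble(
    burst_duration = bd, interburst_interval = ibi, period = period,
    duty = 100 * bd / period, n_spikes = seg$n_spikes[k])
  structure(list(
    available = TRUE, cycles = cycles,
    burst_duration = mean(bd), interburst_interval = mean(ibi),
    period = mean(period), duty = 100 * mean(bd) / mean(period),
    spikes_per_burst = mean(seg$n_spikes[k]), n_cycles = length(k)),
    class = "temporal_stats")
}

#' @export
print.temporal_stats <- function(x, ...) {
  if (!x$available) { cat("<temporal_stats> unavailable (<2 cycles)\n") }
  else cat(sprintf(
    "<temporal_stats> %d cycles | BD %.3f s, IBI %.3f s, period %.3f s, duty %.2f%%\n",
    x$n_cycles, x$burst_duration, x$interburst_interval, x$period, x$duty))
  invisible(x)
}

#' Burst statistics of a voltage trace
#'
#' Convenience pipeline: [detect_spikes()], [segment_bursts()] with the
#' trace's time range as record bounds (so edge-clipped bursts are
#' excluded), then [temporal_stats()].
#'
#' @param trace a trace tibble (`time`, `V`).
#' @param threshold,refractory spike detection settings.
#' @param isi_gap burst segmentation gap, s.
#' @return A `temporal_stats` object.
#' @export
trace_stats <- function(trace, threshold = -0.01, refractory = 0.01,
                        isi_gap = 1) {
  sp <- detect_spikes(trace, threshold, refractory)
  temporal_stats(segment_bursts(sp, isi_gap,
                                record_start = min(trace$time),
                                record_end = max(trace$time)))
}

#' Latency from pulse offset to the next spike
#'
#' @param trace a trace from [pulse_protocol()] on a spiking cell (or any
#'   trace with a `pulse` attribute).
#' @param pulse the [pulse_spec()] that was applied; defaults to the
#'   trace's own `pulse` attribute.
#' @param threshold,refractory spike detection settings.
#' @return Latency in seconds, or `NA` (with a warning) if no spike
#'   follows the pulse.
#' @export
latency_to_spike <- function(trace, pulse = attr(trace, "pulse"),
                             threshold = -0.01, refractory = 0.01) {
  stopifnot(!is.null(pulse))
  off <- pulse$onset + pulse$duration
  sp <- detect_spikes(trace, threshold, refractory)
  after <- sp$time[sp$time > off]
  if (length(after) == 0) {
    warning("no spike after the pulse within the record")
    return(NA_real_)
  }
  after[1] - off
}

#' Duration of a pulse-triggered burst
#'
#' First-to-last spike time of the burst elicited from the silent regime.
#'
#' @inheritParams latency_to_spike
#' @param isi_gap burst segmentation gap, s.
#' @return Burst duration in seconds, or `NA` (with a warning) if the
#'   pulse elicited no burst.
#' @export
pulse_burst_duration <- function(trace, pulse = attr(trace, "pulse"),
                                 isi_gap = 1, threshold = -0.01,
                                 refractory = 0.01) {
  stopifnot(!is.null(pulse))
  sp <- detect_spikes(trace, threshold, refractory)
  sp <- sp[sp$time >= pulse$onset, , drop = FALSE]
  if (nrow(sp) == 0) {
    warning("pulse elicited no spikes")
    return(NA_real_)
  }
  seg <- segment_bursts(sp, isi_gap)
  seg$t_last[1] - seg$t_first[1]
}

#' Metachronal-wave statistics of a multi-cell spike set
#'
#' Computes per-cell periods and duty cycles, per-neighbor-pair relative
#' phases (percent of the reference period), and the number of
#' reference-cell cycles before the wave is formed.  The relative phase of
#' the pair (i, i+1) in a cycle is `100 * ((onset_i - onset_{i+1}) mod P) /
#' P`, with burst onsets matched per reference cycle and P the reference
#' cell's period; a posterior-to-anterior wave gives positive lags.  The
#' wave counts as formed from the first reference cycle after which, for
#' every later recorded cycle, burst onsets are ordered posterior to
#' anterior and every neighbor lag is within ±20 % of its final-cycle
#' value.
#'
#' @param spike_trains a named list of spike-time vectors (or spike-train
#'   tibbles), ordered anterior to posterior (e.g. segments 3..7).
#' @param reference index (into the list) of the reference cell; defaults
#'   to the last (most posterior) cell.
#' @param isi_gap burst segmentation gap, s.
#' @return A list of class `wave_stats`: tibble `cells` (per-cell period,
#'   duty), tibble `pairs` (per-pair mean lag percent), scalars
#'   `mean_phase` (grand mean neighbor lag, percent), `period` (reference
#'   cell), `formation_cycles`, `formed` (logical).
#' @export
wave_stats <- function(spike_trains, reference = length(spike_trains),
                       isi_gap = 1) {
  ncell <- length(spike_trains)
  stopifnot(ncell >= 2)
  times <- lapply(spike_trains, function(s)
    if (is.numeric(s)) sort(s) else sort(s$time))
  segs <- lapply(times, segment_bursts, isi_gap = isi_gap)
  stats <- lapply(segs, temporal_stats)
  if (!all(vapply(stats, `[[`, TRUE, "available")))
    stop("need at least 3 complete cycles for every cell")
  cells <- tibble::tibble(
    cell = if (!is.null(names(spike_trains))) names(spike_trains)
           else as.character(seq_len(ncell)),
    period = vapply(stats, `[[`, 1, "period"),
    duty = vapply(stats, `[[`, 1, "duty"))
  P <- stats[[reference]]$period
  ref_onsets <- segs[[reference]]$t_first[segs[[reference]]$complete]
  ## onset of cell i's burst in the cycle that starts at reference onset t0:
  ## the first onset of cell i at or after t0 (the wave travels ref -> 3)
  onset_in_cycle <- function(i, t0) {
    on <- segs[[i]]$t_first
    cand <- on[on >= t0 - 0.25 * P & on < t0 + P]
    if (length(cand) == 0) NA_real_ else cand[1]
  }
  ncyc <- length(ref_onsets)
  lag_mat <- matrix(NA_real_, nrow = ncyc, ncol = ncell - 1)
  ordered <- rep(FALSE, ncyc)
  for (c in seq_len(ncyc)) {
    ons <- vapply(seq_len(ncell), onset_in_cycle, 1, t0 = ref_onsets[c])
    if (any(is.na(ons))) next
    ordered[c] <- all(diff(ons) < 0)  # posterior fires first
    for (i in seq_len(ncell - 1))
      lag_mat[c, i] <- 100 * ((ons[i] - ons[i + 1]) %% P) / P
  }
  valid <- which(stats::complete.cases(lag_mat))
  if (length(valid) == 0) stop("no reference cycle with onsets in every cell")
  ## trailing reference cycles may lack anterior onsets (the wave has not
  ## reached segment 3 before the record ends); judge only observed cycles
  last_valid <- max(valid)
  final_lag <- lag_mat[last_valid, ]
  stable <- vapply(seq_len(last_valid), function(c) {
    !any(is.na(lag_mat[c, ])) && ordered[c] &&
      all(abs(lag_mat[c, ] - final_lag) <= 0.2 * abs(final_lag))
  }, TRUE)
  formed_from <- NA_integer_
  for (c in seq_len(last_valid))
    if (all(stable[c:last_valid])) { formed_from <- c; break }
  formed <- !is.na(formed_from)
  use <- if (formed) formed_from:last_valid else integer()
  pairs <- tibble::tibble(
    pair = paste(cells$cell[-ncell], cells$cell[-1], sep = "-"),
    phase = if (formed) colMeans(lag_mat[use, , drop = FALSE])
            else rep(NA_real_, ncell - 1))
  structure(list(
    cells = cells, pairs = pairs,
    mean_phase = if (formed) mean(lag_mat[use, ]) else NA_real_,
    period = P,
    formation_cycles = if (formed) formed_from - 1L else NA_integer_,
    formed = formed), class = "wave_stats")
}

#' @export
print.wave_stats <- function(x, ...) {
  cat(sprintf(
    "<wave_stats> period %.2f s | mean neighbor phase %.2f%% | formed after %s cycles\n",
    x$period, x$mean_phase,
    if (x$formed) x$formation_cycles else "never"))
  invisible(x)
}

#' Linear fit of spikes per burst against cycle period
#'
#' Ordinary least squares of the mean number of spikes per burst on the
#' cycle period across model instantiations.
#'
#' @param data a data frame with columns `period` (s) and `spikes` (mean
#'   spikes per burst).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`.
#' @export
spikes_per_burst_fit <- function(data) {
  stopifnot(nrow(data) >= 3)
  if (stats::sd(data$period) == 0) stop("degenerate abscissa")
  fit <- stats::lm(spikes ~ period, data = data)
  tibble::tibble(slope = stats::coef(fit)[["period"]],
                 intercept = stats::coef(fit)[["(Intercept)"]],
                 r_squared = summary(fit)$r.squared)
}
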