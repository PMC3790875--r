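# Synthetic ROI fluorescence traces: slow wave + spike transients + noise +
# slow drift, at a fixed optical sampling interval (default 1.5 ms).

#' Specification of the optical observation model
#'
#' Parameters of the mapping from a neuron's burst pattern to an ROI
#' fluorescence trace: a half-cosine slow-wave envelope over each burst window
#' (peak-to-trough amplitude `slow_wave_amplitude`), a short triangular
#' transient per spike, additive Gaussian noise, and a slow sinusoidal
#' baseline drift (emulating thermal drifts of the light source) with an
#' optional linear trend.
#'
#' The default sampling interval is 1.5 ms, the temporal resolution typical
#' of low-spatial-resolution VSD imaging of the stomatogastric ganglion.
#' Fluorescence amplitudes are arbitrary units; the default amplitude/noise
#' combination yields cycle-averaged signal-to-noise ratios of the order of
#' tens, the range reported for good VSD stainings.
#'
#' @param sample_interval Sampling interval in seconds (default 0.0015).
#' @param slow_wave_amplitude Peak-to-trough slow-wave amplitude (units).
#' @param spike_transient_amplitude Peak amplitude of the per-spike
#'   transient (units).
#' @param noise_sd SD of the additive white Gaussian noise (units).
#' @param drift_amplitude Amplitude of the sinusoidal baseline drift.
#' @param drift_timescale Period of the drift sinusoid, seconds (>= 10 s so
#'   that the 3-s DC-removal window cancels it).
#' @param drift_slope Linear trend, units per second.
#' @param seed Integer seed for the noise draw.
#' @return An object of class `optics_spec`.
#' @export
optics_spec <- function(sample_interval = 0.0015,
                        slow_wave_amplitude = 10,
                        spike_transient_amplitude = 2,
                        noise_sd = 0.75,
                        drift_amplitude = 0,
                        drift_timescale = 30,
                        drift_slope = 0,
                        seed = 1L) {
  stop_if_not_scalar_number(sample_interval, "sample_interval", min = 0,
                            strict_min = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", min = 0)
  stop_if_not_scalar_number(slow_wave_amplitude, "slow_wave_amplitude",
                            min = 0)
  stop_if_not_scalar_number(spike_transient_amplitude,
                            "spike_transient_amplitude", min = 0)
  stop_if_not_scalar_number(drift_timescale, "drift_timescale", min = 0,
                            strict_min = TRUE)
  structure(list(sample_interval = sample_interval,
                 slow_wave_amplitude = slow_wave_amplitude,
                 spike_transient_amplitude = spike_transient_amplitude,
                 noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 drift_timescale = drift_timescale,
                 drift_slope = drift_slope, seed = seed),
            class = "optics_spec")
}

#' Construct a fluorescence trace object
#'
#' A uniformly sampled ROI fluorescence time series.
#'
#' @param values Numeric vector of fluorescence values (arbitrary units).
#' @param sample_interval Sampling interval, seconds.
#' @param start_time Time of the first sample, seconds.
#' @param meta Optional list of metadata (e.g. generator ground truth).
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(values, sample_interval, start_time = 0,
                        meta = list()) {
  stop_if_not_scalar_number(sample_interval, "sample_interval", min = 0,
                            strict_min = TRUE)
  if (length(values) < 2L)
    stop("a fluorescence trace needs at least 2 samples", call. = FALSE)
  structure(list(values = as.numeric(values),
                 sample_interval = sample_interval,
                 start_time = start_time, meta = meta),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("fluorescence trace: %d samples at %.4g ms (%.3g s)\n",
              length(x$values), 1000 * x$sample_interval,
              length(x$values) * x$sample_interval))
  invisible(x)
}

trace_times <- function(trace) {
  trace$start_time +
    (seq_along(trace$values) - 1L) * trace$sample_interval
}

#' Render a synthetic ROI fluorescence trace
#'
#' Maps a neuron's spike train and ground-truth burst windows to an optical
#' trace: within each burst window `[on, off]` the slow wave contributes
#' `A/2 * (1 - cos(2 * pi * (t - on) / (off - on)))` (baseline 0 between
#' bursts, so the peak-to-trough amplitude per cycle is `A`, reached at the
#' burst midpoint with zero slope at the window edges); each spike adds a
#' triangular transient two samples wide; drift and Gaussian noise are
#' added on top.
#' The ground-truth amplitude and noise SD are recorded in the trace
#' metadata for recovery tests.
#'
#' @param rhythm A [generate_rhythm()] result, or a list with elements
#'   `spikes` (numeric vector) and `bursts` (data frame with `onset`,
#'   `offset`). An empty spike train yields a flat trace (noise + drift
#'   only).
#' @param optics An [optics_spec()].
#' @param neuron Which neuron's ROI to render when `rhythm` is a
#'   `pyloric_rhythm` (default `"LP"`).
#' @return A [fluor_trace()] whose `meta` holds `slow_wave_amplitude`,
#'   `noise_sd` and the burst windows used.
#' @export
render_fluorescence <- function(rhythm, optics = optics_spec(),
                                neuron = "LP") {
  stopifnot(inherits(optics, "optics_spec"))
  if (inherits(rhythm, "pyloric_rhythm")) {
    spikes <- rhythm$spikes[[neuron]]
    bursts <- rhythm$bursts[rhythm$bursts$neuron == neuron, , drop = FALSE]
    t_end <- rhythm$t_end
  } else {
    spikes <- rhythm$spikes
    bursts <- rhythm$bursts
    t_end <- max(c(spikes, bursts$offset, 1))
  }
  check_sorted_times(spikes, "spikes", strict = FALSE)
  dt <- optics$sample_interval
  nsmp <- max(2L, ceiling(t_end / dt) + 1L)
  tt <- (seq_len(nsmp) - 1L) * dt
  v <- numeric(nsmp)

  if (optics$slow_wave_amplitude > 0 && !is.null(bursts) && nrow(bursts)) {
    for (b in seq_len(nrow(bursts))) {
      on <- bursts$onset[b]; off <- bursts$offset[b]
      if (off <= on) next
      i0 <- max(1L, ceiling(on / dt) + 1L)
      i1 <- min(nsmp, floor(off / dt) + 1L)
      if (i1 < i0) next
      seg <- i0:i1
      v[seg] <- v[seg] + 0.5 * optics$slow_wave_amplitude *
        (1 - cos(2 * pi * (tt[seg] - on) / (off - on)))
    }
  }
  if (optics$spike_transient_amplitude > 0 && length(spikes)) {
    i <- round(spikes / dt) + 1L
    ok <- i >= 1L & i <= nsmp
    amp <- optics$spike_transient_amplitude
    add_at <- function(idx, w) {
      idx <- idx[idx >= 1L & idx <= nsmp]
      if (length(idx)) {
        tb <- tabulate(idx, nbins = nsmp)
        v <<- v + w * tb
      }
    }
    add_at(i[ok], amp)
    add_at(i[ok] - 1L, amp / 2)
    add_at(i[ok] + 1L, amp / 2)
  }
  if (optics$drift_amplitude != 0)
    v <- v + optics$drift_amplitude * sin(2 * pi * tt / optics$drift_timescale)
  if (optics$drift_slope != 0)
    v <- v + optics$drift_slope * tt
  if (optics$noise_sd > 0)
    v <- v + with_seed(optics$seed, rnorm(nsmp, 0, optics$noise_sd))

  fluor_trace(v, dt, start_time = 0,
              meta = list(slow_wave_amplitude = optics$slow_wave_amplitude,
                          spike_transient_amplitude =
                            optics$spike_transient_amplitude,
                          noise_sd = optics$noise_sd,
                          neuron = if (inherits(rhythm, "pyloric_rhythm"))
                            neuron else NA_character_,
                          bursts = bursts))
}
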