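# Cycle-triggered signal-to-noise procedure for optical traces:
# sliding-mean DC removal, high-pass noise isolation, triggered averaging,
# amplitude and noise-SD measurement.

#' Sliding-mean DC removal
#'
#' Subtracts from each sample the mean of the trace over a symmetric window
#' `[t - half_window, t + half_window]`; near the edges the window is
#' truncated to the available samples, so the output has the same length
#' and sampling as the input. With the default 3-s half-window this removes
#' slow frequency components and baseline drifts (e.g. thermal drifts of
#' the light source) while passing the pyloric-timed signal.
#'
#' @param trace A [fluor_trace()].
#' @param half_window Half-width of the averaging window, seconds; must be
#'   at least one sample interval.
#' @return A [fluor_trace()] of the same length.
#' @export
dc_remove <- function(trace, half_window = 3) {
  stopifnot(inherits(trace, "fluor_trace"))
  stop_if_not_scalar_number(half_window, "half_window", min = 0,
                            strict_min = TRUE)
  h <- round(half_window / trace$sample_interval)
  if (h < 1)
    stop("`half_window` is shorter than one sample interval", call. = FALSE)
  out <- trace
  out$values <- trace$values - running_mean(trace$values, h)
  out
}

#' High-pass filter isolating the noise floor
#'
#' Sliding-mean subtraction with a short time base (default 0.01 s):
#' removes components slower than roughly `1 / time_base` -- i.e. the
#' neuronal events such as slow-wave oscillations and synaptic potentials
#' -- and passes only the fast noise, whose level can then be measured.
#'
#' @param trace A [fluor_trace()].
#' @param time_base Half-width of the averaging window, seconds.
#' @return A [fluor_trace()] of the same length.
#' @export
highpass_noise_filter <- function(trace, time_base = 0.01) {
  dc_remove(trace, half_window = time_base)
}

#' Cycle-triggered average of an optical trace
#'
#' Averages the trace over segments of one cycle period following each
#' trigger (typically the first LP spike of every LP burst). The cycle
#' period is taken as the mean inter-trigger interval; each segment is
#' aligned to the sample grid by nearest-sample rounding and segments that
#' run past the end of the trace are discarded. A warning is issued when
#' fewer than 10 complete cycles are averaged, since reliable averages
#' require averaging over multiple (> 10) cycles.
#'
#' @param trace A [fluor_trace()].
#' @param triggers Ascending trigger times, seconds (>= 1 inside the
#'   trace).
#' @param period Optional known cycle period, seconds; overrides the mean
#'   inter-trigger interval (needed e.g. for a single-sweep segment).
#' @return List with `waveform` (mean cycle, fluorescence units),
#'   `cycle_period` (s), `n_cycles` (segments averaged) and
#'   `sample_interval`.
#' @export
triggered_average <- function(trace, triggers, period = NULL) {
  stopifnot(inherits(trace, "fluor_trace"))
  check_sorted_times(triggers, "triggers")
  if (!length(triggers)) stop("no triggers supplied", call. = FALSE)
  dt <- trace$sample_interval
  n <- length(trace$values)
  if (is.null(period))
    period <- if (length(triggers) >= 2L) mean(diff(triggers)) else
      (n - 1) * dt - (triggers[1] - trace$start_time)
  if (period <= 0) stop("non-positive cycle period", call. = FALSE)
  seg_len <- max(2L, round(period / dt))
  start_idx <- round((triggers - trace$start_time) / dt) + 1L
  ok <- start_idx >= 1L & (start_idx + seg_len - 1L) <= n
  if (!any(ok))
    stop("no trigger has a complete one-period segment inside the trace",
         call. = FALSE)
  start_idx <- start_idx[ok]
  n_cycles <- length(start_idx)
  if (n_cycles < 10L)
    warning(sprintf("only %d complete cycle(s) averaged; > 10 recommended",
                    n_cycles), call. = FALSE)
  idx <- outer(start_idx, seq_len(seg_len) - 1L, "+")
  waveform <- colMeans(matrix(trace$values[idx], nrow = n_cycles))
  list(waveform = waveform, cycle_period = period, n_cycles = n_cycles,
       sample_interval = dt)
}

#' Peak-to-trough amplitude of an averaged cycle
#'
#' The signal amplitude is the difference between the maximum and minimum
#' of the cycle-averaged waveform.
#'
#' @param waveform Numeric vector (one averaged cycle), or the list
#'   returned by [triggered_average()].
#' @return Amplitude in fluorescence units (>= 0).
#' @export
signal_amplitude <- function(waveform) {
  if (is.list(waveform)) waveform <- waveform$waveform
  if (!length(waveform)) stop("empty waveform", call. = FALSE)
  max(waveform) - min(waveform)
}

#' Noise SD of the cycle-averaged, high-pass-filtered trace
#'
#' High-pass filters the trace ([highpass_noise_filter()]), averages the
#' filtered signal over the triggered cycles, and returns the standard
#' deviation of the averaged waveform over one period after the trigger.
#'
#' @param trace A [fluor_trace()].
#' @param triggers Ascending trigger times, seconds.
#' @param time_base High-pass time base, seconds (default 0.01).
#' @param period Optional known cycle period, seconds (see
#'   [triggered_average()]).
#' @return Noise SD in fluorescence units.
#' @export
noise_sd <- function(trace, triggers, time_base = 0.01, period = NULL) {
  filtered <- highpass_noise_filter(trace, time_base)
  ta <- triggered_average(filtered, triggers, period = period)
  sd(ta$waveform)
}

#' Cycle-triggered signal-to-noise ratio
#'
#' The full S/N procedure: (1) DC-remove the trace with a `dc_window`
#' half-window (default 3 s) and average it over the triggered cycles; the
#' amplitude is the peak-to-trough difference within the averaged cycle.
#' (2) Separately, high-pass filter the trace with `noise_time_base`
#' (default 0.01 s), average the filtered signal over the same cycles, and
#' take the SD over one period as the noise level. S/N is the amplitude
#' divided by the noise SD.
#'
#' @param trace A [fluor_trace()].
#' @param triggers Ascending trigger times (first LP spike of each burst),
#'   seconds.
#' @param dc_window Half-window of the slow DC removal, seconds.
#' @param noise_time_base Half-window of the noise high-pass, seconds.
#' @param period Optional known cycle period, seconds (see
#'   [triggered_average()]).
#' @return An object of class `snr_result`: list with `waveform` (averaged
#'   DC-removed cycle), `cycle_period`, `n_cycles`, `amplitude`,
#'   `noise_sd`, `snr` and `infinite_snr` (`TRUE` when the noise SD is
#'   exactly zero, in which case `snr` is `Inf` and flagged rather than
#'   reported as a finite number).
#' @examples
#' r <- generate_rhythm(rhythm_spec(n_cycles = 12))
#' tr <- render_fluorescence(r, optics_spec(noise_sd = 0.5), neuron = "LP")
#' lp <- r$bursts[r$bursts$neuron == "LP", ]
#' res <- compute_snr(tr, lp$onset)
#' res$snr
#' @export
compute_snr <- function(trace, triggers, dc_window = 3,
                        noise_time_base = 0.01, period = NULL) {
  ta <- triggered_average(dc_remove(trace, dc_window), triggers,
                          period = period)
  amplitude <- signal_amplitude(ta$waveform)
  nsd <- suppressWarnings(noise_sd(trace, triggers, noise_time_base,
                                   period = period))
  infinite <- nsd == 0
  structure(list(waveform = ta$waveform, cycle_period = ta$cycle_period,
                 n_cycles = ta$n_cycles, amplitude = amplitude,
                 noise_sd = nsd,
                 snr = if (infinite) Inf else amplitude / nsd,
                 infinite_snr = infinite),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf(paste0("cycle-triggered S/N: amplitude %.4g, noise SD %.4g,",
                     " S/N %s (n = %d cycles, period %.4g s)\n"),
              x$amplitude, x$noise_sd,
              if (x$infinite_snr) "infinite (zero noise)" else
                sprintf("%.4g", x$snr),
              x$n_cycles, x$cycle_period))
  invisible(x)
}
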