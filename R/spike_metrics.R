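# Pyloric pattern statistics: burst detection, cycle period, burst
# duration, intraburst frequency, instantaneous frequency, phase.

#' Detect bursts by an interspike-interval threshold
#'
#' Partitions a spike train into bursts: consecutive spikes whose
#' interspike interval is at most `max_intraburst_isi` belong to the same
#' burst. The partition is exhaustive and ordered; singleton bursts are
#' allowed. The default threshold of 0.25 s separates the pyloric
#' intraburst band (ISIs below 0.1 s for 10--55 Hz firing) from the
#' interburst gaps (0.5 s and longer for cycle periods of 0.5--2 s).
#'
#' @param times Strictly increasing spike times, seconds.
#' @param max_intraburst_isi ISI threshold in seconds (> 0).
#' @return Data frame with one row per burst: `onset` (first spike),
#'   `offset` (last spike), `n_spikes`, `duration` (`offset - onset`).
#'   An empty train gives a zero-row data frame.
#' @examples
#' detect_bursts(c(0, 0.05, 0.10, 1.0, 1.05))
#' @export
detect_bursts <- function(times, max_intraburst_isi = 0.25) {
  stop_if_not_scalar_number(max_intraburst_isi, "max_intraburst_isi",
                            min = 0, strict_min = TRUE)
  check_sorted_times(times, "times")
  if (!length(times))
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      n_spikes = integer(0), duration = numeric(0)))
  new_burst <- c(TRUE, diff(times) > max_intraburst_isi)
  id <- cumsum(new_burst)
  onset <- times[new_burst]
  offset <- times[c(new_burst[-1], TRUE)]
  n <- as.integer(tabulate(id))
  data.frame(onset = onset, offset = offset, n_spikes = n,
             duration = offset - onset)
}

#' Cycle periods from PD burst onsets
#'
#' The cycle period of the pyloric rhythm is the duration between the onset
#' of one PD burst and the onset of the subsequent PD burst.
#'
#' @param pd_burst_onsets Ascending PD burst onset times, seconds.
#' @return Numeric vector of `n - 1` periods; empty if fewer than 2 onsets.
#' @export
cycle_periods <- function(pd_burst_onsets) {
  check_sorted_times(pd_burst_onsets, "pd_burst_onsets")
  if (length(pd_burst_onsets) < 2L) return(numeric(0))
  diff(pd_burst_onsets)
}

#' Intraburst firing frequency
#'
#' The intraburst frequency of a burst is the number of spikes minus one,
#' divided by the burst duration. Single-spike bursts (or zero-duration
#' bursts) have no defined intraburst frequency and yield `NA` rather than
#' an error, so that degraded rhythms do not abort batch analysis.
#'
#' @param bursts A data frame as returned by [detect_bursts()] (columns
#'   `n_spikes` and `duration`).
#' @return Numeric vector of frequencies in Hz, `NA` where undefined.
#' @examples
#' intraburst_frequencies(detect_bursts(c(0, .1, .2, .3, .4)))
#' @export
intraburst_frequencies <- function(bursts) {
  stopifnot(is.data.frame(bursts),
            all(c("n_spikes", "duration") %in% names(bursts)))
  out <- rep(NA_real_, nrow(bursts))
  ok <- bursts$n_spikes >= 2L & bursts$duration > 0
  out[ok] <- (bursts$n_spikes[ok] - 1) / bursts$duration[ok]
  out
}

#' Instantaneous firing frequencies
#'
#' The instantaneous frequency is the reciprocal of each interspike
#' interval; order is preserved (value `i` belongs to the interval between
#' spikes `i` and `i + 1`).
#'
#' @param times Strictly increasing spike times, seconds.
#' @return Numeric vector of `n - 1` frequencies in Hz; empty for fewer
#'   than 2 spikes. Duplicate timestamps (zero ISI) raise an error.
#' @examples
#' instantaneous_frequencies(c(0, 0.1, 0.3))
#' @export
instantaneous_frequencies <- function(times) {
  check_sorted_times(times, "times")
  if (length(times) < 2L) return(numeric(0))
  1 / diff(times)
}

#' Phases of events within pyloric cycles
#'
#' Normalizes event times to the cycle period, referenced to PD burst
#' onsets: an event `t` in cycle `[onset_i, onset_(i+1))` has phase
#' `(t - onset_i) / (onset_(i+1) - onset_i)`, in `[0, 1)` (half-open
#' convention, so an event exactly at a PD onset has phase 0). Events
#' outside the span covered by the onsets are dropped; the number dropped
#' is attached as attribute `n_dropped` and reported with a warning.
#'
#' @param event_times Event times, seconds.
#' @param pd_onsets Ascending PD burst onset times (>= 2), seconds.
#' @return Numeric vector of phases in `[0, 1)` with attribute `n_dropped`.
#' @examples
#' phases(0.4, c(0, 1))
#' @export
phases <- function(event_times, pd_onsets) {
  check_sorted_times(pd_onsets, "pd_onsets")
  if (length(pd_onsets) < 2L)
    stop("need at least 2 PD onsets to define a cycle", call. = FALSE)
  inside <- event_times >= pd_onsets[1] &
    event_times < pd_onsets[length(pd_onsets)]
  n_dropped <- sum(!inside)
  if (n_dropped > 0)
    warning(sprintf("%d event(s) outside the cycle span were dropped",
                    n_dropped), call. = FALSE)
  ev <- event_times[inside]
  i <- findInterval(ev, pd_onsets)
  ph <- (ev - pd_onsets[i]) / (pd_onsets[i + 1L] - pd_onsets[i])
  structure(ph, n_dropped = n_dropped)
}

#' Per-cycle pyloric pattern statistics
#'
#' Computes, for each cycle defined by consecutive PD burst onsets, the
#' cycle period and per-neuron burst duration, spike count, intraburst
#' frequency and on/off phases. Bursts are assigned to the cycle containing
#' their onset (half-open convention).
#'
#' @param spikes Named list of spike-time vectors (one per neuron); must
#'   contain the PD reference train.
#' @param pd_label Name of the PD train in `spikes` (default `"PD"`).
#' @param max_intraburst_isi ISI threshold for [detect_bursts()], seconds.
#' @return Data frame with one row per neuron per cycle: `cycle`,
#'   `cycle_period`, `neuron`, `burst_duration`, `n_spikes`,
#'   `intraburst_frequency`, `onset_phase`, `offset_phase`.
#' @export
cycle_metrics <- function(spikes, pd_label = "PD",
                          max_intraburst_isi = 0.25) {
  stopifnot(is.list(spikes), pd_label %in% names(spikes))
  pd_bursts <- detect_bursts(spikes[[pd_label]], max_intraburst_isi)
  if (nrow(pd_bursts) < 2L)
    stop("need at least 2 PD bursts to define cycles", call. = FALSE)
  onsets <- pd_bursts$onset
  periods <- cycle_periods(onsets)
  out <- list()
  for (nm in names(spikes)) {
    b <- detect_bursts(spikes[[nm]], max_intraburst_isi)
    inside <- b$onset >= onsets[1] & b$onset < onsets[length(onsets)]
    b <- b[inside, , drop = FALSE]
    if (!nrow(b)) next
    ci <- findInterval(b$onset, onsets)
    out[[nm]] <- data.frame(
      cycle = ci,
      cycle_period = periods[ci],
      neuron = nm,
      burst_duration = b$duration,
      n_spikes = b$n_spikes,
      intraburst_frequency = intraburst_frequencies(b),
      onset_phase = (b$onset - onsets[ci]) / periods[ci],
      offset_phase = (b$offset - onsets[ci]) / periods[ci],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cycle, res$onset_phase), ]
}
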