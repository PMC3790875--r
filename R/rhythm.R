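# Synthetic triphasic pyloric rhythm generator.

default_neuron_table <- function() {
  data.frame(
    neuron = c("PD", "LP", "PY"),
    onset_phase = c(0.00, 0.40, 0.75),
    duration_phase = c(0.25, 0.30, 0.20),
    intraburst_frequency = c(30, 20, 25),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic pyloric rhythm
#'
#' Defines the ground-truth triphasic pattern: a sequence of cycles with a
#' (possibly jittered) cycle period, and for each neuron (PD, LP, PY) a burst
#' window given as phase fractions of the cycle plus an intraburst firing
#' frequency. Defaults emulate a healthy preparation: 1.2 s cycle period
#' (within the physiological 0.5--2 s range), PD -> LP -> PY firing order
#' with non-overlapping burst windows, and intraburst frequencies in the
#' 10--55 Hz range.
#'
#' @param cycle_period Nominal cycle period in seconds.
#' @param neurons Data frame with columns `neuron`, `onset_phase`,
#'   `duration_phase` (fractions of the cycle in `[0, 1)`) and
#'   `intraburst_frequency` (Hz). Default: triphasic PD/LP/PY pattern.
#' @param n_cycles Number of cycles to generate.
#' @param period_jitter_sd Gaussian SD of cycle-to-cycle period jitter,
#'   seconds. `0` gives a perfectly regular rhythm.
#' @param triphasic If `TRUE` (default) the burst phase windows must not
#'   overlap; overlapping windows raise an error.
#' @param seed Integer seed for the period jitter draw.
#' @return An object of class `rhythm_spec`.
#' @seealso [generate_rhythm()], [pathology_spec()]
#' @export
rhythm_spec <- function(cycle_period = 1.2,
                        neurons = default_neuron_table(),
                        n_cycles = 10,
                        period_jitter_sd = 0,
                        triphasic = TRUE,
                        seed = 1L) {
  stop_if_not_scalar_number(cycle_period, "cycle_period", min = 0,
                            strict_min = TRUE)
  stop_if_not_scalar_number(n_cycles, "n_cycles", min = 1)
  stop_if_not_scalar_number(period_jitter_sd, "period_jitter_sd", min = 0)
  stopifnot(is.data.frame(neurons),
            all(c("neuron", "onset_phase", "duration_phase",
                  "intraburst_frequency") %in% names(neurons)))
  if (any(neurons$onset_phase < 0 | neurons$onset_phase >= 1))
    stop("`onset_phase` must lie in [0, 1)", call. = FALSE)
  if (any(neurons$duration_phase <= 0 |
          neurons$onset_phase + neurons$duration_phase > 1))
    stop("burst windows must fit within one cycle", call. = FALSE)
  if (any(neurons$intraburst_frequency <= 0))
    stop("`intraburst_frequency` must be positive", call. = FALSE)
  if (isTRUE(triphasic) && nrow(neurons) > 1) {
    ord <- order(neurons$onset_phase)
    on <- neurons$onset_phase[ord]
    off <- on + neurons$duration_phase[ord]
    if (any(off[-length(off)] > on[-1]))
      stop("burst phase windows overlap; a triphasic pattern requires ",
           "disjoint windows", call. = FALSE)
  }
  structure(list(cycle_period = cycle_period, neurons = neurons,
                 n_cycles = as.integer(n_cycles),
                 period_jitter_sd = period_jitter_sd,
                 triphasic = isTRUE(triphasic), seed = seed),
            class = "rhythm_spec")
}

#' Specification of an injected rhythm pathology
#'
#' Describes degradations of the pattern observed under dye toxicity:
#' dropping of single intraburst spikes (leaving gaps that produce lower
#' instantaneous frequencies) and switching of a neuron from rhythmic
#' bursting to tonic firing. Pathologies are applied to spikes at or after
#' `onset_time`.
#'
#' @param missing_spike_prob Probability that each affected intraburst spike
#'   is dropped, in `[0, 1]`.
#' @param tonic_switch If `TRUE`, the affected neuron fires tonically at
#'   `tonic_rate` from `onset_time` onward instead of bursting.
#' @param tonic_rate Tonic firing rate in Hz; the default 5 Hz lies inside
#'   the 3--9 Hz band where toxicity-induced frequencies accumulate.
#' @param onset_time Time (s) from which the pathology acts.
#' @param neuron Label of the affected neuron (default `"LP"`, the unit used
#'   for toxicity scoring).
#' @param seed Integer seed for the spike-dropping draw.
#' @return An object of class `pathology_spec`.
#' @export
pathology_spec <- function(missing_spike_prob = 0,
                           tonic_switch = FALSE,
                           tonic_rate = 5,
                           onset_time = 0,
                           neuron = "LP",
                           seed = 1L) {
  stop_if_not_scalar_number(missing_spike_prob, "missing_spike_prob", 0, 1)
  stop_if_not_scalar_number(tonic_rate, "tonic_rate", min = 0,
                            strict_min = TRUE)
  stop_if_not_scalar_number(onset_time, "onset_time", min = 0)
  structure(list(missing_spike_prob = missing_spike_prob,
                 tonic_switch = isTRUE(tonic_switch),
                 tonic_rate = tonic_rate, onset_time = onset_time,
                 neuron = neuron, seed = seed),
            class = "pathology_spec")
}

#' Generate a synthetic pyloric rhythm
#'
#' Realizes the spike trains described by a [rhythm_spec()]. Each cycle `i`
#' has period `P_i = cycle_period + jitter_i`; within it, each neuron emits a
#' burst of evenly spaced spikes at its intraburst frequency starting at
#' `onset_phase * P_i` after the cycle onset and ending no later than
#' `(onset_phase + duration_phase) * P_i`. Ground-truth burst boundaries and
#' realized cycle periods are returned alongside the spikes so that
#' downstream estimators can be checked for exact parameter recovery.
#'
#' @param spec A [rhythm_spec()].
#' @param pathology Optional [pathology_spec()] applied to its target neuron
#'   after its onset time.
#' @return An object of class `pyloric_rhythm`: a list with elements
#'   `spikes` (named list of numeric spike-time vectors, seconds), `bursts`
#'   (data frame `neuron`, `cycle`, `onset`, `offset`, `n_spikes` of the
#'   scheduled, pre-pathology bursts), `cycle_onsets` (PD-referenced cycle
#'   onset times), `periods` (realized cycle periods), `t_end` (end of the
#'   last cycle) and the input specs.
#' @examples
#' r <- generate_rhythm(rhythm_spec(n_cycles = 3))
#' names(r$spikes)
#' @export
generate_rhythm <- function(spec, pathology = NULL) {
  stopifnot(inherits(spec, "rhythm_spec"))
  if (!is.null(pathology)) stopifnot(inherits(pathology, "pathology_spec"))
  n <- spec$n_cycles
  periods <- with_seed(spec$seed, {
    p <- rep(spec$cycle_period, n)
    if (spec$period_jitter_sd > 0)
      p <- p + rnorm(n, 0, spec$period_jitter_sd)
    p
  })
  # keep periods physical even under extreme jitter draws
  periods <- pmax(periods, 0.05 * spec$cycle_period)
  cycle_onsets <- cumsum(c(0, periods[-n]))
  t_end <- cycle_onsets[n] + periods[n]

  spikes <- list()
  bursts <- vector("list", nrow(spec$neurons))
  for (j in seq_len(nrow(spec$neurons))) {
    nm <- spec$neurons$neuron[j]
    f <- spec$neurons$intraburst_frequency[j]
    b_on <- cycle_onsets + spec$neurons$onset_phase[j] * periods
    b_dur <- spec$neurons$duration_phase[j] * periods
    k <- floor(b_dur * f + 1e-9)          # spikes per burst = k + 1
    idx <- rep.int(seq_len(n), k + 1)
    st <- b_on[idx] + (sequence(k + 1) - 1) / f
    spikes[[nm]] <- st
    bursts[[j]] <- data.frame(neuron = nm, cycle = seq_len(n), onset = b_on,
                              offset = b_on + k / f, n_spikes = k + 1L,
                              stringsAsFactors = FALSE)
  }
  bursts <- do.call(rbind, bursts)

  if (!is.null(pathology) && pathology$neuron %in% names(spikes)) {
    st <- spikes[[pathology$neuron]]
    if (pathology$tonic_switch) {
      keep <- st[st < pathology$onset_time]
      tonic <- seq(pathology$onset_time, t_end, by = 1 / pathology$tonic_rate)
      last_keep <- if (length(keep)) max(keep) else -Inf
      st <- c(keep, tonic[tonic > last_keep])
    } else if (pathology$missing_spike_prob > 0) {
      affected <- st >= pathology$onset_time
      drop <- with_seed(pathology$seed,
                        runif(length(st)) < pathology$missing_spike_prob)
      st <- st[!(affected & drop)]
    }
    spikes[[pathology$neuron]] <- st
  }

  structure(list(spikes = spikes, bursts = bursts,
                 cycle_onsets = cycle_onsets, periods = periods,
                 t_end = t_end, spec = spec, pathology = pathology),
            class = "pyloric_rhythm")
}

#' @export
print.pyloric_rhythm <- function(x, ...) {
  cat(sprintf("pyloric rhythm: %d cycles, period %.3g s (+/- %.3g s jitter)\n",
              x$spec$n_cycles, x$spec$cycle_period,
              x$spec$period_jitter_sd))
  for (nm in names(x$spikes))
    cat(sprintf("  %s: %d spikes\n", nm, length(x$spikes[[nm]])))
  invisible(x)
}
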