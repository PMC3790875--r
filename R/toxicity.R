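# Frequency-band toxicity profile: classify LP instantaneous frequencies
# into the interburst / intermediate / intraburst bands, compute band
# occupancy over the measurement schedule, and score deviation from a
# pre-dye control.

#' Instantaneous-frequency band scheme
#'
#' The three diagnostic bands of LP firing: interburst 0--2 Hz (the gap
#' between successive bursts, roughly the cycle period), intermediate
#' 3--9 Hz (frequencies produced by missing intraburst spikes or tonic
#' firing -- rare in healthy preparations), and intraburst 10--55 Hz. Band
#' bounds are closed on both ends; frequencies in the gaps (2--3, 9--10 Hz)
#' and above 55 Hz fall into an explicit `"other"` class so that occupancy
#' fractions always sum to 1.
#'
#' @param interburst,intermediate,intraburst Numeric `c(low, high)` bounds
#'   in Hz.
#' @return An object of class `band_scheme`: data frame with columns
#'   `band`, `low`, `high`.
#' @export
band_scheme <- function(interburst = c(0, 2),
                        intermediate = c(3, 9),
                        intraburst = c(10, 55)) {
  sc <- data.frame(band = c("interburst", "intermediate", "intraburst"),
                   low = c(interburst[1], intermediate[1], intraburst[1]),
                   high = c(interburst[2], intermediate[2], intraburst[2]),
                   stringsAsFactors = FALSE)
  if (any(sc$low > sc$high)) stop("band bounds inverted", call. = FALSE)
  ord <- order(sc$low)
  if (any(sc$high[ord][-3] >= sc$low[ord][-1]))
    stop("bands must not overlap", call. = FALSE)
  structure(sc, class = c("band_scheme", "data.frame"))
}

band_labels <- function(scheme) c(scheme$band, "other")

#' Classify frequencies into bands
#'
#' Assigns each non-negative frequency to the closed band containing it,
#' or to `"other"` if it lies in a gap between bands or above the highest
#' band.
#'
#' @param freq Numeric vector of frequencies in Hz (>= 0).
#' @param scheme A [band_scheme()].
#' @return Character vector of band labels.
#' @examples
#' classify_band(c(1, 2.5, 5, 20))
#' @export
classify_band <- function(freq, scheme = band_scheme()) {
  stopifnot(inherits(scheme, "band_scheme"))
  if (any(!is.finite(freq) | freq < 0))
    stop("frequencies must be finite and non-negative", call. = FALSE)
  out <- rep("other", length(freq))
  for (b in seq_len(nrow(scheme))) {
    inb <- freq >= scheme$low[b] & freq <= scheme$high[b]
    out[inb] <- scheme$band[b]
  }
  out
}

#' Default measurement schedule
#'
#' Measurement times of the toxicity protocol: every ten minutes for the
#' first hour, then at 90, 120 and 180 minutes.
#'
#' @return Numeric vector of times in seconds.
#' @export
default_schedule <- function() c(seq(0, 3600, by = 600), 5400, 7200, 10800)

#' Band occupancy over a measurement schedule
#'
#' For each scheduled time `T`, takes the spikes in `[T, T + window]`,
#' computes their instantaneous frequencies (each assigned to the window by
#' the first spike of its interval), classifies them into bands, and
#' reports the fraction of frequencies per band (including `"other"`).
#' Windows with fewer than two spikes carry no frequencies and are flagged
#' rather than silently reported as zeros; the same applies to scheduled
#' times beyond the recording span.
#'
#' @param times Strictly increasing spike times, seconds (typically LP).
#' @param schedule Measurement times, seconds (default [default_schedule()]).
#' @param window Window length in seconds (default 60).
#' @param scheme A [band_scheme()].
#' @return An object of class `band_occupancy`: data frame with one row
#'   per scheduled time: `time_s`, `n_freqs`, `flagged` (no measurable
#'   frequencies), and one occupancy column per band plus `other`.
#' @export
band_occupancy <- function(times, schedule = default_schedule(),
                           window = 60, scheme = band_scheme()) {
  check_sorted_times(times, "times")
  stop_if_not_scalar_number(window, "window", min = 0, strict_min = TRUE)
  labs <- band_labels(scheme)
  res <- data.frame(time_s = schedule,
                    n_freqs = 0L,
                    flagged = TRUE,
                    stringsAsFactors = FALSE)
  for (lb in labs) res[[lb]] <- NA_real_
  span_end <- if (length(times)) times[length(times)] else -Inf
  for (i in seq_along(schedule)) {
    T0 <- schedule[i]
    sel <- times >= T0 & times <= T0 + window
    st <- times[sel]
    if (T0 > span_end || length(st) < 2L) next
    fr <- instantaneous_frequencies(st)
    cl <- classify_band(fr, scheme)
    res$n_freqs[i] <- length(fr)
    res$flagged[i] <- FALSE
    for (lb in labs) res[[lb]][i] <- mean(cl == lb)
  }
  structure(res, scheme = scheme, window = window,
            class = c("band_occupancy", "data.frame"))
}

occupancy_matrix <- function(profile) {
  labs <- band_labels(attr(profile, "scheme"))
  as.matrix(profile[, labs, drop = FALSE])
}

#' Total-variation deviation from a control occupancy
#'
#' Scores each scheduled time point of a [band_occupancy()] profile against
#' a control occupancy (measured before dye application) using the
#' total-variation distance `0.5 * sum(|p - q|)`, which is bounded in
#' `[0, 1]`, zero iff the distributions agree, and symmetric. Deviations
#' are classed ordinally at documented cut points (defaults 0.1 and 0.3):
#' `none` < 0.1 <= `moderate` < 0.3 <= `strong`. The `extreme` class is
#' assigned only to flagged time points where spikes were unidentifiable
#' (no measurable frequencies), not from the distance itself.
#'
#' @param profile A [band_occupancy()].
#' @param control Either a single-row [band_occupancy()] (e.g. the pre-dye
#'   window) or a named numeric occupancy vector over the same bands.
#' @param cuts Ascending numeric cut points separating `none`/`moderate`
#'   and `moderate`/`strong`.
#' @return An object of class `deviation_report`: data frame with columns
#'   `time_s`, `deviation` (`NA` for flagged points) and `class` (ordered
#'   factor `none < moderate < strong < extreme`).
#' @export
deviation_from_control <- function(profile, control, cuts = c(0.1, 0.3)) {
  stopifnot(inherits(profile, "band_occupancy"))
  labs <- band_labels(attr(profile, "scheme"))
  if (inherits(control, "band_occupancy")) {
    ctrl_labs <- band_labels(attr(control, "scheme"))
    if (!identical(ctrl_labs, labs))
      stop("band schemes of profile and control differ", call. = FALSE)
    if (nrow(control) != 1L || control$flagged[1])
      stop("control must be a single unflagged occupancy window",
           call. = FALSE)
    q <- as.numeric(control[1, labs])
  } else {
    if (!all(labs %in% names(control)))
      stop("control occupancy does not cover the band scheme",
           call. = FALSE)
    q <- as.numeric(control[labs])
  }
  if (abs(sum(q) - 1) > 1e-8)
    stop("control occupancy must sum to 1", call. = FALSE)
  p <- occupancy_matrix(profile)
  dev <- 0.5 * rowSums(abs(sweep(p, 2, q)))
  cls <- rep("none", nrow(profile))
  cls[!is.na(dev) & dev >= cuts[1]] <- "moderate"
  cls[!is.na(dev) & dev >= cuts[2]] <- "strong"
  cls[profile$flagged] <- "extreme"
  structure(data.frame(time_s = profile$time_s, deviation = dev,
                       class = factor(cls, levels = c("none", "moderate",
                                                      "strong", "extreme"),
                                      ordered = TRUE)),
            cuts = cuts,
            class = c("deviation_report", "data.frame"))
}
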