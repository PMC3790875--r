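# Synthetic 8-bit image stacks: ring-stained somata, exponential
# photobleaching, and dye internalization (interior brightening with a
# distinct nucleus disk).

default_cell_table <- function() {
  data.frame(
    label = c("cell1", "cell2", "cell3"),
    cx = c(12, 34, 24), cy = c(12, 14, 34),
    radius = c(9, 9, 9), ring_width = c(3, 3, 3),
    nucleus_radius = c(3, 3, 3),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic image stack
#'
#' Describes a timestamped sequence of 8-bit greyscale frames showing
#' membrane-ring-stained cell bodies. The ring brightness bleaches as
#' `initial_brightness * exp(-t / bleach_time_constant)`. Optionally, from
#' `internalization_onset` onward, dye migrates into the cytoplasm: the cell
#' interior brightens from the background level toward the (bleaching) ring
#' brightness along a logistic ramp with rate `internalization_rate`, and a
#' nucleus disk at 50% of the interior fluorescence stays visibly distinct.
#'
#' @param width,height Frame size in pixels.
#' @param frame_times Strictly increasing frame times, seconds. The default
#'   emulates photos taken every 10 minutes for one hour.
#' @param cells Data frame with columns `label`, `cx`, `cy` (center, pixels,
#'   1-based), `radius`, `ring_width`, `nucleus_radius`. All cells must lie
#'   within the frame.
#' @param initial_brightness Ring grey value at `t = 0` (0--255).
#' @param background Background grey value (0--255).
#' @param bleach_time_constant Bleaching time constant tau in seconds;
#'   `Inf` disables bleaching.
#' @param internalization_onset Time (s) at which internalization starts;
#'   `NA` (default) for no internalization.
#' @param internalization_rate Logistic rate of the interior brightening,
#'   per second.
#' @param pixel_noise_sd SD of additive Gaussian pixel noise (grey values);
#'   frames are rounded and clipped to 0--255 after noise.
#' @param seed Integer seed for the pixel noise.
#' @return An object of class `stack_spec`.
#' @export
stack_spec <- function(width = 48, height = 48,
                       frame_times = seq(0, 3600, by = 600),
                       cells = default_cell_table(),
                       initial_brightness = 200,
                       background = 20,
                       bleach_time_constant = 1200,
                       internalization_onset = NA_real_,
                       internalization_rate = 0.005,
                       pixel_noise_sd = 0,
                       seed = 1L) {
  stop_if_not_scalar_number(width, "width", min = 4)
  stop_if_not_scalar_number(height, "height", min = 4)
  check_sorted_times(frame_times, "frame_times")
  if (length(frame_times) < 1L) stop("need at least one frame", call. = FALSE)
  stop_if_not_scalar_number(initial_brightness, "initial_brightness", 0, 255)
  stop_if_not_scalar_number(background, "background", 0, 255)
  if (!(is.numeric(bleach_time_constant) && length(bleach_time_constant) == 1 &&
        bleach_time_constant > 0))
    stop("`bleach_time_constant` must be a positive number (Inf allowed)",
         call. = FALSE)
  stop_if_not_scalar_number(pixel_noise_sd, "pixel_noise_sd", min = 0)
  stopifnot(is.data.frame(cells),
            all(c("label", "cx", "cy", "radius", "ring_width",
                  "nucleus_radius") %in% names(cells)))
  if (any(cells$cx - cells$radius < 1 | cells$cx + cells$radius > width |
          cells$cy - cells$radius < 1 | cells$cy + cells$radius > height))
    stop("cells must lie within the frame bounds", call. = FALSE)
  if (any(cells$ring_width <= 0 | cells$ring_width >= cells$radius))
    stop("`ring_width` must be in (0, radius)", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 frame_times = as.numeric(frame_times), cells = cells,
                 initial_brightness = initial_brightness,
                 background = background,
                 bleach_time_constant = bleach_time_constant,
                 internalization_onset = internalization_onset,
                 internalization_rate = internalization_rate,
                 pixel_noise_sd = pixel_noise_sd, seed = seed),
            class = "stack_spec")
}

#' Pixel masks for a ring-stained cell
#'
#' Rasterizes the interior, membrane ring and nucleus of a circular cell on
#' a pixel grid with center-of-pixel inclusion. Masks are logical matrices
#' (rows = y, columns = x, 1-based).
#'
#' @param width,height Frame size in pixels.
#' @param cell One row of a `cells` table (list or data frame row) with
#'   `cx`, `cy`, `radius`, `ring_width`, `nucleus_radius`.
#' @return List of logical matrices `soma` (full disk), `ring`
#'   (annulus `radius - ring_width < d <= radius`), `interior`
#'   (`d <= radius - ring_width`) and `nucleus` (`d <= nucleus_radius`).
#' @export
cell_masks <- function(width, height, cell) {
  x <- matrix(rep(seq_len(width), each = height), nrow = height)
  y <- matrix(rep(seq_len(height), times = width), nrow = height)
  d <- sqrt((x - cell$cx)^2 + (y - cell$cy)^2)
  soma <- d <= cell$radius
  interior <- d <= cell$radius - cell$ring_width
  list(soma = soma, ring = soma & !interior, interior = interior,
       nucleus = d <= cell$nucleus_radius)
}

# Logistic internalization ramp: 0 at onset, -> 1, slope ~ rate.
internalization_ramp <- function(t, onset, rate) {
  if (is.na(onset)) return(rep(0, length(t)))
  ifelse(t < onset, 0, 2 / (1 + exp(-rate * (t - onset))) - 1)
}

#' Render a synthetic image stack
#'
#' Realizes the frames described by a [stack_spec()]. Ring pixels carry the
#' bleaching brightness `initial_brightness * exp(-t / tau)`; interior
#' pixels sit at the background level until internalization lifts them
#' toward the ring brightness; the nucleus disk stays at 50% of the interior
#' fluorescence. Gaussian pixel noise is added before rounding and clipping
#' to the 8-bit range. Ground truth (exact per-frame ring/interior means per
#' cell, internalization state, masks) is returned in `meta`.
#'
#' @param spec A [stack_spec()].
#' @return An object of class `image_stack`: list with `frames` (list of
#'   integer matrices, grey values 0--255), `frame_times`, and `meta`
#'   (ground truth: `ring_brightness`, `interior_brightness` matrices
#'   (frames x cells), `internalized` logical per frame, `masks`, `spec`).
#' @export
render_stack <- function(spec) {
  stopifnot(inherits(spec, "stack_spec"))
  nt <- length(spec$frame_times)
  masks <- lapply(seq_len(nrow(spec$cells)), function(j)
    cell_masks(spec$width, spec$height, as.list(spec$cells[j, ])))
  names(masks) <- spec$cells$label

  tvec <- spec$frame_times
  ring_b <- spec$initial_brightness * exp(-tvec / spec$bleach_time_constant)
  ramp <- internalization_ramp(tvec, spec$internalization_onset,
                               spec$internalization_rate)
  int_b <- spec$background + pmax(ring_b - spec$background, 0) * ramp

  noise <- NULL
  if (spec$pixel_noise_sd > 0)
    noise <- with_seed(spec$seed,
                       rnorm(spec$height * spec$width * nt, 0,
                             spec$pixel_noise_sd))

  frames <- vector("list", nt)
  for (i in seq_len(nt)) {
    fr <- matrix(spec$background, nrow = spec$height, ncol = spec$width)
    for (m in masks) {
      fr[m$interior] <- int_b[i]
      fr[m$nucleus] <- spec$background +
        (int_b[i] - spec$background) * 0.5
      fr[m$ring] <- ring_b[i]
    }
    if (!is.null(noise)) {
      off <- (i - 1L) * spec$height * spec$width
      fr <- fr + matrix(noise[off + seq_len(spec$height * spec$width)],
                        nrow = spec$height)
    }
    frames[[i]] <- matrix(as.integer(pmin(pmax(round(fr), 0), 255)),
                          nrow = spec$height)
  }

  structure(list(frames = frames, frame_times = tvec,
                 meta = list(ring_brightness = ring_b,
                             interior_brightness = int_b,
                             internalized = ramp > 0,
                             masks = masks, spec = spec)),
            class = "image_stack")
}

#' Construct an image stack object from frames
#'
#' @param frames List of integer matrices with grey values 0--255, all of
#'   the same dimensions.
#' @param frame_times Strictly increasing frame times, seconds.
#' @param meta Optional metadata list.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_times, meta = list()) {
  if (!length(frames)) stop("no frames", call. = FALSE)
  dims <- lapply(frames, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all frames must have the same dimensions", call. = FALSE)
  if (length(frame_times) != length(frames))
    stop("`frame_times` must match the number of frames", call. = FALSE)
  check_sorted_times(frame_times, "frame_times")
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < 0 || rng[2] > 255)
    stop("grey values must lie in 0..255 (8-bit)", call. = FALSE)
  structure(list(frames = frames, frame_times = as.numeric(frame_times),
                 meta = meta),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image stack: %d frames of %dx%d px, t = %.4g..%.4g s\n",
              length(x$frames), d[1], d[2],
              min(x$frame_times), max(x$frame_times)))
  invisible(x)
}
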