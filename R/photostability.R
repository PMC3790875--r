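# Bleaching and internalization analysis of 8-bit image stacks.

as_mask <- function(roi, frame) {
  if (is.logical(roi)) {
    if (!identical(dim(roi), dim(frame)))
      stop("ROI mask dimensions do not match the frame", call. = FALSE)
    return(roi)
  }
  stop("`roi` must be a logical mask matrix", call. = FALSE)
}

#' Mean grey value of a region of interest
#'
#' Arithmetic mean of the pixel grey values inside an ROI mask, the
#' standard brightness measure for staining-intensity and bleaching
#' quantification. Saturated pixels (value 255) are included in the mean
#' but counted, since staining can exceed the camera's sensitivity range
#' and saturation must remain visible in quality control.
#'
#' @param frame Integer matrix of grey values 0--255.
#' @param roi Logical mask matrix of the same dimensions with at least one
#'   `TRUE` pixel.
#' @return Mean grey value, with attribute `n_saturated` (count of pixels
#'   at 255 inside the ROI).
#' @export
mean_grey <- function(frame, roi) {
  m <- as_mask(roi, frame)
  if (!any(m)) stop("empty ROI", call. = FALSE)
  px <- frame[m]
  structure(mean(px), n_saturated = sum(px == 255L))
}

#' Bleaching curve of an image stack
#'
#' Per-frame ROI mean grey values, normalized to the brightest picture of
#' the series (usually the first). Optionally fits the exponential decay
#' `grey(t) = a * exp(-t / tau) + b` by nonlinear least squares; the fitted
#' time constant is an added quantification beyond the normalized curve
#' itself and is labelled as such in the output.
#'
#' @param stack An `image_stack` (>= 2 frames).
#' @param roi Logical mask matrix.
#' @param fit If `TRUE` (default), attempt the exponential fit.
#' @return An object of class `bleach_curve`: data frame with columns
#'   `time_s`, `mean_grey`, `normalized` plus attributes `tau` (fitted time
#'   constant in seconds, `NA` when the fit is not possible or the stack
#'   does not decay), `fit` (coefficients `a`, `b`, `tau` or `NULL`) and
#'   `fit_note` marking the fit as a derived quantification.
#' @export
bleach_curve <- function(stack, roi, fit = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) < 2L)
    stop("need at least 2 frames for a bleaching curve", call. = FALSE)
  means <- vapply(stack$frames, function(f) as.numeric(mean_grey(f, roi)),
                  numeric(1))
  if (max(means) <= 0)
    stop("all-zero frames: normalization undefined", call. = FALSE)
  curve <- data.frame(time_s = stack$frame_times, mean_grey = means,
                      normalized = means / max(means))
  tau <- NA_real_
  coefs <- NULL
  if (isTRUE(fit) && diff(range(means)) > 0) {
    b0 <- min(means)
    a0 <- max(means) - b0
    t50 <- stats::approx(means, stack$frame_times,
                         xout = b0 + a0 / 2, ties = "ordered")$y
    tau0 <- if (is.finite(t50) && t50 > 0) t50 / log(2) else
      diff(range(stack$frame_times)) / 2
    ft <- tryCatch(
      minpack.lm::nlsLM(mean_grey ~ b + a * exp(-time_s / tau),
                        data = curve,
                        start = list(a = a0, b = b0, tau = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(ft)) {
      cf <- coef(ft)
      if (is.finite(cf[["tau"]]) && cf[["tau"]] > 0) {
        tau <- unname(cf[["tau"]])
        coefs <- as.list(cf)
      }
    }
  }
  structure(curve, tau = tau, fit = coefs,
            fit_note = "exponential fit is a derived quantification",
            class = c("bleach_curve", "data.frame"))
}

#' Luminosity histogram of a frame
#'
#' Frequency density of pixel brightness over an ROI: 256 bins of width 1
#' covering grey values 0--255, normalized so the densities sum to 1.
#' Right-shifts of the histogram over time reveal dye internalization
#' (interior brightening) despite overall bleaching.
#'
#' @param frame Integer matrix of grey values 0--255.
#' @param roi Logical mask matrix; `NULL` uses the whole frame.
#' @return An object of class `luminosity_histogram`: data frame with
#'   columns `grey` (0--255) and `density`.
#' @export
luminosity_histogram <- function(frame, roi = NULL) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(frame), ncol(frame))
  m <- as_mask(roi, frame)
  if (!any(m)) stop("empty ROI", call. = FALSE)
  px <- as.integer(frame[m])
  if (any(px < 0L | px > 255L))
    stop("grey values outside 0..255", call. = FALSE)
  counts <- tabulate(px + 1L, nbins = 256L)
  structure(data.frame(grey = 0:255, density = counts / sum(counts)),
            class = c("luminosity_histogram", "data.frame"))
}

#' Mean brightness of a luminosity histogram
#'
#' @param hist A [luminosity_histogram()].
#' @return Density-weighted mean grey value.
#' @export
histogram_mean <- function(hist) {
  stopifnot(inherits(hist, "luminosity_histogram"))
  sum(hist$grey * hist$density)
}

#' Detect dye internalization in an image stack
#'
#' Dye internalization moves fluorophore from the membrane ring into the
#' cytoplasm: the cell interior brightens (eventually making the nucleus
#' visible) even while the ring continues to bleach. The quantitative
#' surrogate for that visual call is a per-frame shift statistic: the
#' change, relative to the previous frame, of the mean brightness over the
#' cell-interior mask. Internalization is called at the first frame where
#' the interior brightens beyond `threshold` plus an automatic noise floor
#' (three standard errors of the between-frame difference, estimated from
#' the within-mask pixel scatter) while the concurrent ring change is
#' non-positive within the same noise allowance.
#'
#' @param stack An `image_stack` (>= 2 frames).
#' @param cells List of per-cell mask pairs, each a list with logical
#'   matrices `interior` and `ring`. Defaults to the masks recorded in the
#'   stack's generator metadata, if present.
#' @param threshold Minimum interior brightening per frame, grey values
#'   (default 0; the automatic noise floor is added on top).
#' @return An object of class `internalization_call`: list with `detected`,
#'   `onset_frame` (1-based frame index, `NA` when not detected),
#'   `shift_statistic` (frames x cells matrix of interior changes, first
#'   row `NA`), `ring_change` (same shape), `criterion` (text tag) and
#'   `histogram_shift` (per-frame change of the interior histogram mean,
#'   corroborating output).
#' @export
detect_internalization <- function(stack, cells = NULL, threshold = 0) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- length(stack$frames)
  if (nt < 2L) stop("need at least 2 frames", call. = FALSE)
  if (is.null(cells)) cells <- stack$meta$masks
  if (is.null(cells) || !length(cells))
    stop("no interior/ring masks available: supply `cells`", call. = FALSE)
  for (cl in cells)
    if (is.null(cl$interior) || is.null(cl$ring))
      stop("each cell needs `interior` and `ring` masks", call. = FALSE)

  nc <- length(cells)
  int_mean <- ring_mean <- int_se <- ring_se <- matrix(NA_real_, nt, nc)
  for (j in seq_len(nc)) {
    mi <- cells[[j]]$interior
    mr <- cells[[j]]$ring
    for (i in seq_len(nt)) {
      pi <- stack$frames[[i]][mi]
      pr <- stack$frames[[i]][mr]
      int_mean[i, j] <- mean(pi)
      ring_mean[i, j] <- mean(pr)
      int_se[i, j] <- stats::sd(pi) / sqrt(length(pi))
      ring_se[i, j] <- stats::sd(pr) / sqrt(length(pr))
    }
  }
  d_int <- rbind(NA_real_, diff(int_mean))
  d_ring <- rbind(NA_real_, diff(ring_mean))
  # noise floor for a between-frame difference of mask means
  guard_int <- rbind(NA_real_,
                     3 * sqrt(int_se[-nt, , drop = FALSE]^2 +
                              int_se[-1, , drop = FALSE]^2))
  guard_ring <- rbind(NA_real_,
                      3 * sqrt(ring_se[-nt, , drop = FALSE]^2 +
                               ring_se[-1, , drop = FALSE]^2))
  hit <- d_int > threshold + guard_int & d_ring <= guard_ring
  hit[is.na(hit)] <- FALSE
  detected <- any(hit)
  onset <- if (detected) min(which(apply(hit, 1, any))) else NA_integer_

  hist_means <- vapply(seq_len(nt), function(i) {
    hm <- 0
    for (j in seq_len(nc))
      hm <- hm + histogram_mean(
        luminosity_histogram(stack$frames[[i]], cells[[j]]$interior))
    hm / nc
  }, numeric(1))

  structure(list(detected = detected, onset_frame = onset,
                 shift_statistic = d_int, ring_change = d_ring,
                 criterion = paste("interior brightening above noise floor",
                                   "while ring dims or stays"),
                 threshold = threshold,
                 histogram_shift = c(NA_real_, diff(hist_means))),
            class = "internalization_call")
}

#' @export
print.internalization_call <- function(x, ...) {
  if (x$detected)
    cat(sprintf("internalization detected at frame %d\n", x$onset_frame))
  else cat("no internalization detected\n")
  invisible(x)
}
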