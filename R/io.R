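# Shared readers and writers. Dialects: CSV, comma-separated, UTF-8,
# mandatory header row; TIFF, multi-page 8-bit greyscale with a JSON
# sidecar carrying frame times; JSON for ROIs and configuration.
# Times are seconds everywhere.

#' Write and read spike tables
#'
#' Spike tables are CSV files with columns `neuron` and `time_s`; times
#' must be sorted within each neuron.
#'
#' @param spikes Named list of numeric spike-time vectors.
#' @param path File path.
#' @return `read_spikes()` returns a named list of spike-time vectors;
#'   `write_spikes()` returns `path` invisibly.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(is.list(spikes), length(names(spikes)) == length(spikes))
  df <- do.call(rbind, lapply(names(spikes), function(nm)
    if (length(spikes[[nm]]))
      data.frame(neuron = nm, time_s = spikes[[nm]]) else NULL))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("neuron", "time_s") %in% names(df)))
    stop(sprintf("%s: spike CSV must have columns `neuron` and `time_s`",
                 path), call. = FALSE)
  out <- split(df$time_s, df$neuron)
  for (nm in names(out)) {
    if (is.unsorted(out[[nm]], strictly = FALSE))
      stop(sprintf("%s: spike times for neuron %s are not sorted",
                   path, nm), call. = FALSE)
    out[[nm]] <- as.numeric(out[[nm]])
  }
  out[unique(df$neuron)]
}

#' Write and read fluorescence traces
#'
#' Trace CSVs carry one column per ROI plus a mandatory `sample_interval_s`
#' column (constant) and optionally `start_time_s`; files without the
#' `sample_interval_s` header are rejected.
#'
#' @param traces A [fluor_trace()] or named list of them, all with the
#'   same sampling.
#' @param path File path.
#' @return `read_trace()` returns a named list of [fluor_trace()] objects;
#'   `write_trace()` returns `path` invisibly.
#' @export
write_trace <- function(traces, path) {
  if (inherits(traces, "fluor_trace")) traces <- list(roi1 = traces)
  stopifnot(length(traces) >= 1, !is.null(names(traces)))
  dt <- unique(vapply(traces, function(x) x$sample_interval, numeric(1)))
  t0 <- unique(vapply(traces, function(x) x$start_time, numeric(1)))
  if (length(dt) != 1L || length(t0) != 1L)
    stop("all traces must share sampling and start time", call. = FALSE)
  lens <- vapply(traces, function(x) length(x$values), integer(1))
  if (length(unique(lens)) != 1L)
    stop("all traces must have the same length", call. = FALSE)
  df <- as.data.frame(lapply(traces, function(x) x$values))
  names(df) <- names(traces)
  df$sample_interval_s <- dt
  df$start_time_s <- t0
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_interval_s" %in% names(df))
    stop(sprintf("%s: trace CSV must carry a `sample_interval_s` column",
                 path), call. = FALSE)
  dt <- df$sample_interval_s[1]
  t0 <- if ("start_time_s" %in% names(df)) df$start_time_s[1] else 0
  rois <- setdiff(names(df), c("sample_interval_s", "start_time_s"))
  out <- lapply(rois, function(nm) fluor_trace(df[[nm]], dt, t0))
  names(out) <- rois
  out
}

#' Write and read image stacks
#'
#' Stacks are stored as multi-page 8-bit greyscale TIFF files with a JSON
#' sidecar (`<path>.json`) carrying `frame_times_s` and optional ground
#' truth metadata. Non-8-bit TIFFs are rejected on read.
#'
#' @param stack An `image_stack`.
#' @param path TIFF file path; the sidecar is written next to it.
#' @param sidecar Sidecar path (default `paste0(path, ".json")`).
#' @return `read_stack()` returns an `image_stack`; `write_stack()`
#'   returns `path` invisibly.
#' @export
write_stack <- function(stack, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stack, "image_stack"))
  imgs <- lapply(stack$frames, function(f) f / 255)
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  meta <- list(frame_times_s = stack$frame_times)
  sp <- stack$meta$spec
  if (!is.null(sp)) {
    meta$ground_truth <- list(
      ring_brightness = stack$meta$ring_brightness,
      interior_brightness = stack$meta$interior_brightness,
      internalized = stack$meta$internalized)
    meta$stack_spec <- unclass(sp)[setdiff(names(sp), "cells")]
    meta$cells <- sp$cells
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  for (i in seq_along(imgs)) {
    bps <- attr(imgs[[i]], "bits.per.sample")
    if (!is.null(bps) && bps != 8L)
      stop(sprintf("%s, frame %d: only 8-bit greyscale TIFF is supported (found %d bits per sample)",
                   path, i, bps), call. = FALSE)
    if (length(dim(imgs[[i]])) != 2L)
      stop(sprintf("%s, frame %d: only single-channel greyscale frames are supported",
                   path, i), call. = FALSE)
    if (max(imgs[[i]]) > 255 || min(imgs[[i]]) < 0)
      stop(sprintf("%s, frame %d: grey values outside 0..255", path, i),
           call. = FALSE)
    imgs[[i]] <- matrix(as.integer(imgs[[i]]), nrow = nrow(imgs[[i]]))
  }
  meta <- list()
  frame_times <- seq_along(imgs) - 1
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(sc$frame_times_s)) frame_times <- sc$frame_times_s
    meta$sidecar <- sc
    if (!is.null(sc$cells) && !is.null(sc$stack_spec)) {
      cells <- as.data.frame(sc$cells)
      d <- dim(imgs[[1]])
      meta$masks <- lapply(seq_len(nrow(cells)), function(j)
        cell_masks(d[2], d[1], as.list(cells[j, ])))
      names(meta$masks) <- cells$label
    }
  }
  image_stack(imgs, frame_times, meta = meta)
}

#' Read ROI definitions
#'
#' ROI JSON files contain either `cells` (a table with `label`, `cx`,
#' `cy`, `radius`, `ring_width`, `nucleus_radius`, rasterized with
#' [cell_masks()]) and/or `rect` regions (`label`, `x0`, `y0`, `x1`, `y1`,
#' pixel bounds, inclusive).
#'
#' @param path JSON file path.
#' @param width,height Frame dimensions used to rasterize masks.
#' @return List with `cells` (per-cell mask lists, named by label) and
#'   `rects` (logical mask matrices, named by label).
#' @export
read_roi <- function(path, width, height) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(cells = list(), rects = list())
  if (!is.null(js$cells)) {
    cells <- as.data.frame(js$cells)
    out$cells <- lapply(seq_len(nrow(cells)), function(j)
      cell_masks(width, height, as.list(cells[j, ])))
    names(out$cells) <- cells$label
  }
  if (!is.null(js$rect)) {
    rects <- as.data.frame(js$rect)
    out$rects <- lapply(seq_len(nrow(rects)), function(j) {
      m <- matrix(FALSE, height, width)
      m[rects$y0[j]:rects$y1[j], rects$x0[j]:rects$x1[j]] <- TRUE
      m
    })
    names(out$rects) <- rects$label
  }
  out
}
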