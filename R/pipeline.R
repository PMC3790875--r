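# End-to-end pipeline: simulate -> burst metrics -> S/N -> bleaching ->
# internalization -> toxicity -> report.

pipeline_stage_names <- function()
  c("simulate", "bursts", "snr", "bleach", "internalization", "toxicity")

#' Build a pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. All
#' randomness downstream derives from the single `seed`; per-stage
#' generator seeds are fixed offsets of it. Unknown stage names or
#' parameter blocks are rejected rather than ignored.
#'
#' @param seed Integer master seed.
#' @param stages Character vector of stages to run, in pipeline order; a
#'   subset of `simulate`, `bursts`, `snr`, `bleach`, `internalization`,
#'   `toxicity`. All stages except `simulate` require `simulate`.
#' @param rhythm,optics,stack Parameter lists passed to [rhythm_spec()],
#'   [optics_spec()], [stack_spec()] (seeds are filled in from `seed`).
#' @param pathology Optional parameter list for [pathology_spec()].
#' @param bursts,snr,toxicity Parameter lists: `bursts` takes
#'   `max_intraburst_isi` and `pd_label`; `snr` takes `dc_window`,
#'   `noise_time_base` and `neuron`; `toxicity` takes `schedule`, `window`
#'   and `cuts`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = pipeline_stage_names(),
                            rhythm = list(), optics = list(),
                            stack = list(), pathology = NULL,
                            bursts = list(), snr = list(),
                            toxicity = list()) {
  bad <- setdiff(stages, pipeline_stage_names())
  if (length(bad))
    stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!identical(stages, "simulate") && !("simulate" %in% stages))
    stop("all analysis stages depend on `simulate`; add it to `stages` ",
         "or supply inputs explicitly via the module functions",
         call. = FALSE)
  known <- list(
    rhythm = names(formals(rhythm_spec)),
    optics = names(formals(optics_spec)),
    stack = names(formals(stack_spec)),
    pathology = names(formals(pathology_spec)),
    bursts = c("max_intraburst_isi", "pd_label"),
    snr = c("dc_window", "noise_time_base", "neuron"),
    toxicity = c("schedule", "window", "cuts"))
  blocks <- list(rhythm = rhythm, optics = optics, stack = stack,
                 pathology = pathology, bursts = bursts, snr = snr,
                 toxicity = toxicity)
  for (nm in names(blocks)) {
    if (is.null(blocks[[nm]])) next
    extra <- setdiff(names(blocks[[nm]]), known[[nm]])
    if (length(extra))
      stop(sprintf("unknown key(s) in `%s` block: %s", nm,
                   paste(extra, collapse = ", ")), call. = FALSE)
  }
  structure(c(list(seed = as.integer(seed), stages = stages), blocks),
            class = "pipeline_config")
}

#' Read or write a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("seed", "stages", "rhythm", "optics", "stack", "pathology",
               "bursts", "snr", "toxicity")
  extra <- setdiff(names(js), allowed)
  if (length(extra))
    stop("unknown key(s) in pipeline config: ",
         paste(extra, collapse = ", "), call. = FALSE)
  as_block <- function(x) if (is.null(x)) list() else as.list(x)
  pipeline_config(seed = js$seed,
                  stages = unlist(js$stages),
                  rhythm = as_block(js$rhythm),
                  optics = as_block(js$optics),
                  stack = as_block(js$stack),
                  pathology = if (is.null(js$pathology)) NULL else
                    as.list(js$pathology),
                  bursts = as_block(js$bursts),
                  snr = as_block(js$snr),
                  toxicity = as_block(js$toxicity))
}

#' Run the end-to-end pipeline
#'
#' Executes the configured stages in order on synthetic data: `simulate`
#' generates the rhythm, an LP fluorescence trace and an image stack;
#' `bursts` computes per-cycle pattern statistics; `snr` the
#' cycle-triggered signal-to-noise ratio; `bleach` the normalized
#' bleaching curve; `internalization` the internalization call; `toxicity`
#' the band-occupancy deviation from the first (pre-exposure) window. Any
#' stage failure aborts with the stage name. Output files (when `out_dir`
#' is given) are listed in the report with MD5 checksums; warnings are
#' collected per stage, never suppressed.
#'
#' @param config A [pipeline_config()], or a path to its JSON form.
#' @param out_dir Optional output directory; when given, spike tables,
#'   traces, stacks, per-stage CSV/JSON results and the report are
#'   written there.
#' @return A list of class `run_report`: `seed`, `stages` (per-stage
#'   parameters and result summaries), `warnings`, `files` (data frame
#'   `path`, `md5`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(seed = config$seed, stages = list(),
                 warnings = character(0))
  files <- character(0)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    wh <- function(w) {
      report$warnings <<- c(report$warnings,
                            sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e)
        stop(sprintf("pipeline stage `%s` failed: %s", name,
                     conditionMessage(e)), call. = FALSE)),
      warning = wh)
    report$stages[[name]] <<- res
  }

  for (stage in intersect(pipeline_stage_names(), config$stages)) {
    switch(stage,
      simulate = run_stage("simulate", function() {
        rs <- do.call(rhythm_spec,
                      utils::modifyList(list(seed = config$seed),
                                        config$rhythm))
        ps <- if (length(config$pathology))
          do.call(pathology_spec,
                  utils::modifyList(list(seed = config$seed + 1L),
                                    config$pathology)) else NULL
        state$rhythm <- generate_rhythm(rs, ps)
        os <- do.call(optics_spec,
                      utils::modifyList(list(seed = config$seed + 2L),
                                        config$optics))
        neuron <- config$snr$neuron %||% "LP"
        state$trace <- render_fluorescence(state$rhythm, os, neuron = neuron)
        ss <- do.call(stack_spec,
                      utils::modifyList(list(seed = config$seed + 3L),
                                        config$stack))
        state$stack <- render_stack(ss)
        if (!is.null(out_dir)) {
          files <<- c(files,
                      write_spikes(state$rhythm$spikes,
                                   file.path(out_dir, "spikes.csv")),
                      write_trace(state$trace,
                                  file.path(out_dir, "trace.csv")),
                      write_stack(state$stack,
                                  file.path(out_dir, "stack.tiff")),
                      file.path(out_dir, "stack.tiff.json"))
        }
        list(n_cycles = rs$n_cycles, cycle_period = rs$cycle_period,
             n_spikes = vapply(state$rhythm$spikes, length, integer(1)),
             pathology = if (is.null(ps)) "none" else
               unclass(ps)[c("missing_spike_prob", "tonic_switch",
                             "onset_time")])
      }),
      bursts = run_stage("bursts", function() {
        pars <- utils::modifyList(list(max_intraburst_isi = 0.25,
                                       pd_label = "PD"), config$bursts)
        cm <- cycle_metrics(state$rhythm$spikes, pd_label = pars$pd_label,
                            max_intraburst_isi = pars$max_intraburst_isi)
        if (!is.null(out_dir)) {
          f <- file.path(out_dir, "cycle_metrics.csv")
          write.csv(cm, f, row.names = FALSE)
          files <<- c(files, f)
        }
        list(parameters = pars,
             n_cycles = length(unique(cm$cycle)),
             mean_cycle_period = mean(cm$cycle_period),
             mean_onset_phase = vapply(split(cm$onset_phase, cm$neuron),
                                       mean, numeric(1)))
      }),
      snr = run_stage("snr", function() {
        pars <- utils::modifyList(list(dc_window = 3, noise_time_base = 0.01,
                                       neuron = "LP"), config$snr)
        b <- state$rhythm$bursts
        trig <- b$onset[b$neuron == pars$neuron]
        res <- compute_snr(state$trace, trig, dc_window = pars$dc_window,
                           noise_time_base = pars$noise_time_base)
        if (!is.null(out_dir)) {
          f <- file.path(out_dir, "snr.json")
          jsonlite::write_json(list(amplitude = res$amplitude,
                                    noise_sd = res$noise_sd, snr = res$snr,
                                    n_cycles = res$n_cycles,
                                    cycle_period_s = res$cycle_period),
                               f, auto_unbox = TRUE, digits = NA)
          fw <- file.path(out_dir, "snr_waveform.csv")
          write.csv(data.frame(
            time_s = (seq_along(res$waveform) - 1) * state$trace$sample_interval,
            value = res$waveform), fw, row.names = FALSE)
          files <<- c(files, f, fw)
        }
        list(parameters = pars[c("dc_window", "noise_time_base", "neuron")],
             amplitude = res$amplitude, noise_sd = res$noise_sd,
             snr = res$snr, n_cycles = res$n_cycles)
      }),
      bleach = run_stage("bleach", function() {
        masks <- state$stack$meta$masks
        roi <- Reduce(`|`, lapply(masks, `[[`, "soma"))
        bc <- bleach_curve(state$stack, roi)
        if (!is.null(out_dir)) {
          f <- file.path(out_dir, "bleach_curve.csv")
          write.csv(as.data.frame(bc), f, row.names = FALSE)
          files <<- c(files, f)
        }
        list(normalized = bc$normalized, tau_s = attr(bc, "tau"),
             fit_note = attr(bc, "fit_note"))
      }),
      internalization = run_stage("internalization", function() {
        ic <- detect_internalization(state$stack)
        if (!is.null(out_dir)) {
          f <- file.path(out_dir, "internalization.json")
          jsonlite::write_json(list(detected = ic$detected,
                                    onset_frame = ic$onset_frame,
                                    criterion = ic$criterion),
                               f, auto_unbox = TRUE, digits = NA)
          files <<- c(files, f)
        }
        list(detected = ic$detected, onset_frame = ic$onset_frame)
      }),
      toxicity = run_stage("toxicity", function() {
        pars <- utils::modifyList(list(schedule = default_schedule(),
                                       window = 60, cuts = c(0.1, 0.3)),
                                  config$toxicity)
        lp <- state$rhythm$spikes$LP
        prof <- band_occupancy(lp, schedule = pars$schedule,
                               window = pars$window)
        ctrl <- band_occupancy(lp, schedule = pars$schedule[1],
                               window = pars$window)
        dev <- deviation_from_control(prof, ctrl, cuts = pars$cuts)
        if (!is.null(out_dir)) {
          f1 <- file.path(out_dir, "occupancy.csv")
          write.csv(as.data.frame(prof), f1, row.names = FALSE)
          f2 <- file.path(out_dir, "deviation.json")
          jsonlite::write_json(list(time_s = dev$time_s,
                                    deviation = dev$deviation,
                                    class = as.character(dev$class)),
                               f2, digits = NA)
          files <<- c(files, f1, f2)
        }
        list(parameters = pars[c("window", "cuts")],
             deviation = dev$deviation, class = as.character(dev$class))
      }))
  }

  checks <- if (length(files))
    data.frame(path = files, md5 = unname(tools::md5sum(files)),
               stringsAsFactors = FALSE)
  else data.frame(path = character(0), md5 = character(0))
  report$files <- checks
  report <- structure(report, class = "run_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(seed = report$seed, stages = report$stages,
                              warnings = report$warnings,
                              files = report$files),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d): stages %s\n", x$seed,
              paste(names(x$stages), collapse = " -> ")))
  if (length(x$warnings))
    cat(sprintf("  %d warning(s)\n", length(x$warnings)))
  invisible(x)
}
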