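#' Detect and count steps in a magnetometer trace
#'
#' Runs the full streaming step-detection pipeline on a single-axis field
#' trace: samples are pushed through the three-subblock circular buffer;
#' each full block is low-pass filtered with the previous (historical)
#' block as warm-up, so block-wise filtering equals single-pass filtering
#' exactly; local extrema of the filtered stream are detected incrementally
#' across block boundaries; sub-threshold extrema pairs are rejected by the
#' complementary-extremum test; and extrema falling in motionless
#' (standing) blocks are discarded. Every surviving extremum is one step.
#' Reported step times are corrected for the filter group delay.
#'
#' Two finite-trace details differ from an endless real-time stream: the
#' first block, having no history, is warmed up on a replicate of its first
#' sample (flagged in the report), and at end of stream the partial pending
#' block plus a held-last-value tail are flushed through the filter so the
#' group-delayed images of the final samples are not lost. Extrema are kept
#' only if their delay-corrected time lies within the recorded trace.
#'
#' @param x A [sample_series()], a [simulate_walk()] result (its series is
#'   used), or a plain numeric vector (assumed uT at 40 Hz). Traces in raw
#'   counts are converted to uT first.
#' @param filter A [design_lowpass()] specification.
#' @param control A [detector_config()]; its `block_size` must exceed the
#'   filter order.
#' @param sensor A [sensor_spec()], used only to convert `"lsb"` traces.
#' @return An object of class `"step_report"`: list with `step_count`,
#'   `step_events` (data frame `time_s`, `index`, `value`, `kind`),
#'   `raw_extrema_count`, `rejected_by_threshold`, `rejected_by_motionless`,
#'   `moving` (per-block motion flags), `filtered` (the filtered trace as a
#'   [sample_series()]), `warm_up` flag, plus the configurations used.
#' @examples
#' tr <- simulate_walk(gait_sim_config(walk_speed_kmh = 5, seed = 1))
#' rep <- detect_steps(tr)
#' rep
#' @export
detect_steps <- function(x,
                         filter = design_lowpass(),
                         control = detector_config(),
                         sensor = sensor_spec()) {
  series <- if (inherits(x, "mag_trace")) x$series
            else if (inherits(x, "sample_series")) x
            else sample_series(x)
  if (series$units == "lsb") series <- convert_units(series, "uT", sensor)
  stopifnot(inherits(filter, "fir_spec"), inherits(control, "detector_config"))
  if (control$block_size < filter$order + 1)
    stop("block_size must be at least filter order + 1")

  values <- series$values
  fs <- series$sampling_hz
  n <- length(values)
  if (n < control$block_size) {
    warning("trace shorter than one block; no steps detected")
    return(empty_step_report(series, filter, control))
  }

  bb <- block_buffer(control$block_size)
  st <- extrema_stream()
  filtered <- numeric(0)
  extrema <- NULL
  warm_up <- FALSE
  last_hist <- NULL   # raw samples backing the final flush

  process <- function(hist_raw, cur_raw) {
    if (length(hist_raw) < filter$order) {
      warm_up <<- TRUE
      hist_raw <- rep(cur_raw[1], filter$order)
    }
    fb <- filter_block(hist_raw, cur_raw, filter)
    filtered <<- c(filtered, fb)
    ex <- extrema_stream_feed(st, fb)
    extrema <<- rbind(extrema, ex)
  }

  for (s in values) {
    if (buffer_push(bb, s)) {
      buffer_swap(bb)
      process(bb$historical, bb$current)
      last_hist <- bb$current
    }
  }
  if (length(bb$pending) > 0) {
    tail_raw <- bb$pending
    process(last_hist, tail_raw)
    last_hist <- c(last_hist, tail_raw)
  }
  # flush the group delay with a held-last-value tail
  pad <- ceiling(filter$group_delay)
  if (pad > 0) {
    process(last_hist, rep(values[n], pad))
  }

  if (is.null(extrema)) {
    extrema <- data.frame(index = integer(0), value = numeric(0),
                          kind = character(0), stringsAsFactors = FALSE)
  }
  # delay-corrected times; keep extrema whose image lies inside the trace
  time_s <- series$start_time + (extrema$index - 1 - filter$group_delay) / fs
  inside <- time_s >= series$start_time - 1e-9 &
            time_s <= series$start_time + n / fs + 1e-9
  extrema <- extrema[inside, , drop = FALSE]
  time_s <- time_s[inside]
  extrema$time_s <- time_s
  raw_count <- nrow(extrema)

  accepted <- threshold_filter(extrema, control$fake_step_threshold_uT)
  rej_thr <- raw_count - nrow(accepted)

  mf <- motionless_filter(filtered, accepted, control)
  rej_motion <- nrow(accepted) - nrow(mf$extrema)
  steps <- mf$extrema

  structure(
    list(step_count = nrow(steps),
         step_events = steps[, c("time_s", "index", "value", "kind")],
         raw_extrema_count = raw_count,
         rejected_by_threshold = rej_thr,
         rejected_by_motionless = rej_motion,
         moving = mf$moving,
         filtered = sample_series(filtered, fs, series$start_time, "uT"),
         warm_up = warm_up,
         n_samples = n,
         filter = filter,
         control = control),
    class = "step_report")
}

empty_step_report <- function(series, filter, control) {
  structure(
    list(step_count = 0L,
         step_events = data.frame(time_s = numeric(0), index = integer(0),
                                  value = numeric(0), kind = character(0),
                                  stringsAsFactors = FALSE),
         raw_extrema_count = 0L,
         rejected_by_threshold = 0L,
         rejected_by_motionless = 0L,
         moving = logical(0),
         filtered = sample_series(numeric(0), series$sampling_hz,
                                  series$start_time, "uT"),
         warm_up = TRUE,
         n_samples = length(series$values),
         filter = filter,
         control = control),
    class = "step_report")
}

#' @export
print.step_report <- function(x, ...) {
  cat(sprintf("Step detection: %d steps over %.1f s (%d samples)\n",
              x$step_count, x$n_samples / x$filtered$sampling_hz,
              x$n_samples))
  cat(sprintf(
    "  extrema: %d raw, %d rejected by %.2g uT threshold, %d in motionless blocks\n",
    as.integer(x$raw_extrema_count), as.integer(x$rejected_by_threshold),
    x$control$fake_step_threshold_uT, as.integer(x$rejected_by_motionless)))
  invisible(x)
}

#' @export
summary.step_report <- function(object, ...) {
  cat(sprintf("Steps detected: %d\n", object$step_count))
  cat(sprintf("Raw extrema: %d (peak/valley alternation)\n",
              object$raw_extrema_count))
  cat(sprintf("Rejected as fake steps (< %.2g uT gap): %d\n",
              object$control$fake_step_threshold_uT,
              object$rejected_by_threshold))
  cat(sprintf("Rejected in motionless blocks: %d (of %d blocks, %d moving)\n",
              object$rejected_by_motionless, length(object$moving),
              sum(object$moving)))
  if (object$step_count > 1) {
    dt <- diff(object$step_events$time_s)
    cat(sprintf("Median step interval: %.3f s (cadence %.2f steps/s)\n",
                stats::median(dt), 1 / stats::median(dt)))
  }
  if (object$warm_up)
    cat("First block warm-up used replicated-sample history\n")
  invisible(object)
}

#' @export
plot.step_report <- function(x, ...) {
  f <- x$filtered
  graphics::plot(sample_times(f) - x$filter$group_delay / f$sampling_hz,
                 f$values, type = "l",
                 xlab = "time [s]", ylab = "filtered Bz [uT]",
                 main = sprintf("%d detected steps", x$step_count), ...)
  graphics::points(x$step_events$time_s, x$step_events$value,
                   col = ifelse(x$step_events$kind == "peak", "red", "blue"),
                   pch = 19, cex = 0.6)
  invisible(x)
}
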