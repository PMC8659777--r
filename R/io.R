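#' Write and read magnetometer traces as CSV
#'
#' Traces are exchanged as CSV with header `time_s,bx_uT,by_uT,bz_uT`; the
#' pipeline analyses the Z column only, so the simulator fills `bx`/`by`
#' with the baseline field. Ground-truth step times, when present, go to a
#' sidecar CSV with the single column `step_time_s`.
#'
#' @param x A [sample_series()] or [simulate_walk()] result.
#' @param file Path of the trace CSV.
#' @param truth_file Optional sidecar path for ground-truth step times
#'   (written only when `x` is a `mag_trace`).
#' @return `file`, invisibly.
#' @export
write_trace <- function(x, file, truth_file = NULL) {
  series <- if (inherits(x, "mag_trace")) x$series else x
  stopifnot(inherits(series, "sample_series"))
  series <- convert_units(series, "uT")
  bg <- if (inherits(x, "mag_trace")) x$config$field_mean_uT else 0
  df <- data.frame(time_s = sample_times(series),
                   bx_uT = bg, by_uT = bg, bz_uT = series$values)
  utils::write.csv(df, file, row.names = FALSE)
  if (!is.null(truth_file) && inherits(x, "mag_trace")) {
    utils::write.csv(data.frame(step_time_s = x$truth$step_times),
                     truth_file, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_trace
#' @param axis Which field column to read (`"z"`, `"x"` or `"y"`).
#' @param sampling_hz Sampling rate to assume if the time column is absent;
#'   otherwise inferred from the median time step.
#' @return `read_trace()`: a [sample_series()] in uT.
#' @export
read_trace <- function(file, axis = c("z", "x", "y"), sampling_hz = 40) {
  axis <- match.arg(axis)
  df <- utils::read.csv(file)
  col <- paste0("b", axis, "_uT")
  if (!col %in% names(df)) stop("column ", col, " not found in ", file)
  start <- 0
  if ("time_s" %in% names(df) && nrow(df) > 1) {
    dt <- stats::median(diff(df$time_s))
    if (dt <= 0) stop("non-increasing time column")
    sampling_hz <- 1 / dt
    start <- df$time_s[1]
  }
  sample_series(df[[col]], sampling_hz, start, "uT")
}
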