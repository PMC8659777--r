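#' Magnetometer sensor description
#'
#' Describes the digital magnetometer whose output the pipeline processes:
#' a 3-axis sensor sampled at 40 Hz with 16-bit resolution over +/- 1000 uT,
#' a sensitivity of 0.1 uT per count and an RMS noise level of 0.25 uT.
#' Only the Z axis is analysed; these defaults match that datasheet and are
#' used both by the simulator (noise, quantization) and for unit conversion
#' of recorded traces.
#'
#' @param sampling_hz Sampling frequency in Hz.
#' @param resolution_bits ADC resolution in bits.
#' @param full_range_uT Full measurement range (+/-) in microtesla.
#' @param sensitivity_uT_per_lsb Field increment represented by one count.
#' @param noise_sigma_uT Standard deviation of the sensor noise in microtesla.
#'
#' @return An object of class `"sensor_spec"`.
#' @examples
#' sensor_spec()
#' @export
sensor_spec <- function(sampling_hz = 40,
                        resolution_bits = 16,
                        full_range_uT = 1000,
                        sensitivity_uT_per_lsb = 0.1,
                        noise_sigma_uT = 0.25) {
  stopifnot(sampling_hz > 0, sensitivity_uT_per_lsb > 0, noise_sigma_uT >= 0,
            full_range_uT > 0, resolution_bits >= 1)
  # counts needed to span the full +/- range at the stated sensitivity
  needed <- 2 * full_range_uT / sensitivity_uT_per_lsb
  if (needed > 2^resolution_bits) {
    warning(sprintf(
      "full range +/-%g uT at %g uT/LSB needs %g counts; %d bits give %g",
      full_range_uT, sensitivity_uT_per_lsb, needed, resolution_bits,
      2^resolution_bits))
  }
  structure(
    list(sampling_hz = sampling_hz,
         resolution_bits = resolution_bits,
         full_range_uT = full_range_uT,
         sensitivity_uT_per_lsb = sensitivity_uT_per_lsb,
         noise_sigma_uT = noise_sigma_uT),
    class = "sensor_spec")
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat(sprintf(
    "Magnetometer: %g Hz, %d bit, +/-%g uT, %g uT/LSB, noise sigma %g uT\n",
    x$sampling_hz, x$resolution_bits, x$full_range_uT,
    x$sensitivity_uT_per_lsb, x$noise_sigma_uT))
  invisible(x)
}

#' Uniformly sampled single-axis field trace
#'
#' Container for a single-axis (Z) magnetic field time series with its
#' sampling rate, start time and units -- either microtesla (`"uT"`) or raw
#' sensor counts (`"lsb"`).
#'
#' @param values Numeric vector of field samples.
#' @param sampling_hz Sampling frequency in Hz.
#' @param start_time Time of the first sample, seconds.
#' @param units `"uT"` or `"lsb"`.
#' @return An object of class `"sample_series"`.
#' @examples
#' s <- sample_series(sin(2 * pi * 1 * seq(0, 2, by = 1 / 40)))
#' s
#' @export
sample_series <- function(values, sampling_hz = 40, start_time = 0,
                          units = c("uT", "lsb")) {
  units <- match.arg(units)
  stopifnot(is.numeric(values), sampling_hz > 0)
  structure(
    list(values = as.numeric(values), sampling_hz = sampling_hz,
         start_time = start_time, units = units),
    class = "sample_series")
}

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf("Field trace: %d samples @ %g Hz (%.2f s), units %s\n",
              length(x$values), x$sampling_hz,
              length(x$values) / x$sampling_hz, x$units))
  invisible(x)
}

#' @export
length.sample_series <- function(x) length(x$values)

#' Sample times of a trace
#'
#' @param series A [sample_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
sample_times <- function(series) {
  series$start_time + (seq_along(series$values) - 1) / series$sampling_hz
}

#' Convert a trace between microtesla and raw counts
#'
#' Conversion uses the sensor sensitivity (uT per LSB); counts are integers,
#' so a uT -> lsb -> uT round trip changes each sample by at most half a
#' count (0.05 uT at the 0.1 uT/LSB default).
#'
#' @param series A [sample_series()].
#' @param units Target units, `"uT"` or `"lsb"`.
#' @param sensor A [sensor_spec()] supplying the sensitivity.
#' @return The converted [sample_series()].
#' @examples
#' s <- sample_series(c(1.23, -0.47))
#' convert_units(convert_units(s, "lsb"), "uT")$values
#' @export
convert_units <- function(series, units = c("uT", "lsb"),
                          sensor = sensor_spec()) {
  units <- match.arg(units)
  stopifnot(inherits(series, "sample_series"))
  if (identical(series$units, units)) return(series)
  k <- sensor$sensitivity_uT_per_lsb
  values <- if (units == "lsb") round(series$values / k) else series$values * k
  sample_series(values, series$sampling_hz, series$start_time, units)
}
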