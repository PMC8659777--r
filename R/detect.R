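#' Detector configuration
#'
#' Tunable thresholds of the step classifier. The fake-step threshold is
#' the minimum amplitude gap between an extremum and the previously
#' accepted (complementary) one for it to count as a step: 0.5 uT, twice
#' the sensor noise level, determined as the average adjacent-extrema gap
#' in disturbance-free recordings. The motionless threshold is the minimum
#' per-block mean absolute deviation of the filtered signal for a block to
#' count as movement; the default is 3x the mean absolute deviation of
#' pure sensor noise at the datasheet sigma of 0.25 uT
#' (`3 * 0.25 * sqrt(2/pi) ~= 0.6 uT`), and can be recalibrated from
#' standing recordings with [calibrate_motionless_threshold()].
#'
#' @param fake_step_threshold_uT Minimum peak-to-valley gap in uT.
#' @param motionless_threshold_uT Block deviation below which the block is
#'   labelled motionless and its extrema discarded, uT.
#' @param block_size Samples per processing block.
#' @return An object of class `"detector_config"`.
#' @export
detector_config <- function(fake_step_threshold_uT = 0.5,
                            motionless_threshold_uT = 0.6,
                            block_size = 80) {
  stopifnot(fake_step_threshold_uT >= 0, motionless_threshold_uT >= 0,
            block_size >= 1)
  structure(
    list(fake_step_threshold_uT = fake_step_threshold_uT,
         motionless_threshold_uT = motionless_threshold_uT,
         block_size = as.integer(block_size)),
    class = "detector_config")
}

# Strict local extrema of a run-length-encoded value sequence.
# A run is a peak (valley) iff both flanking runs are strictly lower
# (higher); the extremum index is the run's first sample. Interior runs
# only -- a plateau touching either end of `values` cannot be classified.
extrema_of_runs <- function(values, offset = 0L) {
  r <- rle(values)
  k <- length(r$values)
  if (k < 3) {
    return(data.frame(index = integer(0), value = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  starts <- cumsum(c(1L, r$lengths[-k]))
  v <- r$values
  j <- 2:(k - 1)
  peak <- v[j] > v[j - 1] & v[j] > v[j + 1]
  valley <- v[j] < v[j - 1] & v[j] < v[j + 1]
  sel <- j[peak | valley]
  data.frame(index = starts[sel] + offset,
             value = v[sel],
             kind = ifelse(v[sel] > v[sel - 1], "peak", "valley"),
             stringsAsFactors = FALSE)
}

#' Detect local peaks and valleys
#'
#' Classifies every interior point whose neighbours are strictly lower
#' (peak) or strictly higher (valley). A plateau -- a run of equal values
#' flanked by lower (higher) values on both sides -- is reported as a
#' single peak (valley) at the run's first index. Retained extrema
#' alternate peak/valley by construction.
#'
#' @param x A [sample_series()] or numeric vector (typically the filtered
#'   signal); fewer than 3 samples yield an empty result.
#' @return Data frame with columns `index` (1-based sample position),
#'   `value`, and `kind` (`"peak"` or `"valley"`), in index order.
#' @examples
#' detect_extrema(c(1, 3, 1))   # one peak at index 2
#' detect_extrema(c(3, 1, 3))   # one valley at index 2
#' @export
detect_extrema <- function(x) {
  values <- if (inherits(x, "sample_series")) x$values else as.numeric(x)
  if (length(values) < 3) {
    return(data.frame(index = integer(0), value = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  extrema_of_runs(values)
}

# Streaming extrema detector over run-length state: O(1) memory, exact.
# Keeps the last two closed runs plus the run being built; a run is
# classified the moment the following run opens, so feeding a stream block
# by block emits exactly the extrema detect_extrema() finds on the whole
# stream, regardless of where block boundaries fall (including plateaus
# spanning blocks).
extrema_stream <- function() {
  st <- new.env(parent = emptyenv())
  st$prev_val <- NA_real_   # run before the current one
  st$run_val <- NA_real_    # value of the run being built
  st$run_start <- NA_integer_
  st$n_seen <- 0L
  st
}

extrema_stream_feed <- function(st, block) {
  out_idx <- integer(0); out_val <- numeric(0); out_kind <- character(0)
  for (s in block) {
    st$n_seen <- st$n_seen + 1L
    if (is.na(st$run_val)) {
      st$run_val <- s
      st$run_start <- st$n_seen
    } else if (s != st$run_val) {
      # current run closes; classify it if it has both flanks
      if (!is.na(st$prev_val)) {
        if (st$run_val > st$prev_val && st$run_val > s) {
          out_idx <- c(out_idx, st$run_start)
          out_val <- c(out_val, st$run_val)
          out_kind <- c(out_kind, "peak")
        } else if (st$run_val < st$prev_val && st$run_val < s) {
          out_idx <- c(out_idx, st$run_start)
          out_val <- c(out_val, st$run_val)
          out_kind <- c(out_kind, "valley")
        }
      }
      st$prev_val <- st$run_val
      st$run_val <- s
      st$run_start <- st$n_seen
    }
  }
  data.frame(index = out_idx, value = out_val, kind = out_kind,
             stringsAsFactors = FALSE)
}

# Collapse runs of same-kind extrema to the most extreme one, restoring the
# peak-valley alternation the threshold test assumes.
normalize_alternating <- function(extrema) {
  n <- nrow(extrema)
  if (n < 2) return(extrema)
  keep <- logical(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && extrema$kind[j + 1] == extrema$kind[i]) j <- j + 1
    run <- i:j
    best <- if (extrema$kind[i] == "peak") run[which.max(extrema$value[run])]
            else run[which.min(extrema$value[run])]
    keep[best] <- TRUE
    i <- j + 1
  }
  extrema[keep, , drop = FALSE]
}

#' Reject fake steps with the complementary-extremum threshold test
#'
#' Greedy left-to-right scan over an alternating peak/valley sequence.
#' The first extremum is accepted. Each later candidate of the kind
#' complementary to the last accepted extremum is compared to it: if the
#' amplitude gap reaches the threshold the candidate is accepted and both
#' extrema stand as steps; otherwise the candidate is skipped *together
#' with* the immediately following extremum (which, in an alternating
#' sequence, has the same kind as the last accepted one), and the test is
#' repeated with the next complementary extremum. Sub-threshold
#' peak/valley wiggles from ambient field fluctuations are thereby removed
#' without breaking the alternation.
#'
#' @param extrema Data frame as returned by [detect_extrema()]. Input that
#'   does not alternate is first normalized (each same-kind run reduced to
#'   its most extreme member) with a warning.
#' @param threshold_uT Minimum gap in uT; 0 makes the filter the identity.
#' @return The accepted subset of `extrema` (row order preserved).
#' @examples
#' ex <- data.frame(index = 1:3, value = c(10, 9.8, 10.1),
#'                  kind = c("peak", "valley", "peak"))
#' threshold_filter(ex, 0.5)   # only the first peak survives
#' @export
threshold_filter <- function(extrema, threshold_uT = 0.5) {
  stopifnot(threshold_uT >= 0)
  n <- nrow(extrema)
  if (n == 0) return(extrema)
  if (n > 1 && any(extrema$kind[-1] == extrema$kind[-n])) {
    warning("extrema do not alternate; normalizing same-kind runs")
    extrema <- normalize_alternating(extrema)
    n <- nrow(extrema)
  }
  accept <- logical(n)
  accept[1] <- TRUE
  last <- 1
  i <- 2
  while (i <= n) {
    if (extrema$kind[i] == extrema$kind[last]) {
      i <- i + 1              # not complementary to the last accepted
    } else if (abs(extrema$value[i] - extrema$value[last]) >= threshold_uT) {
      accept[i] <- TRUE
      last <- i
      i <- i + 1
    } else {
      i <- i + 2              # skip candidate and the following same-kind one
    }
  }
  extrema[accept, , drop = FALSE]
}

#' Calibrate the motionless threshold from standing recordings
#'
#' The motionless detector compares each block's mean absolute deviation
#' (MAD about the block mean) against a constant. That constant is
#' calibrated as the average MAD over recordings collected while standing
#' still, times a safety factor. For pure Gaussian sensor noise the MAD is
#' `sigma * sqrt(2/pi)` (about 0.199 uT at sigma = 0.25 uT), so the default
#' factor of 3 puts the threshold at ~0.6 uT -- well below the deviation
#' of any detectable walk, whose swing must exceed the 0.5 uT step gap.
#'
#' @param standing_traces A list of [sample_series()] (or numeric vectors)
#'   recorded during motionless phases.
#' @param safety_factor Multiplier applied to the average deviation.
#' @return Threshold in uT.
#' @export
calibrate_motionless_threshold <- function(standing_traces, safety_factor = 3) {
  if (length(standing_traces) == 0) stop("need at least one standing trace")
  mads <- vapply(standing_traces, function(s) {
    v <- if (inherits(s, "sample_series")) s$values else as.numeric(s)
    mean(abs(v - mean(v)))
  }, numeric(1))
  safety_factor * mean(mads)
}

# Per-block motion labels: TRUE where the block's mean absolute deviation
# reaches the threshold. `values` is the filtered signal.
motion_labels <- function(values, block_size, threshold_uT) {
  n <- length(values)
  if (n == 0) return(logical(0))
  blk <- ((seq_len(n) - 1) %/% block_size) + 1
  dev <- tapply(values, blk, function(v) mean(abs(v - mean(v))))
  as.vector(dev) >= threshold_uT
}

#' Discard extrema detected during motionless phases
#'
#' Splits the filtered signal into consecutive blocks, computes each
#' block's mean absolute deviation about its mean, labels blocks below the
#' threshold as motionless (standing), and discards extrema falling in
#' them. This is the final classification stage: residual noise extrema
#' during a walk halt survive the amplitude test only rarely, but here the
#' whole standing phase is excluded at once.
#'
#' @param x A [sample_series()] or numeric vector of the *filtered* signal.
#' @param extrema Data frame of extrema (with `index` into `x`).
#' @param config A [detector_config()] supplying block size and threshold.
#' @return List with `extrema` (surviving rows) and `moving` (logical,
#'   one flag per block, `TRUE` = movement).
#' @export
motionless_filter <- function(x, extrema, config = detector_config()) {
  values <- if (inherits(x, "sample_series")) x$values else as.numeric(x)
  moving <- motion_labels(values, config$block_size,
                          config$motionless_threshold_uT)
  if (nrow(extrema) == 0) return(list(extrema = extrema, moving = moving))
  blk <- ((extrema$index - 1L) %/% config$block_size) + 1L
  keep <- blk >= 1 & blk <= length(moving)
  keep[keep] <- moving[blk[keep]]
  list(extrema = extrema[keep, , drop = FALSE], moving = moving)
}
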