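#' Three-subblock circular buffer for streaming samples
#'
#' The streaming pipeline keeps three equal blocks of samples: *historical*
#' (already processed, retained so the next stage can warm up its filter and
#' resolve extrema at block edges), *current* (ready for processing) and
#' *pending* (filling with incoming samples). When pending fills, a swap
#' rotates the roles: current becomes historical, pending becomes current,
#' and the old historical slot is cleared to receive new samples. Memory is
#' therefore fixed at three blocks regardless of stream length. Samples
#' arriving between the fill signal and the swap are staged in a small
#' overflow FIFO and are never dropped.
#'
#' The buffer has reference semantics (it is an environment):
#' [buffer_push()] and [buffer_swap()] modify it in place.
#'
#' @param block_size Samples per subblock. For use with an FIR filter of
#'   order p it must satisfy `block_size >= p + 1` so one historical block
#'   suffices as warm-up. The default, 80 samples (2 s at 40 Hz), holds at
#'   least one full gait cycle and exceeds the default filter order 47.
#' @return An object of classes `"block_buffer"` (an environment).
#' @examples
#' bb <- block_buffer(4)
#' for (x in 1:4) ready <- buffer_push(bb, x)
#' ready           # pending full, swap due
#' buffer_swap(bb)
#' bb$current      # 1 2 3 4
#' @export
block_buffer <- function(block_size = 80) {
  stopifnot(block_size >= 1)
  bb <- new.env(parent = emptyenv())
  bb$block_size <- as.integer(block_size)
  bb$historical <- numeric(0)
  bb$current <- numeric(0)
  bb$pending <- numeric(0)
  bb$overflow <- numeric(0)   # staging for samples arriving mid-swap
  bb$ready <- FALSE
  bb$swaps <- 0L
  class(bb) <- "block_buffer"
  bb
}

#' Push one sample into a block buffer
#'
#' Appends the sample to the pending block (or to the overflow staging FIFO
#' if a swap is already due) and reports whether the pending block is full.
#'
#' @param buffer A [block_buffer()].
#' @param sample A single numeric sample.
#' @return `TRUE` if a swap is due (pending block full), else `FALSE`.
#' @export
buffer_push <- function(buffer, sample) {
  stopifnot(inherits(buffer, "block_buffer"), length(sample) == 1)
  if (buffer$ready) {
    buffer$overflow <- c(buffer$overflow, sample)
  } else {
    buffer$pending <- c(buffer$pending, sample)
    if (length(buffer$pending) == buffer$block_size) buffer$ready <- TRUE
  }
  buffer$ready
}

#' Rotate the subblock roles after a fill signal
#'
#' Current data (already processed) replace the historical block, the full
#' pending block becomes current, and the cleared slot starts collecting --
#' seeded with any overflow-staged samples first, preserving order.
#'
#' @param buffer A [block_buffer()].
#' @return The buffer, invisibly.
#' @export
buffer_swap <- function(buffer) {
  stopifnot(inherits(buffer, "block_buffer"))
  if (!buffer$ready) stop("swap without a pending fill signal")
  buffer$historical <- buffer$current
  buffer$current <- buffer$pending
  buffer$pending <- numeric(0)
  buffer$ready <- FALSE
  buffer$swaps <- buffer$swaps + 1L
  if (length(buffer$overflow)) {
    ov <- buffer$overflow
    buffer$overflow <- numeric(0)
    for (s in ov) buffer_push(buffer, s)
  }
  invisible(buffer)
}

#' @export
print.block_buffer <- function(x, ...) {
  cat(sprintf(
    "Block buffer: block_size %d | historical %d, current %d, pending %d (%s), %d swaps\n",
    x$block_size, length(x$historical), length(x$current), length(x$pending),
    if (x$ready) "full" else "filling", x$swaps))
  invisible(x)
}
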