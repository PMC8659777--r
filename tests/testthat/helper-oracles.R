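# Independent oracles used across the suite. Each re-derives a quantity by
# a different route than the implementation under test.

# Independent reference FIR design: signal::fir1 (Hamming default),
# renormalized to unit DC gain to share the package's convention. fir1
# scales its response at mid-passband and shapes the transition slightly
# differently, so agreement is expected at the percent level, not exact.
oracle_reference_lowpass <- function(order, cutoff_hz, sampling_hz) {
  h <- as.numeric(signal::fir1(order, cutoff_hz / (sampling_hz / 2),
                               type = "low"))
  h / sum(h)
}

oracle_response <- function(coef, f, fs) {
  k <- seq_along(coef) - 1
  vapply(f, function(fr) Mod(sum(coef * exp(-2i * pi * fr * k / fs))),
         numeric(1))
}

# Brute-force strict-neighbour extrema scan (no plateau handling; use on
# tie-free inputs only).
oracle_extrema <- function(v) {
  idx <- integer(0); val <- numeric(0); kind <- character(0)
  for (i in seq_along(v)[-c(1, length(v))]) {
    if (v[i] > v[i - 1] && v[i] > v[i + 1]) {
      idx <- c(idx, i); val <- c(val, v[i]); kind <- c(kind, "peak")
    } else if (v[i] < v[i - 1] && v[i] < v[i + 1]) {
      idx <- c(idx, i); val <- c(val, v[i]); kind <- c(kind, "valley")
    }
  }
  data.frame(index = idx, value = val, kind = kind, stringsAsFactors = FALSE)
}

# Independent re-statement of the complementary-extremum skip rule, using
# explicit liveness marking instead of an index-jumping scan: starting from
# the first (accepted) extremum, repeatedly look for the next live
# complementary extremum; on failure of the gap test mark it and the
# immediately following extremum dead and look again.
oracle_threshold_rule <- function(extrema, threshold) {
  n <- nrow(extrema)
  if (n == 0) return(integer(0))
  alive <- rep(TRUE, n)
  accepted <- 1L
  ref <- 1L
  repeat {
    advanced <- FALSE
    i <- ref + 1L
    while (i <= n) {
      if (alive[i] && extrema$kind[i] != extrema$kind[ref]) {
        if (abs(extrema$value[i] - extrema$value[ref]) >= threshold) {
          accepted <- c(accepted, i)
          ref <- i
          advanced <- TRUE
          break
        }
        alive[i] <- FALSE
        if (i + 1L <= n) alive[i + 1L] <- FALSE
      }
      i <- i + 1L
    }
    if (!advanced) break
  }
  accepted
}

# Random strictly-alternating extrema sequence for property tests.
random_alternating <- function(n, start_kind = sample(c("peak", "valley"), 1)) {
  kinds <- rep(if (start_kind == "peak") c("peak", "valley")
               else c("valley", "peak"), length.out = n)
  base <- 40 + cumsum(stats::rnorm(n, 0, 0.2))
  offs <- stats::runif(n, 0, 1.5)
  vals <- ifelse(kinds == "peak", base + offs, base - offs)
  data.frame(index = seq_len(n) * 10L, value = vals, kind = kinds,
             stringsAsFactors = FALSE)
}

# Ground-truth step count of a noiseless stride sinusoid over one walking
# segment: sign changes of the analytic derivative cos(2*pi*f*t + phase)
# on a fine grid.
oracle_sinusoid_extrema_count <- function(f, duration, phase = 0) {
  t <- seq(0, duration, by = 1 / (f * 1000))
  t <- t[t < duration]
  d <- cos(2 * pi * f * t + phase)
  sum(diff(sign(d)) != 0)
}
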