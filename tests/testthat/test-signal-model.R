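test_that("stride frequency matches the walking band and is exact arithmetic", {
  expect_equal(round(step_frequency(4, 1.3), 2), 0.85)
  expect_equal(step_frequency(4, 1.3), (4 / 3.6) / 1.3)
  expect_equal(step_frequency(6.5, 1.3), 1.3889, tolerance = 1e-4)
  expect_equal(step_frequency(0, 1.3), 0)
  expect_error(step_frequency(5, 0), "stride")
  expect_error(step_frequency(-1, 1.3), "non-negative")
})

test_that("stride frequency is linear in speed and inverse in stride length", {
  speeds <- c(1, 2.5, 4, 6.5)
  expect_equal(step_frequency(2 * speeds), 2 * step_frequency(speeds))
  expect_equal(step_frequency(speeds, 2.6), step_frequency(speeds, 1.3) / 2)
})

test_that("sensor spec validates its fields and warns on unrepresentable range", {
  s <- sensor_spec()
  expect_equal(s$sampling_hz, 40)
  expect_equal(s$noise_sigma_uT, 0.25)
  expect_error(sensor_spec(sampling_hz = 0))
  expect_warning(sensor_spec(resolution_bits = 8), "bits")
})

test_that("uT <-> LSB round trip moves each sample by less than half a count", {
  set.seed(11)
  s <- sample_series(rnorm(500, 40, 3))
  back <- convert_units(convert_units(s, "lsb"), "uT")
  expect_lt(max(abs(back$values - s$values)), 0.05)
  expect_identical(back$units, "uT")
})

test_that("simulated ground-truth step count matches the analytic sinusoid extrema count", {
  cases <- expand.grid(speed = c(4, 5, 6.5), dur = c(30, 60), phase = c(0, 1.2))
  for (i in seq_len(nrow(cases))) {
    f <- step_frequency(cases$speed[i])
    cfg <- gait_sim_config(walk_speed_kmh = cases$speed[i],
                           segments = data.frame(state = "walking",
                                                 duration_s = cases$dur[i]),
                           phase = cases$phase[i], seed = i)
    tr <- simulate_walk(cfg)
    expect_equal(length(tr$truth$step_times),
                 oracle_sinusoid_extrema_count(f, cases$dur[i], cases$phase[i]))
    # two steps per stride period, within one per segment boundary
    expect_lte(abs(length(tr$truth$step_times) - 2 * f * cases$dur[i]), 1)
    expect_true(all(diff(tr$truth$step_times) > 0))
  }
})

test_that("standing-only noiseless trace is constant with zero steps", {
  cfg <- gait_sim_config(segments = data.frame(state = "standing",
                                               duration_s = 10),
                         sensor = sensor_spec(noise_sigma_uT = 0), seed = 3)
  tr <- simulate_walk(cfg)
  expect_equal(length(unique(tr$series$values)), 1)
  expect_length(tr$truth$step_times, 0)
  expect_true(all(tr$truth$segment_labels == "standing"))
})

test_that("simulation is bitwise reproducible for a fixed seed", {
  cfg <- gait_sim_config(seed = 42,
                         disturbance_events = data.frame(time_s = 10,
                                                         amplitude_uT = 2,
                                                         width_s = 0.5))
  expect_identical(simulate_walk(cfg)$series$values,
                   simulate_walk(cfg)$series$values)
  cfg2 <- cfg; cfg2$seed <- 43L
  expect_false(identical(simulate_walk(cfg)$series$values,
                         simulate_walk(cfg2)$series$values))
})

test_that("ground-truth steps fall inside walking segments", {
  cfg <- gait_sim_config(segments = data.frame(
    state = c("standing", "walking", "standing", "walking"),
    duration_s = c(5, 20, 10, 15)), seed = 9)
  tr <- simulate_walk(cfg)
  in_walk <- (tr$truth$step_times >= 5 & tr$truth$step_times < 25) |
             (tr$truth$step_times >= 35 & tr$truth$step_times < 50)
  expect_true(all(in_walk))
})

test_that("spectrum recovers a pure tone and the walking band", {
  t <- (0:1599) / 40
  sp <- field_spectrum(sample_series(3 * sin(2 * pi * 1 * t) + 40))
  expect_equal(sp$frequency_hz[which.max(sp$magnitude)], 1.0)
  expect_lte(max(sp$frequency_hz), 20)

  tr <- simulate_walk(gait_sim_config(walk_speed_kmh = 5, seed = 21))
  sp2 <- field_spectrum(tr$series)
  fpk <- sp2$frequency_hz[which.max(sp2$magnitude)]
  expect_true((fpk >= 0.85 && fpk <= 1.38) || (fpk >= 1.7 && fpk <= 2.76))

  set.seed(5)
  spn <- field_spectrum(sample_series(rnorm(2000)))
  expect_lt(max(spn$magnitude), 5 * median(spn$magnitude))
  expect_error(field_spectrum(sample_series(numeric(0))), "2 samples")
})
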