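test_that("the slow envelope of a constant signal is the constant itself", {
  x <- rep(-40, 300)
  expect_identical(slow_envelope(x, 50, 1), x)
})

test_that("a single-frame spike is rejected by the envelope", {
  x <- rep(-40, 300)
  x[150] <- -10
  env <- slow_envelope(x, 50, 1, percentile = 0.1)
  expect_true(all(env == -40))
})

test_that("after a level step the envelope waits (1 - p) * tau to follow", {
  x <- c(rep(-40, 200), rep(-20, 200))
  env <- slow_envelope(x, 50, 1, percentile = 0.1)
  first_up <- which(env > -40)[1]
  expect_gte(first_up - 200, (1 - 0.1) * 50)
  expect_identical(env, oracle_slow_envelope(x, 50, 0.1))
})

test_that("the sliding percentile is bit-equal to the brute-force oracle", {
  for (seed in 1:3) {
    x <- soniscape:::with_seed(seed,
                               matrix(rnorm(400 * 4, -50, 8), 400, 4))
    for (window in c(1, 7, 50)) {
      expect_identical(slow_envelope(x, 1, window, 0.1),
                       oracle_slow_envelope(x, window, 0.1))
    }
    expect_identical(slow_envelope(x, 1, 30, 0.5),
                     oracle_slow_envelope(x, 30, 0.5))
  }
})

test_that("envelope configuration errors are caught", {
  expect_error(slow_envelope(rnorm(10), 50, 0.001),
               class = "soniscape_error_config")
  expect_error(slow_envelope(rnorm(10), 50, 1, percentile = 0.9),
               class = "soniscape_error_config")
})

test_that("the envelope is idempotent on stationary history", {
  x <- matrix(rep(c(-60, -45, -52), each = 200), ncol = 1)
  env <- slow_envelope(x, 50, 1)
  # constant per channel: re-running changes nothing at all
  const <- matrix(-47, 400, 3)
  expect_identical(slow_envelope(const, 50, 1),
                   slow_envelope(slow_envelope(const, 50, 1), 50, 1))
  # piecewise-stationary: re-running only perturbs onset transients
  env2 <- slow_envelope(env, 50, 1)
  expect_lt(mean(env != env2), 0.3)
  expect_identical(env[100:200], env2[100:200])
})

test_that("decomposition reconstructs the input exactly with ordered envelopes", {
  bundle <- scene_cochleogram(routing_schedule(), 430, frame_rate = 25,
                              n_channels = 24, seed = 4)
  layers <- suppressMessages(
    decompose_layers(bundle$cochleogram, taus = routing_taus))
  expect_lt(max(abs(reconstruct(layers) - bundle$cochleogram$levels)), 1e-9)
  expect_gte(min(layers$second_fg), 0)
  expect_gte(min(layers$minute_fg), 0)
  expect_gte(min(layers$hour_fg), 0)
  env <- layers$slow_envelopes
  expect_true(all(env$s1 >= env$s2) && all(env$s2 >= env$s3))
})

test_that("stationary noise ends up almost entirely in the hour background", {
  x <- soniscape:::with_seed(5, matrix(rnorm(3000 * 8, -50, 2), 3000, 8))
  co <- as_cochleogram(x, 50, round(exp(seq(log(100), log(5000),
                                            length.out = 8))))
  layers <- suppressMessages(decompose_layers(co, taus = c(1, 10, 60)))
  sh <- glance(layers)
  expect_gt(sh$hour_bg_share, 0.9)
})

test_that("sub-second bursts route to the second foreground", {
  sched <- dplyr::bind_rows(
    event_spec("background", 0, 30, c(100, 5000), -60),
    event_spec("pulse_train", 5, 20, c(2000, 4000), -20, rate = 0.5,
               pulse_width = 0.2, rise_fall = 0.02)
  )
  bundle <- scene_cochleogram(sched, 30, frame_rate = 50, n_channels = 24,
                              upper_edge = 6000, seed = 2)
  layers <- suppressMessages(
    decompose_layers(bundle$cochleogram, taus = c(1, 10, 60)))
  routing <- layer_routing(bundle, layers)
  expect_gt(routing$frac_second_fg[routing$kind == "pulse_train"], 0.8)
})

test_that("a 20 s broadband bump routes to the minute foreground", {
  sched <- dplyr::bind_rows(
    event_spec("background", 0, 60, c(100, 5000), -60),
    event_spec("passage", 20, 20, c(200, 3000), -25, rise_fall = 2)
  )
  bundle <- scene_cochleogram(sched, 60, frame_rate = 50, n_channels = 24,
                              upper_edge = 6000, seed = 3)
  layers <- suppressMessages(
    decompose_layers(bundle$cochleogram, taus = c(1, 60, 600)))
  routing <- layer_routing(bundle, layers)
  expect_gt(routing$frac_minute_fg[routing$kind == "passage"], 0.8)
})

test_that("reconstruction validates layer shapes", {
  ls1 <- make_layer_set(n_frames = 100)
  ls1$minute_fg <- ls1$minute_fg[1:50, ]
  expect_error(reconstruct(ls1), class = "soniscape_error_input")
})

test_that("layer sets round-trip through their serialized form", {
  sched <- dplyr::bind_rows(
    event_spec("background", 0, 60, c(100, 5000), -55),
    event_spec("passage", 20, 15, c(200, 2000), -25, rise_fall = 1))
  bundle <- scene_cochleogram(sched, 60, frame_rate = 25, n_channels = 16,
                              seed = 6)
  layers <- suppressMessages(
    decompose_layers(bundle$cochleogram, taus = c(1, 10, 60)))
  dir <- withr::local_tempdir()
  write_layers(layers, dir)
  back <- read_layers(dir)
  for (nm in c("second_fg", "minute_fg", "hour_fg", "hour_bg"))
    expect_equal(back[[nm]], layers[[nm]], tolerance = 1e-12)
  expect_equal(back$taus, layers$taus)
})

test_that("short recordings are decomposed with provisional envelopes", {
  x <- matrix(-50, 100, 4)
  co <- as_cochleogram(x, 50, c(100, 500, 1000, 2000))
  expect_message(decompose_layers(co, taus = c(1, 10, 60)), "provisional")
  layers <- suppressMessages(decompose_layers(co, taus = c(1, 10, 60)))
  expect_equal(layers$provisional, c(50, 100, 100))
})
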