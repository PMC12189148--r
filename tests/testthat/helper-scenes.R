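# Shared fixtures, built in code.

# Hand-built layer set with all-zero foregrounds and an all-floor
# background; pass replacement matrices to activate individual layers.
make_layer_set <- function(n_frames = 500, center_freqs = NULL,
                           frame_rate = 50, floor_db = -100,
                           second = NULL, minute = NULL, hour = NULL,
                           bg = NULL) {
  if (is.null(center_freqs))
    center_freqs <- round(exp(seq(log(60), log(7000), length.out = 32)))
  n_ch <- length(center_freqs)
  zero <- matrix(0, n_frames, n_ch)
  flo <- matrix(floor_db, n_frames, n_ch)
  structure(list(
    second_fg = if (is.null(second)) zero else second,
    minute_fg = if (is.null(minute)) zero else minute,
    hour_fg = if (is.null(hour)) zero else hour,
    hour_bg = if (is.null(bg)) flo else bg,
    slow_envelopes = NULL, taus = c(1, 60, 3600), percentile = 0.1,
    provisional = c(0, 0, 0), frame_rate = frame_rate,
    center_freqs = center_freqs, floor_db = floor_db,
    calibration_offset = 94 + 10 * log10(2)
  ), class = "layer_set")
}

# Scaled-tau routing scene: the four source archetypes on a constant
# background, with taus {1, 60, 600} s (hour constant scaled down; the
# decomposition is parametric in tau, so routing transfers).
routing_taus <- c(1, 60, 600)

routing_schedule <- function() {
  dplyr::bind_rows(
    event_spec("background", 0, 430, c(50, 8000), -50),
    event_spec("passage", 30, 20, c(100, 2000), -20, rise_fall = 1,
               taus = routing_taus),
    event_spec("quasi_stationary", 60, 330, c(300, 1500), -25,
               rise_fall = 1, taus = routing_taus),
    event_spec("pulse_train", 395, 30, c(3000, 6000), -15, rate = 1,
               pulse_width = 0.3, rise_fall = 0.05, taus = routing_taus)
  )
}

routing_scene <- function(seed = 1) {
  scene_cochleogram(routing_schedule(), 430, frame_rate = 50, seed = seed)
}

# Bird-chorus vs car-passage audio scene for end-to-end quadrant checks.
birds_cars_schedule <- function(duration = 90) {
  dplyr::bind_rows(
    event_spec("background", 0, duration, c(100, 7000), -55),
    event_spec("pulse_train", 10, 30, c(3500, 6500), -25, rate = 0.8,
               pulse_width = 0.25, rise_fall = 0.02,
               expected_quadrant = "calm"),
    event_spec("passage", 55, 20, c(100, 1500), -20, rise_fall = 4,
               expected_quadrant = "chaotic")
  )
}
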