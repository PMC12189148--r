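# Seeded synthetic acoustic scenes with ground truth, emulating the source
# taxonomy the decomposition is built around: sub-second high-frequency
# pulse events (bird-like), sub-second low-frequency vocal-band events,
# 5-30 s broadband passages (car-like), minute-scale quasi-stationary
# sounds (machinery, rain) and a constant broadband background. Events are
# spectro-temporally schematic stand-ins (band-limited noise under a
# trapezoid envelope), not naturalistic syntheses. Scenes can be realised
# as audio or directly in the cochleogram domain (hour-scale material is
# wasteful to synthesise as samples).

event_kinds <- c("pulse_train", "passage", "quasi_stationary", "background",
                 "ramp")

#' Specify one synthetic scene event
#'
#' @param kind One of `"pulse_train"`, `"passage"`, `"quasi_stationary"`,
#'   `"background"`, `"ramp"`.
#' @param t_start Event onset in seconds.
#' @param duration Event duration in seconds (> 0).
#' @param band Frequency band `c(f_lo, f_hi)` in Hz.
#' @param peak_level Peak level in dB (dBFS for audio realisation; cell
#'   level for cochleogram realisation).
#' @param rate Pulses per second (`pulse_train` only).
#' @param rise_fall Rise/fall ramp length in seconds.
#' @param pulse_width Single-pulse width in seconds (`pulse_train` only).
#' @param expected_layer Ground-truth layer label; inferred from `kind` and
#'   `duration` against `taus` when `NULL`.
#' @param expected_quadrant Ground-truth quadrant label (optional).
#' @param taus Time constants used for layer inference.
#' @return One-row tibble (an event schedule row).
#' @export
event_spec <- function(kind, t_start, duration, band, peak_level,
                       rate = 1, rise_fall = 0.05, pulse_width = 0.15,
                       expected_layer = NULL, expected_quadrant = NA_character_,
                       taus = c(1, 60, 3600)) {
  kind <- match.arg(kind, event_kinds)
  if (duration <= 0) stop_input("`duration` must be positive")
  if (band[1] >= band[2] || band[1] < 0)
    stop_input("`band` must be an increasing pair of non-negative Hz values")
  if (is.null(expected_layer)) {
    eff <- if (kind == "pulse_train") pulse_width else duration
    expected_layer <- if (kind == "background") "hour_bg"
      else if (eff < taus[1]) "second_fg"
      else if (eff < taus[2]) "minute_fg"
      else if (eff < taus[3]) "hour_fg"
      else "hour_bg"
  }
  tibble(kind = kind, t_start = t_start, duration = duration,
         f_lo = band[1], f_hi = band[2], peak_level = peak_level,
         rate = rate, rise_fall = rise_fall, pulse_width = pulse_width,
         expected_layer = expected_layer,
         expected_quadrant = expected_quadrant)
}

# Amplitude envelope of an event on a time grid (values in [0, 1]).
event_envelope <- function(spec, t) {
  rel <- t - spec$t_start
  inside <- rel >= 0 & rel <= spec$duration
  env <- numeric(length(t))
  if (spec$kind == "pulse_train") {
    period <- 1 / spec$rate
    ph <- rel %% period
    env <- ifelse(inside & ph <= spec$pulse_width,
                  ramp01(ph, spec$pulse_width, spec$rise_fall), 0)
  } else if (spec$kind == "ramp") {
    env[inside] <- rel[inside] / spec$duration
  } else {
    env[inside] <- ramp01(rel[inside], spec$duration, spec$rise_fall)
  }
  env
}

# Trapezoid: linear rise over `rf`, hold, linear fall over the last `rf`.
ramp01 <- function(rel, dur, rf) {
  rf <- min(rf, dur / 2)
  up <- if (rf > 0) pmin(rel / rf, 1) else 1
  down <- if (rf > 0) pmin((dur - rel) / rf, 1) else 1
  pmax(pmin(up, down), 0)
}

#' Render one event as audio samples
#'
#' Band-limited Gaussian noise (brick-wall FFT filter) scaled to the
#' specified peak RMS level and shaped by the event envelope; bit-identical
#' for identical spec and seed.
#'
#' @param spec An [event_spec()] row.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return Numeric vector of `round(duration * sample_rate)` samples.
#' @export
gen_event <- function(spec, sample_rate, seed) {
  if (spec$f_hi > sample_rate / 2)
    stop_config("event band exceeds the Nyquist frequency")
  n <- round(spec$duration * sample_rate)
  noise <- with_seed(seed, rnorm(n))
  x <- fft(noise)
  freqs <- (seq_len(n) - 1L) * sample_rate / n
  freqs <- pmin(freqs, sample_rate - freqs)  # mirrored axis
  x[freqs < spec$f_lo | freqs > spec$f_hi] <- 0
  noise <- Re(fft(x, inverse = TRUE)) / n
  rms <- sqrt(mean(noise^2))
  if (rms > 0) noise <- noise / rms
  amp <- 10^(spec$peak_level / 20)
  t <- spec$t_start + (seq_len(n) - 0.5) / sample_rate
  amp * event_envelope(spec, t) * noise
}

#' Render a schedule of events as an audio scene
#'
#' @param schedule Tibble of [event_spec()] rows.
#' @param duration Scene duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed; per-event seeds are derived from it, so the
#'   scene is bit-identical for identical (schedule, seed).
#' @return A `scene_bundle`: `samples`, `sample_rate`, `events`, `seed`.
#' @export
gen_scene <- function(schedule, duration, sample_rate, seed) {
  n <- round(duration * sample_rate)
  samples <- numeric(n)
  if (!is.null(schedule) && nrow(schedule) > 0) {
    if (any(schedule$t_start < 0 |
              schedule$t_start + schedule$duration > duration + 1e-9))
      stop_input("events must fit within the scene duration")
    bg <- schedule$kind == "background"
    if (sum(bg) > 1) inform("overlapping background events are summed")
    for (i in seq_len(nrow(schedule))) {
      ev <- gen_event(schedule[i, ], sample_rate, derive_seed(seed, i))
      i0 <- round(schedule$t_start[i] * sample_rate)
      idx <- seq_along(ev) + i0
      keep <- idx <= n
      samples[idx[keep]] <- samples[idx[keep]] + ev[keep]
    }
  }
  structure(list(samples = samples, sample_rate = sample_rate,
                 events = schedule, seed = seed),
            class = "scene_bundle")
}

#' Render a schedule of events directly in the cochleogram domain
#'
#' Builds a level matrix by summing each event's band energy (trapezoid
#' energy envelope at `peak_level`) into the channels its band covers,
#' on top of an empty (floor) scene. Also records the baseline levels
#' (background events only), the ground truth needed to measure layer
#' routing.
#'
#' @param schedule Tibble of [event_spec()] rows.
#' @param duration Scene duration in seconds.
#' @param frame_rate Frames per second.
#' @param n_channels,lower_edge,upper_edge Frequency axis (ERB-spaced).
#' @param floor_db Level floor in dB.
#' @param jitter_db Per-cell Gaussian level jitter (dB, seeded); 0 disables.
#' @param seed Integer seed.
#' @return A `scene_bundle` with `cochleogram`, `baseline` (level matrix of
#'   background events only), `events`, `seed`.
#' @export
scene_cochleogram <- function(schedule, duration, frame_rate = 50,
                              n_channels = 48, lower_edge = 50,
                              upper_edge = 8000, floor_db = -100,
                              jitter_db = 0, seed = 1) {
  cf <- erb_rate_inv(seq(erb_rate(lower_edge), erb_rate(upper_edge),
                         length.out = n_channels))
  n_frames <- as.integer(ceiling(duration * frame_rate))
  t <- (seq_len(n_frames) - 0.5) / frame_rate
  energy <- matrix(0, n_frames, n_channels)
  baseline_energy <- matrix(0, n_frames, n_channels)
  if (!is.null(schedule) && nrow(schedule) > 0) {
    if (any(schedule$t_start + schedule$duration > duration + 1e-9))
      stop_input("events must fit within the scene duration")
    for (i in seq_len(nrow(schedule))) {
      sp <- schedule[i, ]
      chans <- which(cf >= sp$f_lo & cf < sp$f_hi)
      if (!length(chans))
        stop_config(sprintf("event %d band matches no channel", i))
      env <- event_envelope(sp, t)
      lev <- matrix(sp$peak_level, n_frames, length(chans))
      if (jitter_db > 0)
        lev <- lev + with_seed(derive_seed(seed, i),
                               matrix(rnorm(length(lev), sd = jitter_db),
                                      n_frames))
      e <- db_to_energy(lev) * env
      energy[, chans] <- energy[, chans] + e
      if (sp$kind == "background")
        baseline_energy[, chans] <- baseline_energy[, chans] + e
    }
  }
  coch <- as_cochleogram(energy_to_db(energy, floor_db), frame_rate, cf,
                         floor_db = floor_db)
  structure(list(cochleogram = coch,
                 baseline = energy_to_db(baseline_energy, floor_db),
                 events = schedule, seed = seed),
            class = "scene_bundle")
}

#' Measure layer-routing accuracy against scene ground truth
#'
#' For each event of a cochleogram-domain scene, the fraction of the
#' event's above-baseline dB mass that each perceptual layer captured. For
#' foreground events the baseline is the background-only scene; for
#' background events the mass is counted above the level floor.
#'
#' @param bundle A `scene_bundle` from [scene_cochleogram()].
#' @param layers The `layer_set` obtained by decomposing
#'   `bundle$cochleogram`.
#' @return Tibble: one row per event with `kind`, `expected_layer`,
#'   `frac_second_fg`, `frac_minute_fg`, `frac_hour_fg`, `frac_hour_bg`
#'   and `frac_expected`.
#' @export
layer_routing <- function(bundle, layers) {
  stopifnot(inherits(bundle, "scene_bundle"), inherits(layers, "layer_set"))
  if (is.null(bundle$cochleogram))
    stop_input("layer routing needs a cochleogram-domain scene bundle")
  L <- bundle$cochleogram$levels
  cf <- bundle$cochleogram$center_freqs
  fr <- bundle$cochleogram$frame_rate
  floor_db <- bundle$cochleogram$floor_db
  sched <- bundle$events
  dplyr::bind_rows(lapply(seq_len(nrow(sched)), function(i) {
    sp <- sched[i, ]
    chans <- which(cf >= sp$f_lo & cf < sp$f_hi)
    f1 <- max(1L, as.integer(floor(sp$t_start * fr)) + 1L)
    f2 <- min(nrow(L), as.integer(ceiling((sp$t_start + sp$duration) * fr)))
    sub <- function(m) m[f1:f2, chans, drop = FALSE]
    if (sp$kind == "background") {
      # The background's own dB mass; other events overlapping its cells are
      # not attributable to it, so its capture is judged against the
      # baseline, capped there (foreground-layer fractions may overcount
      # where other events overlap).
      added <- sub(bundle$baseline) - floor_db
      mass <- c(second_fg = sum(sub(layers$second_fg)),
                minute_fg = sum(sub(layers$minute_fg)),
                hour_fg = sum(sub(layers$hour_fg)),
                hour_bg = sum(pmin(sub(layers$hour_bg),
                                   sub(bundle$baseline)) - floor_db))
    } else {
      added <- pmax(sub(L) - sub(bundle$baseline), 0)
      mass <- c(second_fg = sum(sub(layers$second_fg)),
                minute_fg = sum(sub(layers$minute_fg)),
                hour_fg = sum(sub(layers$hour_fg)),
                hour_bg = sum(pmax(sub(layers$hour_bg) -
                                     sub(bundle$baseline), 0)))
    }
    tot <- sum(added)
    frac <- if (tot > 0) mass / tot else rep(NA_real_, 4)
    tibble(event = i, kind = sp$kind, expected_layer = sp$expected_layer,
           frac_second_fg = frac[[1]], frac_minute_fg = frac[[2]],
           frac_hour_fg = frac[[3]], frac_hour_bg = frac[[4]],
           frac_expected = frac[[match(sp$expected_layer, layer_names)]])
  }))
}

#' Read or write an event schedule as YAML/JSON
#'
#' @param schedule Tibble of [event_spec()] rows.
#' @param path Path ending in `.yaml`/`.yml` or `.json`.
#' @return `path` (write) or a schedule tibble (read).
#' @export
write_schedule <- function(schedule, path) {
  rows <- lapply(seq_len(nrow(schedule)), function(i) as.list(schedule[i, ]))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(rows, path)
  }
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("schedule file '%s' not found", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- if (is.data.frame(raw)) as_tibble(raw)
    else dplyr::bind_rows(lapply(raw, as_tibble))
  # all-missing label columns deserialize as logical; keep them character
  for (nm in c("expected_layer", "expected_quadrant", "kind"))
    if (nm %in% names(out)) out[[nm]] <- as.character(out[[nm]])
  # fill optional fields a hand-written schedule may omit
  defaults <- list(rate = 1, rise_fall = 0.05, pulse_width = 0.15,
                   expected_quadrant = NA_character_)
  for (nm in names(defaults)) {
    if (!nm %in% names(out)) out[[nm]] <- defaults[[nm]]
    out[[nm]][is.na(out[[nm]])] <- defaults[[nm]]
  }
  if (!"expected_layer" %in% names(out))
    out$expected_layer <- NA_character_
  miss <- which(is.na(out$expected_layer))
  out$expected_layer[miss] <- vapply(miss, function(i)
    event_spec(out$kind[i], out$t_start[i], out$duration[i],
               c(out$f_lo[i], out$f_hi[i]), out$peak_level[i],
               pulse_width = out$pulse_width[i])$expected_layer,
    character(1))
  out
}
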