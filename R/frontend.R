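# Cochleogram front end: ERB-spaced, gammatone-weighted band-grouped
# spectrogram. Any tonotopic energy representation would do for the later
# stages; this one is chosen because it conserves in-span energy (per-bin
# weight columns are normalised) while keeping strict tonotopy (a tone at a
# channel's centre frequency always peaks in that channel).

# ERB-rate scale (Glasberg & Moore).
erb_rate <- function(f) 21.4 * log10(4.37e-3 * f + 1)
erb_rate_inv <- function(r) (10^(r / 21.4) - 1) / 4.37e-3
erb_bandwidth <- function(f) 24.7 * (4.37e-3 * f + 1)

#' Front-end parameters for cochleogram computation
#'
#' @param n_channels Number of frequency channels (>= 16).
#' @param lower_edge,upper_edge Analysis span in Hz. The upper edge is
#'   clamped at analysis time to `min(23000, 0.45 * sample_rate)`.
#' @param frame_rate Output frames per second (>= 10).
#' @param spacing Channel spacing: `"erb"` (auditory) or `"log"`.
#' @param floor_db Level floor in dB relative to digital full scale; cells
#'   with no energy sit exactly at this floor.
#' @param calibration_offset dB added when absolute (dB SPL-like) levels are
#'   needed, e.g. for broadband dB(A). The default maps a full-scale sine to
#'   approximately 94 dB.
#'
#' @return A `frontend_params` object (named list).
#' @export
frontend_params <- function(n_channels = 64, lower_edge = 50,
                            upper_edge = 23000, frame_rate = 50,
                            spacing = c("erb", "log"), floor_db = -100,
                            calibration_offset = 94 + 10 * log10(2)) {
  spacing <- match.arg(spacing)
  if (lower_edge <= 0 || lower_edge >= upper_edge)
    stop_config("`lower_edge` must be positive and below `upper_edge`")
  if (frame_rate < 10) stop_config("`frame_rate` must be at least 10 frames/s")
  if (frame_rate != round(frame_rate))
    stop_config("`frame_rate` must be a whole number of frames per second")
  if (n_channels < 16) stop_config("`n_channels` must be at least 16")
  structure(list(n_channels = as.integer(n_channels),
                 lower_edge = lower_edge, upper_edge = upper_edge,
                 frame_rate = frame_rate, spacing = spacing,
                 floor_db = floor_db,
                 calibration_offset = calibration_offset),
            class = "frontend_params")
}

center_frequencies <- function(params, sample_rate) {
  upper <- min(params$upper_edge, 23000, 0.45 * sample_rate)
  if (upper < params$upper_edge)
    inform(sprintf("upper edge clamped to %.0f Hz for sample rate %g Hz",
                   upper, sample_rate))
  if (params$lower_edge >= upper)
    stop_config("analysis span collapsed: lower edge above clamped upper edge")
  if (params$spacing == "erb") {
    erb_rate_inv(seq(erb_rate(params$lower_edge), erb_rate(upper),
                     length.out = params$n_channels))
  } else {
    exp(seq(log(params$lower_edge), log(upper),
            length.out = params$n_channels))
  }
}

#' Compute a cochleogram from audio samples
#'
#' Converts PCM samples into a time x frequency matrix of band levels in dB
#' relative to digital full scale. Frames are Hann-windowed with a hop of
#' `sample_rate / frame_rate` samples and a window of twice the hop; FFT bin
#' powers are pooled into ERB-spaced channels through 4th-order gammatone
#' magnitude responses whose per-bin weights are normalised so that
#' broadband energy inside the analysis span is conserved.
#'
#' @param samples Numeric vector in \[-1, 1\] (or a matrix with one column
#'   per channel; channels are averaged to mono).
#' @param sample_rate Sampling rate in Hz (>= 8000).
#' @param params A [frontend_params()] object.
#'
#' @return A `cochleogram` object: list with `levels`
#'   (frames x channels, dB), `frame_rate`, `center_freqs`, `floor_db`,
#'   `calibration_offset`, `sample_rate`.
#' @export
cochleogram <- function(samples, sample_rate, params = frontend_params()) {
  if (is.matrix(samples) && ncol(samples) > 1L) {
    inform("multichannel input averaged to mono")
    samples <- rowMeans(samples)
  }
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop_input("`samples` must be non-empty")
  if (!all(is.finite(samples))) stop_input("`samples` contains non-finite values")
  if (sample_rate < 8000) stop_input("`sample_rate` must be at least 8000 Hz")
  stopifnot(inherits(params, "frontend_params"))

  cf <- center_frequencies(params, sample_rate)
  hop <- round(sample_rate / params$frame_rate)
  win_len <- 2L * hop
  n_frames <- as.integer(ceiling(length(samples) / hop))

  pad <- numeric((n_frames - 1L) * hop + win_len)
  pad[seq_along(samples)] <- samples
  idx <- outer(seq_len(win_len), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(pad[idx], nrow = win_len)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win_len) - 1L) / (win_len - 1L))
  spec <- mvfft(frames * w)

  n_bins <- win_len %/% 2L + 1L
  power <- Mod(spec[seq_len(n_bins), , drop = FALSE])^2
  # One-sided PSD scaled so the total equals the windowed mean square.
  power <- power / (win_len * sum(w^2))
  if (n_bins > 2L) power[2:(n_bins - 1L), ] <- 2 * power[2:(n_bins - 1L), ]

  freqs <- (seq_len(n_bins) - 1L) * sample_rate / win_len
  weights <- gammatone_weights(freqs, cf)
  energy <- crossprod(power, weights)   # frames x channels

  levels <- energy_to_db(energy, params$floor_db)
  new_cochleogram(levels, params$frame_rate, cf,
                  floor_db = params$floor_db,
                  calibration_offset = params$calibration_offset,
                  sample_rate = sample_rate)
}

# 4th-order gammatone squared-magnitude responses, column-normalised per
# frequency bin (where overlapping channels over-cover) so in-span energy is
# conserved; normalisation divides all channels by a common per-bin factor,
# so tonotopy (argmax at the matching channel) is unaffected.
gammatone_weights <- function(freqs, cf) {
  b <- 1.019 * erb_bandwidth(cf)
  W <- sapply(seq_along(cf), function(c) {
    (1 + ((freqs - cf[c]) / b[c])^2)^(-4)
  })
  colsum <- rowSums(W)
  W / pmax(colsum, 1)
}

#' Construct a cochleogram from an existing level matrix
#'
#' Used by the synthetic-scene generator and by audibility analysis when the
#' time-frequency representation is produced directly rather than from audio.
#'
#' @param levels Matrix (frames x channels) of levels in dB.
#' @param frame_rate Frames per second.
#' @param center_freqs Strictly increasing channel centre frequencies (Hz).
#' @param floor_db Level floor in dB.
#' @param calibration_offset Calibration offset in dB.
#' @param sample_rate Optional originating sample rate.
#' @return A `cochleogram` object.
#' @export
as_cochleogram <- function(levels, frame_rate, center_freqs,
                           floor_db = -100,
                           calibration_offset = 94 + 10 * log10(2),
                           sample_rate = NA_real_) {
  new_cochleogram(pmax(as.matrix(levels), floor_db), frame_rate,
                  center_freqs, floor_db, calibration_offset, sample_rate)
}

new_cochleogram <- function(levels, frame_rate, center_freqs, floor_db,
                            calibration_offset, sample_rate) {
  if (any(!is.finite(levels))) stop_input("cochleogram levels must be finite")
  if (ncol(levels) != length(center_freqs))
    stop_input("channel count does not match `center_freqs`")
  if (any(diff(center_freqs) <= 0))
    stop_input("`center_freqs` must be strictly increasing")
  structure(list(levels = unname(levels), frame_rate = frame_rate,
                 center_freqs = center_freqs, floor_db = floor_db,
                 calibration_offset = calibration_offset,
                 sample_rate = sample_rate),
            class = "cochleogram")
}

#' @export
print.cochleogram <- function(x, ...) {
  cat(sprintf("<cochleogram> %d frames x %d channels @ %g frames/s\n",
              nrow(x$levels), ncol(x$levels), x$frame_rate))
  cat(sprintf("  span %.0f-%.0f Hz, floor %g dB, calibration %+.1f dB\n",
              min(x$center_freqs), max(x$center_freqs), x$floor_db,
              x$calibration_offset))
  invisible(x)
}

#' @export
dim.cochleogram <- function(x) dim(x$levels)

#' IEC 61672 A-weighting
#'
#' Standard A-frequency-weighting gain, normalised to exactly 0 dB at
#' 1000 Hz.
#'
#' @param freq Frequency or frequencies in Hz (> 0).
#' @return Gain(s) in dB.
#' @export
a_weighting <- function(freq) {
  if (any(freq <= 0)) stop_input("`freq` must be positive")
  ra <- function(f) {
    (12194^2 * f^4) /
      ((f^2 + 20.6^2) * sqrt((f^2 + 107.7^2) * (f^2 + 737.9^2)) *
         (f^2 + 12194^2))
  }
  20 * log10(ra(freq)) - 20 * log10(ra(1000))
}

#' A-weighted broadband level per frame
#'
#' Sums channel energies with per-channel A-weighting and adds the
#' calibration offset, yielding an approximate dB(A) level. Channels sitting
#' exactly at the level floor are treated as silent; a frame with no
#' above-floor channel returns `floor_db + calibration_offset`.
#'
#' @param coch A `cochleogram` (or `layer_set` matrix via
#'   [broadband_level_matrix()]).
#' @param frames Frame indices (default: all frames).
#' @return Numeric vector of dB(A) levels, one per requested frame.
#' @export
broadband_level_dba <- function(coch, frames = NULL) {
  stopifnot(inherits(coch, "cochleogram"))
  n <- nrow(coch$levels)
  if (is.null(frames)) frames <- seq_len(n)
  if (any(frames < 1 | frames > n)) stop_index("frame index out of range")
  broadband_level_matrix(coch$levels[frames, , drop = FALSE],
                         coch$center_freqs, coch$floor_db,
                         coch$calibration_offset)
}

#' A-weighted broadband level of a level matrix
#'
#' Worker behind [broadband_level_dba()], usable on any level matrix that
#' shares a cochleogram's frequency axis (e.g. a single perceptual layer).
#'
#' @param levels Matrix (frames x channels) of levels in dB.
#' @param center_freqs Channel centre frequencies in Hz.
#' @param floor_db Level floor; at-floor channels are excluded from the sum.
#' @param calibration_offset dB added to the summed level.
#' @return Numeric vector of dB(A) levels per frame.
#' @export
broadband_level_matrix <- function(levels, center_freqs, floor_db = -100,
                                   calibration_offset = 94 + 10 * log10(2)) {
  aw <- db_to_energy(a_weighting(center_freqs))
  e <- db_to_energy(levels)
  e[levels <= floor_db] <- 0
  tot <- as.numeric(e %*% aw)
  out <- rep(floor_db, length(tot))
  pos <- tot > 0
  out[pos] <- pmax(10 * log10(tot[pos]), floor_db)
  out + calibration_offset
}

#' Serialize a cochleogram to CSV plus a JSON header
#'
#' Writes `<path>` as a plain CSV of levels (frames in rows) and
#' `<path>.json` with the frame rate, centre frequencies, floor and
#' calibration metadata.
#'
#' @param coch A `cochleogram`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cochleogram <- function(coch, path) {
  stopifnot(inherits(coch, "cochleogram"))
  utils::write.table(coch$levels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- coch[c("frame_rate", "center_freqs", "floor_db",
                 "calibration_offset", "sample_rate")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cochleogram
#' @export
read_cochleogram <- function(path) {
  if (!file.exists(path) || !file.exists(paste0(path, ".json")))
    stop_io(sprintf("cochleogram files not found at '%s'", path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  levels <- as.matrix(utils::read.table(path, sep = ","))
  sr <- meta$sample_rate
  if (is.null(sr) || length(sr) == 0L) sr <- NA_real_
  new_cochleogram(levels, meta$frame_rate, meta$center_freqs,
                  meta$floor_db, meta$calibration_offset, sr)
}

#' @export
tidy.cochleogram <- function(x, ...) {
  tibble(
    frame = rep(seq_len(nrow(x$levels)), times = ncol(x$levels)),
    time = (rep(seq_len(nrow(x$levels)), times = ncol(x$levels)) - 0.5) /
      x$frame_rate,
    channel = rep(seq_len(ncol(x$levels)), each = nrow(x$levels)),
    center_freq = rep(x$center_freqs, each = nrow(x$levels)),
    level = as.vector(x$levels)
  )
}

#' @export
glance.cochleogram <- function(x, ...) {
  tibble(n_frames = nrow(x$levels), n_channels = ncol(x$levels),
         frame_rate = x$frame_rate,
         duration = nrow(x$levels) / x$frame_rate,
         mean_level = mean(x$levels),
         mean_broadband_dba = mean(broadband_level_dba(x)))
}

#' @export
autoplot.cochleogram <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$center_freq,
                                  fill = .data$level)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "level (dB)") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
}
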