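# Perceptual-layer decomposition: cascaded slow-envelope subtraction at
# second / minute / hour time constants (old-plus-new heuristic). Each stage
# tracks a slower background as a causal running low-percentile of the
# previous stage's output, clamped to never exceed it; the clamp is what
# makes foregrounds non-negative and the four layers sum back to the input
# exactly.

#' Causal slow envelope of a level matrix
#'
#' Per-channel causal running low-percentile over a sliding window of
#' `tau` seconds, clamped cell-wise so the envelope never exceeds the input.
#' The percentile is the type-1 order statistic: the k-th smallest window
#' member with `k = ceiling(percentile * n)`, `n` the current window
#' occupancy. During warm-up (the first `tau` seconds) the window is the
#' available history.
#'
#' @param x Level matrix (frames x channels) or numeric vector.
#' @param frame_rate Frames per second.
#' @param tau Window length in seconds; `tau * frame_rate` must be >= 1.
#' @param percentile Fraction in (0, 0.5]; default 0.1 (10th percentile).
#' @return Matrix (or vector) of envelope levels, same shape as `x`.
#' @export
slow_envelope <- function(x, frame_rate, tau, percentile = 0.1) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1L)
  window <- as.integer(round(tau * frame_rate))
  if (tau * frame_rate < 1) stop_config("`tau` must span at least one frame")
  if (percentile <= 0 || percentile > 0.5)
    stop_config("`percentile` must lie in (0, 0.5]")
  q <- running_percentile_cpp(x, window, percentile)
  env <- pmin(q, x)
  if (vec) env <- as.vector(env)
  env
}

#' Decompose a cochleogram into four perceptual layers
#'
#' Cascaded fast-to-slow envelope subtraction: the 1 s envelope is computed
#' from the input, the 1 min envelope from the 1 s envelope, and the 1 h
#' envelope from the 1 min envelope. The three foregrounds are the
#' differences of successive estimates (audibility in dB above the next
#' slower level); the hour background is the slowest estimate itself.
#'
#' @param coch A `cochleogram`.
#' @param taus Strictly increasing time constants in seconds,
#'   default `c(1, 60, 3600)`.
#' @param percentile Envelope percentile, see [slow_envelope()].
#' @return A `layer_set`: matrices `second_fg`, `minute_fg`, `hour_fg`
#'   (audibility, >= 0), `hour_bg` (absolute level), the three
#'   `slow_envelopes`, the `taus`, per-stage `provisional` warm-up frame
#'   counts, and the source cochleogram's metadata.
#' @export
decompose_layers <- function(coch, taus = c(1, 60, 3600), percentile = 0.1) {
  stopifnot(inherits(coch, "cochleogram"))
  if (length(taus) != 3L || any(diff(taus) <= 0))
    stop_config("`taus` must be three strictly increasing time constants")
  L <- coch$levels
  n_frames <- nrow(L)
  fr <- coch$frame_rate

  s1 <- slow_envelope(L, fr, taus[1], percentile)
  s2 <- slow_envelope(s1, fr, taus[2], percentile)
  s3 <- slow_envelope(s2, fr, taus[3], percentile)

  provisional <- pmin(as.integer(round(taus * fr)), n_frames)
  if (n_frames < round(taus[3] * fr))
    inform(sprintf(paste0("recording (%.1f s) shorter than the largest time",
                          " constant (%g s); slower envelopes are",
                          " provisional"), n_frames / fr, taus[3]))

  structure(list(
    second_fg = L - s1,
    minute_fg = s1 - s2,
    hour_fg = s2 - s3,
    hour_bg = s3,
    slow_envelopes = list(s1 = s1, s2 = s2, s3 = s3),
    taus = taus, percentile = percentile,
    provisional = provisional,
    frame_rate = fr, center_freqs = coch$center_freqs,
    floor_db = coch$floor_db, calibration_offset = coch$calibration_offset
  ), class = "layer_set")
}

#' Reconstruct the original levels from a layer set
#'
#' The sum of the hour background and the three foregrounds yields the
#' original cochleogram levels (to numerical round-off).
#'
#' @param layers A `layer_set`.
#' @return Level matrix (frames x channels).
#' @export
reconstruct <- function(layers) {
  stopifnot(inherits(layers, "layer_set"))
  dims <- lapply(layers[c("second_fg", "minute_fg", "hour_fg", "hour_bg")],
                 dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop_input("layer matrices have mismatching shapes")
  layers$second_fg + layers$minute_fg + layers$hour_fg + layers$hour_bg
}

#' @export
print.layer_set <- function(x, ...) {
  cat(sprintf("<layer_set> %d frames x %d channels @ %g frames/s\n",
              nrow(x$hour_bg), ncol(x$hour_bg), x$frame_rate))
  cat(sprintf("  taus: %s s, percentile %.2f\n",
              paste(x$taus, collapse = "/"), x$percentile))
  sh <- glance(x)
  cat(sprintf("  dB-mass shares above floor: second %.2f minute %.2f hour %.2f background %.2f\n",
              sh$second_fg_share, sh$minute_fg_share, sh$hour_fg_share,
              sh$hour_bg_share))
  invisible(x)
}

layer_names <- c("second_fg", "minute_fg", "hour_fg", "hour_bg")

#' @export
tidy.layer_set <- function(x, ...) {
  n_fr <- nrow(x$hour_bg)
  n_ch <- ncol(x$hour_bg)
  base <- tibble(
    frame = rep(seq_len(n_fr), times = n_ch),
    time = (rep(seq_len(n_fr), times = n_ch) - 0.5) / x$frame_rate,
    channel = rep(seq_len(n_ch), each = n_fr),
    center_freq = rep(x$center_freqs, each = n_fr)
  )
  dplyr::bind_rows(lapply(layer_names, function(nm) {
    dplyr::mutate(base, layer = nm, level = as.vector(x[[nm]]))
  }))
}

#' @export
glance.layer_set <- function(x, ...) {
  # Shares of the above-floor dB mass carried by each layer; the background
  # share counts its height above the floor.
  fg <- vapply(layer_names[1:3], function(nm) sum(x[[nm]]), numeric(1))
  bg <- sum(x$hour_bg - x$floor_db)
  tot <- sum(fg) + bg
  tibble(n_frames = nrow(x$hour_bg),
         second_fg_share = fg[[1]] / tot, minute_fg_share = fg[[2]] / tot,
         hour_fg_share = fg[[3]] / tot, hour_bg_share = bg / tot)
}

#' @export
autoplot.layer_set <- function(object, ...) {
  d <- tidy(object)
  d$layer <- factor(d$layer, levels = layer_names)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$center_freq,
                                  fill = .data$level)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~layer, ncol = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
}

#' Serialize a layer set to per-layer CSV files plus a JSON manifest
#'
#' @param layers A `layer_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_layers <- function(layers, dir) {
  stopifnot(inherits(layers, "layer_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in layer_names)
    utils::write.table(layers[[nm]], file.path(dir, paste0(nm, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  manifest <- layers[c("taus", "percentile", "provisional", "frame_rate",
                       "center_freqs", "floor_db", "calibration_offset")]
  manifest$layers <- paste0(layer_names, ".csv")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_layers
#' @export
read_layers <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop_io(sprintf("no layer manifest in '%s'", dir))
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  out <- lapply(layer_names, function(nm)
    as.matrix(utils::read.table(file.path(dir, paste0(nm, ".csv")),
                                sep = ",")))
  names(out) <- layer_names
  out <- lapply(out, unname)
  # Envelopes are recoverable from the layer sums.
  s3 <- out$hour_bg
  s2 <- s3 + out$hour_fg
  s1 <- s2 + out$minute_fg
  structure(c(out, list(slow_envelopes = list(s1 = s1, s2 = s2, s3 = s3),
                        taus = meta$taus, percentile = meta$percentile,
                        provisional = meta$provisional,
                        frame_rate = meta$frame_rate,
                        center_freqs = meta$center_freqs,
                        floor_db = meta$floor_db,
                        calibration_offset = meta$calibration_offset)),
            class = "layer_set")
}
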