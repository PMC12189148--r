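# Per-second soundscape appraisal: each configuration row's value (band
# audibility of a foreground layer, or A-weighted broadband level of the
# hour background) is pooled over its look-back scope, mapped linearly to a
# weight in [0, 1] over the row's value range, and the weights pull the
# appraisal point along their quadrant diagonals:
#   (p, e) = sum(w_i * u_i) / max(1, sum(w_i)),
# radially clipped to the unit disk. A single saturated row reaches the rim;
# a weak row yields a proportionally small magnitude; opposing rows cancel;
# "center" rows pull nowhere but damp extremity through the denominator.

#' Linear contribution weight over a value range
#'
#' Contributions scale linearly from 0 to 1 within the row's value range and
#' are clipped outside it.
#'
#' @param value Value in dB or dB(A).
#' @param value_range Numeric `c(v_min, v_max)` with `v_min < v_max`.
#' @return Weight(s) in \[0, 1\].
#' @export
contribution_weight <- function(value, value_range) {
  if (value_range[1] >= value_range[2])
    stop_config("`value_range` must have v_min < v_max")
  pmin(pmax((value - value_range[1]) /
              (value_range[2] - value_range[1]), 0), 1)
}

#' Pooled band audibility of a layer at one second
#'
#' Maximum audibility across the channels whose centre frequency lies in
#' `[f_lo, f_hi)`, pooled as the 90th percentile of the per-frame band
#' maxima over the `scope`-second window ending at second `t` (truncated at
#' the recording start). The percentile is taken over the window's *active*
#' frames (band maximum above 0 dB), so a brief event keeps influencing the
#' appraisal for the whole scope; with no active frame the audibility is 0.
#'
#' @param layer_matrix Foreground layer matrix (frames x channels, dB >= 0).
#' @param center_freqs Channel centre frequencies (Hz).
#' @param band Numeric `c(f_lo, f_hi)` in Hz.
#' @param t Second index (1-based).
#' @param scope Look-back window in seconds.
#' @param frame_rate Frames per second.
#' @return Pooled audibility in dB.
#' @export
band_audibility <- function(layer_matrix, center_freqs, band, t, scope,
                            frame_rate) {
  chans <- which(center_freqs >= band[1] & center_freqs < band[2])
  if (!length(chans))
    stop_config(sprintf("band [%g, %g) Hz matches no channel", band[1],
                        band[2]))
  if (t < 1) stop_index("`t` must be a positive second index")
  pf <- row_max(layer_matrix, chans)
  pool_audibility(pf, t, scope, frame_rate)
}

pool_audibility <- function(pf, t, scope, frame_rate) {
  f1 <- max(1L, as.integer((t - scope) * frame_rate) + 1L)
  f2 <- min(length(pf), as.integer(t * frame_rate))
  vals <- pf[f1:f2]
  act <- vals > 0
  if (!any(act)) return(0)
  quantile(vals[act], 0.9, type = 7, names = FALSE)
}

pool_level <- function(pf, t, scope, frame_rate) {
  f1 <- max(1L, as.integer((t - scope) * frame_rate) + 1L)
  f2 <- min(length(pf), as.integer(t * frame_rate))
  quantile(pf[f1:f2], 0.9, type = 7, names = FALSE)
}

# Per-frame value series for every configuration row.
row_frame_values <- function(layers, config) {
  cf <- layers$center_freqs
  lapply(seq_len(nrow(config$rows)), function(i) {
    r <- config$rows[i, ]
    if (!r$layer %in% names(layers) || is.null(layers[[r$layer]]))
      stop_input(sprintf("layer '%s' missing from layer set", r$layer))
    if (r$unit == "level_dba") {
      broadband_level_matrix(layers[[r$layer]], cf, layers$floor_db,
                             layers$calibration_offset)
    } else {
      chans <- which(cf >= r$f_lo & cf < r$f_hi)
      if (!length(chans))
        stop_config(sprintf("row '%s': band matches no channel", r$label))
      row_max(layers[[r$layer]], chans)
    }
  })
}

appraise_one <- function(pf_list, config, t, frame_rate) {
  rows <- config$rows
  w <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    v <- if (r$unit == "level_dba") {
      pool_level(pf_list[[i]], t, r$scope, frame_rate)
    } else {
      pool_audibility(pf_list[[i]], t, r$scope, frame_rate)
    }
    contribution_weight(v, c(r$v_min, r$v_max))
  }, numeric(1))
  u <- quadrant_vectors[rows$quadrant, , drop = FALSE]
  vec <- colSums(w * u) / max(1, sum(w))
  r2 <- sqrt(sum(vec^2))
  if (r2 > 1) vec <- vec / r2
  list(p = vec[[1]], e = vec[[2]], w = w)
}

#' Appraise a single second
#'
#' @param layers A `layer_set`.
#' @param config An [appraisal_config()].
#' @param t Second index (1-based), within the recording.
#' @return One-row tibble: `t`, `pleasantness`, `eventfulness`, and one
#'   `w_<label>` column per configuration row.
#' @export
appraise_second <- function(layers, config = appraisal_config(), t) {
  stopifnot(inherits(layers, "layer_set"))
  n_sec <- nrow(layers$hour_bg) %/% layers$frame_rate
  if (t < 1 || t > n_sec) stop_index("second index `t` out of range")
  pf <- row_frame_values(layers, config)
  res <- appraise_one(pf, config, t, layers$frame_rate)
  frame_tibble(t, res, config)
}

frame_tibble <- function(t, res, config) {
  out <- tibble(t = t, pleasantness = res$p, eventfulness = res$e)
  w <- stats::setNames(as.list(res$w), paste0("w_", config$rows$label))
  dplyr::bind_cols(out, as_tibble(w))
}

#' Appraise every full second of a recording
#'
#' @param layers A `layer_set`.
#' @param config An [appraisal_config()].
#' @return An `appraisal_series`: a tibble with one row per full second
#'   (`t`, `pleasantness`, `eventfulness`, per-row weights), carrying the
#'   configuration as an attribute. Zero-length input yields an empty
#'   series.
#' @export
appraise <- function(layers, config = appraisal_config()) {
  stopifnot(inherits(layers, "layer_set"))
  fr <- layers$frame_rate
  n_sec <- nrow(layers$hour_bg) %/% fr
  if (n_sec < 1) {
    out <- tibble(t = integer(), pleasantness = numeric(),
                  eventfulness = numeric())
  } else {
    pf <- row_frame_values(layers, config)
    out <- dplyr::bind_rows(lapply(seq_len(n_sec), function(t) {
      frame_tibble(t, appraise_one(pf, config, t, fr), config)
    }))
  }
  new_appraisal_series(out, config)
}

new_appraisal_series <- function(tbl, config) {
  structure(tbl, config = config,
            class = c("appraisal_series", class(tibble())))
}

#' @export
tidy.appraisal_series <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::starts_with("w_"),
                      names_to = "row", values_to = "weight",
                      names_prefix = "w_")
}

#' @export
glance.appraisal_series <- function(x, ...) {
  q <- appraisal_quadrant(x$pleasantness, x$eventfulness)
  n <- nrow(x)
  frac <- function(lbl) if (n) mean(q == lbl) else NA_real_
  tibble(n_seconds = n,
         mean_pleasantness = if (n) mean(x$pleasantness) else NA_real_,
         mean_eventfulness = if (n) mean(x$eventfulness) else NA_real_,
         frac_calm = frac("calm"), frac_lively = frac("lively"),
         frac_chaotic = frac("chaotic"), frac_boring = frac("boring"),
         frac_center = frac("center"))
}

appraisal_quadrant <- function(p, e) {
  dplyr::case_when(
    p > 0 & e < 0 ~ "calm",
    p > 0 & e > 0 ~ "lively",
    p < 0 & e > 0 ~ "chaotic",
    p < 0 & e < 0 ~ "boring",
    TRUE ~ "center"
  )
}

#' @export
autoplot.appraisal_series <- function(object, ...) {
  circle <- tibble(theta = seq(0, 2 * pi, length.out = 256))
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$pleasantness,
                               y = .data$eventfulness)) +
    ggplot2::geom_path(data = circle,
                       ggplot2::aes(x = cos(.data$theta),
                                    y = sin(.data$theta)),
                       inherit.aes = FALSE, colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$t), alpha = 0.6) +
    ggplot2::coord_fixed(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "pleasantness", y = "eventfulness", colour = "second")
}

#' Read or write an appraisal series as CSV
#'
#' @param series An `appraisal_series`.
#' @param path CSV path.
#' @return `path` (write) or an `appraisal_series` with the default
#'   configuration attached (read).
#' @export
write_appraisal_series <- function(series, path) {
  utils::write.csv(as_tibble(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_appraisal_series
#' @export
read_appraisal_series <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("series file '%s' not found", path))
  new_appraisal_series(as_tibble(utils::read.csv(path)), appraisal_config())
}
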