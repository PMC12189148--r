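# End-to-end convenience wrappers tying the stages together.

#' Appraise an audio recording end to end
#'
#' Cochleogram, layer decomposition, and per-second appraisal in one call.
#'
#' @param samples Numeric samples in \[-1, 1\], or a path to a WAV file.
#' @param sample_rate Sampling rate in Hz (ignored when `samples` is a
#'   path).
#' @param params [frontend_params()].
#' @param config [appraisal_config()]; its `taus` and `percentile` drive
#'   the layer decomposition.
#' @return An `appraisal_series`.
#' @export
appraise_audio <- function(samples, sample_rate = NULL,
                           params = frontend_params(),
                           config = appraisal_config()) {
  if (is.character(samples)) {
    audio <- read_wav(samples)
    samples <- audio$samples
    sample_rate <- audio$sample_rate
  }
  if (is.null(sample_rate)) stop_input("`sample_rate` is required")
  coch <- cochleogram(samples, sample_rate, params)
  layers <- decompose_layers(coch, taus = config$taus,
                             percentile = config$percentile)
  appraise(layers, config)
}

#' Sonic climate of an audio recording
#'
#' @inheritParams appraise_audio
#' @param n_bins Histogram bins per axis (odd); defaults to the
#'   configuration's `histogram_bins`.
#' @return A `climate_histogram`.
#' @export
sonic_climate <- function(samples, sample_rate = NULL,
                          params = frontend_params(),
                          config = appraisal_config(),
                          n_bins = config$histogram_bins) {
  climate_histogram(appraise_audio(samples, sample_rate, params, config),
                    n_bins = n_bins)
}
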