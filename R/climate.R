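# Sonic climate: the long-term aggregate of per-second appraisals as a 2D
# histogram over the pleasantness x eventfulness square, with quadrant
# fractions and a total-variation distance for comparing climates.

#' Aggregate an appraisal series into a sonic-climate histogram
#'
#' Equal-width bins over \[-1, 1\] on each axis, half-open `[lo, hi)` except
#' the last bin, which is closed so that (1, 1) is counted. The bin count
#' must be odd so the origin lies inside a single centre bin.
#'
#' @param series An `appraisal_series` (or any data frame with
#'   `pleasantness` and `eventfulness` columns).
#' @param n_bins Bins per axis, odd, >= 3 (default 21).
#' @return A `climate_histogram`: `bins` (pleasantness x eventfulness matrix
#'   of fractions), `edges`, `n_bins`, `n_samples`, `time_span`.
#' @export
climate_histogram <- function(series, n_bins = 21) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 3L || n_bins %% 2L == 0L)
    stop_config("`n_bins` must be odd and at least 3")
  edges <- seq(-1, 1, length.out = n_bins + 1L)
  p <- series$pleasantness
  e <- series$eventfulness
  n <- length(p)
  counts <- matrix(0, n_bins, n_bins)
  if (n > 0) {
    ip <- findInterval(p, edges, rightmost.closed = TRUE)
    ie <- findInterval(e, edges, rightmost.closed = TRUE)
    ok <- ip >= 1 & ip <= n_bins & ie >= 1 & ie <= n_bins
    if (!all(ok)) stop_input("appraisal points outside [-1, 1] x [-1, 1]")
    counts <- matrix(tabulate((ie - 1L) * n_bins + ip, n_bins * n_bins),
                     n_bins, n_bins)
  }
  structure(list(bins = if (n > 0) counts / n else counts,
                 edges = edges, n_bins = n_bins, n_samples = n,
                 time_span = if (!is.null(series$t) && n > 0)
                   range(series$t) else c(NA_real_, NA_real_)),
            class = "climate_histogram")
}

#' @export
print.climate_histogram <- function(x, ...) {
  cat(sprintf("<climate_histogram> %d x %d bins over [-1,1]^2, %d seconds\n",
              x$n_bins, x$n_bins, x$n_samples))
  qf <- quadrant_fractions(x)
  cat("  ", paste(sprintf("%s %.2f", qf$quadrant, qf$fraction),
                  collapse = "  "), "\n")
  invisible(x)
}

#' Quadrant fractions of a sonic climate
#'
#' Mass fractions of the histogram falling in each circumplex quadrant:
#' calm (p > 0, e < 0), lively (p > 0, e > 0), chaotic (p < 0, e > 0),
#' boring (p < 0, e < 0); mass in bins straddling either zero axis is
#' assigned to "center". The five fractions sum to 1.
#'
#' @param hist A `climate_histogram`.
#' @return Tibble with columns `quadrant`, `fraction`.
#' @export
quadrant_fractions <- function(hist) {
  stopifnot(inherits(hist, "climate_histogram"))
  mids <- (hist$edges[-1] + hist$edges[-length(hist$edges)]) / 2
  straddle <- hist$edges[-length(hist$edges)] < 0 & hist$edges[-1] > 0
  out <- stats::setNames(numeric(5), quadrant_labels)
  for (i in seq_len(hist$n_bins)) {
    for (j in seq_len(hist$n_bins)) {
      m <- hist$bins[i, j]
      if (m == 0) next
      lbl <- if (straddle[i] || straddle[j]) "center"
        else appraisal_quadrant(mids[i], mids[j])
      out[lbl] <- out[lbl] + m
    }
  }
  tibble(quadrant = quadrant_labels, fraction = unname(out))
}

#' Total-variation distance between two sonic climates
#'
#' `0.5 * sum(|h1 - h2|)`: 0 for identical climates, 1 for climates with
#' disjoint support. Useful for flagging days that deviate from a norm.
#'
#' @param h1,h2 `climate_histogram`s with equal bin counts.
#' @return Distance in \[0, 1\].
#' @export
climate_distance <- function(h1, h2) {
  stopifnot(inherits(h1, "climate_histogram"),
            inherits(h2, "climate_histogram"))
  if (h1$n_bins != h2$n_bins)
    stop_input("histograms have different bin counts")
  0.5 * sum(abs(h1$bins - h2$bins))
}

#' Merge two sonic climates
#'
#' Weighted by sample counts, so merging equals accumulating the
#' concatenated series.
#'
#' @param h1,h2 `climate_histogram`s with equal bin counts.
#' @return A `climate_histogram`.
#' @export
climate_merge <- function(h1, h2) {
  if (h1$n_bins != h2$n_bins)
    stop_input("histograms have different bin counts")
  n <- h1$n_samples + h2$n_samples
  bins <- if (n > 0)
    (h1$bins * h1$n_samples + h2$bins * h2$n_samples) / n else h1$bins
  structure(list(bins = bins, edges = h1$edges, n_bins = h1$n_bins,
                 n_samples = n,
                 time_span = suppressWarnings(
                   range(c(h1$time_span, h2$time_span), na.rm = TRUE))),
            class = "climate_histogram")
}

#' @export
tidy.climate_histogram <- function(x, ...) {
  mids <- (x$edges[-1] + x$edges[-length(x$edges)]) / 2
  tibble(
    p_mid = rep(mids, times = x$n_bins),
    e_mid = rep(mids, each = x$n_bins),
    fraction = as.vector(x$bins)
  )
}

#' @export
glance.climate_histogram <- function(x, ...) {
  qf <- quadrant_fractions(x)
  dplyr::bind_cols(
    tibble(n_samples = x$n_samples, n_bins = x$n_bins),
    tidyr::pivot_wider(qf, names_from = "quadrant",
                       values_from = "fraction",
                       names_prefix = "frac_")
  )
}

#' @export
autoplot.climate_histogram <- function(object, contour_mass = c(0.5, 0.9, 0.99),
                                       ...) {
  d <- tidy(object)
  # Density thresholds enclosing the requested cumulative mass fractions.
  thr <- vapply(contour_mass, function(m) {
    f <- sort(d$fraction, decreasing = TRUE)
    cs <- cumsum(f)
    f[which(cs >= m)[1]]
  }, numeric(1))
  pl <- ggplot2::ggplot(d, ggplot2::aes(x = .data$p_mid, y = .data$e_mid)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fraction)) +
    ggplot2::scale_fill_viridis_c(name = "fraction") +
    ggplot2::coord_fixed(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "pleasantness", y = "eventfulness")
  thr <- thr[is.finite(thr) & thr > 0]
  if (length(thr))
    pl <- pl + ggplot2::geom_contour(ggplot2::aes(z = .data$fraction),
                                     breaks = unique(thr), colour = "white")
  pl
}

#' Serialize a sonic-climate histogram to JSON
#'
#' @param hist A `climate_histogram`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_climate <- function(hist, path) {
  stopifnot(inherits(hist, "climate_histogram"))
  jsonlite::write_json(list(bins = hist$bins, edges = hist$edges,
                            n_bins = hist$n_bins,
                            n_samples = hist$n_samples,
                            time_span = hist$time_span),
                       path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_climate
#' @export
read_climate <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("climate file '%s' not found", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bins <- raw$bins
  if (!is.matrix(bins))
    bins <- matrix(unlist(bins), raw$n_bins, raw$n_bins, byrow = TRUE)
  structure(list(bins = bins,
                 edges = raw$edges, n_bins = as.integer(raw$n_bins),
                 n_samples = raw$n_samples, time_span = raw$time_span),
            class = "climate_histogram")
}
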