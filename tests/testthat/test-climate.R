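series_at <- function(p, e) tibble::tibble(t = seq_along(p),
                                           pleasantness = p,
                                           eventfulness = e)

test_that("identical origin frames all fall in the single centre bin", {
  h <- climate_histogram(series_at(rep(0, 40), rep(0, 40)), 21)
  expect_equal(h$bins[11, 11], 1)
  expect_equal(sum(h$bins), 1)
})

test_that("the (1, 1) corner lands in the closed top-right bin", {
  h <- climate_histogram(series_at(1, 1), 21)
  expect_equal(h$bins[21, 21], 1)
  h2 <- climate_histogram(series_at(-1, -1), 21)
  expect_equal(h2$bins[1, 1], 1)
})

test_that("binning matches the brute-force oracle bin-for-bin", {
  pts <- soniscape:::with_seed(42, {
    th <- runif(1000, 0, 2 * pi); r <- sqrt(runif(1000))
    list(p = r * cos(th), e = r * sin(th))
  })
  h <- climate_histogram(series_at(pts$p, pts$e), 21)
  expect_identical(h$bins, oracle_climate_bins(pts$p, pts$e, 21))
})

test_that("histograms normalise to one and merge like concatenation", {
  pts <- soniscape:::with_seed(9, list(p = runif(500, -1, 1),
                                       e = runif(500, -1, 1)))
  s1 <- series_at(pts$p[1:200], pts$e[1:200])
  s2 <- series_at(pts$p[201:500], pts$e[201:500])
  h1 <- climate_histogram(s1, 21); h2 <- climate_histogram(s2, 21)
  expect_equal(sum(h1$bins), 1, tolerance = 1e-12)
  h12 <- climate_merge(h1, h2)
  hall <- climate_histogram(series_at(pts$p, pts$e), 21)
  expect_equal(h12$bins, hall$bins, tolerance = 1e-12)
  expect_equal(h12$n_samples, 500)
})

test_that("empty series give an all-zero histogram", {
  h <- climate_histogram(series_at(numeric(0), numeric(0)), 21)
  expect_equal(h$n_samples, 0)
  expect_true(all(h$bins == 0))
})

test_that("bin counts must be odd and at least 3", {
  s <- series_at(0, 0)
  expect_error(climate_histogram(s, 20), class = "soniscape_error_config")
  expect_error(climate_histogram(s, 1), class = "soniscape_error_config")
})

test_that("quadrant fractions split by sign with zero-straddling mass centred", {
  h <- climate_histogram(series_at(rep(0, 10), rep(0, 10)), 21)
  qf <- quadrant_fractions(h)
  expect_equal(qf$fraction[qf$quadrant == "center"], 1)
  h2 <- climate_histogram(series_at(-0.5, 0.5), 21)
  qf2 <- quadrant_fractions(h2)
  expect_equal(qf2$fraction[qf2$quadrant == "chaotic"], 1)
  # mixed series: fractions match a direct per-frame sign count
  pts <- soniscape:::with_seed(5, list(p = runif(400, -1, 1),
                                       e = runif(400, -1, 1)))
  h3 <- climate_histogram(series_at(pts$p, pts$e), 21)
  qf3 <- quadrant_fractions(h3)
  expect_equal(sum(qf3$fraction), 1, tolerance = 1e-12)
  edges <- h3$edges
  centred <- function(v) {
    i <- findInterval(v, edges, rightmost.closed = TRUE)
    edges[i] < 0 & edges[i + 1] > 0
  }
  ctr <- centred(pts$p) | centred(pts$e)
  direct <- c(
    calm = mean(pts$p > 0 & pts$e < 0 & !ctr),
    lively = mean(pts$p > 0 & pts$e > 0 & !ctr),
    chaotic = mean(pts$p < 0 & pts$e > 0 & !ctr),
    boring = mean(pts$p < 0 & pts$e < 0 & !ctr),
    center = mean(ctr)
  )
  expect_equal(stats::setNames(qf3$fraction, qf3$quadrant), direct,
               tolerance = 1e-12)
})

test_that("climate distance is the total variation metric", {
  expect_equal(climate_distance(climate_histogram(series_at(0, 0), 21),
                                climate_histogram(series_at(0, 0), 21)), 0)
  h1 <- climate_histogram(series_at(1, 1), 21)
  h2 <- climate_histogram(series_at(-1, -1), 21)
  expect_equal(climate_distance(h1, h2), 1)
  hs <- lapply(1:3, function(s) {
    pts <- soniscape:::with_seed(s, list(p = runif(300, -1, 1),
                                         e = runif(300, -1, 1)))
    climate_histogram(series_at(pts$p, pts$e), 21)
  })
  # brute-force half-L1
  expect_equal(climate_distance(hs[[1]], hs[[2]]),
               0.5 * sum(abs(hs[[1]]$bins - hs[[2]]$bins)))
  # symmetry, identity, triangle inequality
  expect_equal(climate_distance(hs[[1]], hs[[2]]),
               climate_distance(hs[[2]], hs[[1]]))
  expect_equal(climate_distance(hs[[3]], hs[[3]]), 0)
  expect_lte(climate_distance(hs[[1]], hs[[3]]),
             climate_distance(hs[[1]], hs[[2]]) +
               climate_distance(hs[[2]], hs[[3]]) + 1e-12)
  expect_error(climate_distance(hs[[1]], climate_histogram(series_at(0, 0),
                                                           11)),
               class = "soniscape_error_input")
})

test_that("climates serialize to JSON and back", {
  pts <- soniscape:::with_seed(3, list(p = runif(100, -1, 1),
                                       e = runif(100, -1, 1)))
  h <- climate_histogram(series_at(pts$p, pts$e), 21)
  path <- file.path(withr::local_tempdir(), "climate.json")
  write_climate(h, path)
  back <- read_climate(path)
  expect_equal(back$bins, h$bins, tolerance = 1e-12)
  expect_equal(back$n_samples, h$n_samples)
  expect_s3_class(autoplot(h), "ggplot")
  expect_equal(sum(tidy(h)$fraction), 1, tolerance = 1e-12)
})
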