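cfg <- appraisal_config()

test_that("contribution weights scale linearly and clip at the range ends", {
  expect_identical(contribution_weight(0, c(0, 15)), 0)
  expect_identical(contribution_weight(15, c(0, 15)), 1)
  expect_identical(contribution_weight(50, c(30, 70)), 0.5)
  expect_identical(contribution_weight(-3, c(0, 15)), 0)
  expect_identical(contribution_weight(99, c(0, 15)), 1)
  expect_error(contribution_weight(1, c(10, 10)),
               class = "soniscape_error_config")
})

test_that("band audibility pools max-then-percentile over active frames", {
  cf <- round(exp(seq(log(60), log(7000), length.out = 32)))
  m <- matrix(0, 500, 32)
  expect_identical(band_audibility(m, cf, c(100, 5000), 5, 1, 50), 0)
  # one active cell inside band and scope -> its own level
  m[180, 10] <- 12
  expect_identical(band_audibility(m, cf, c(100, 5000), 4, 1, 50), 12)
  # still visible to later seconds through a 5 s scope
  expect_identical(band_audibility(m, cf, c(100, 5000), 8, 5, 50), 12)
  # outside the band -> unseen
  expect_identical(band_audibility(m, cf, c(3000, 7000), 4, 1, 50), 0)
  expect_error(band_audibility(m, cf, c(7500, 8000), 4, 1, 50),
               class = "soniscape_error_config")
})

test_that("band audibility equals the brute-force max-then-percentile oracle", {
  cf <- round(exp(seq(log(60), log(7000), length.out = 32)))
  for (seed in 1:3) {
    m <- soniscape:::with_seed(seed, {
      m0 <- matrix(0, 400, 32)
      hot <- sample(length(m0), 600)
      m0[hot] <- runif(600, 0, 30)
      m0
    })
    for (t in c(1, 3, 8)) {
      expect_identical(band_audibility(m, cf, c(200, 4000), t, 5, 50),
                       oracle_band_audibility(m, cf, c(200, 4000), t, 5, 50))
    }
  }
})

test_that("silence appraises to the origin", {
  ls0 <- make_layer_set()
  fr <- appraise_second(ls0, cfg, 3)
  expect_identical(c(fr$pleasantness, fr$eventfulness), c(0, 0))
})

test_that("saturated single rows land on their quadrant diagonals", {
  ls0 <- make_layer_set()
  cf <- ls0$center_freqs
  n <- nrow(ls0$second_fg)
  d <- 1 / sqrt(2)
  sat <- function(band, level) {
    m <- matrix(0, n, length(cf))
    m[, cf >= band[1] & cf < band[2]] <- level
    m
  }
  # minute foreground >= 15 dB -> chaotic diagonal
  fr <- appraise_second(make_layer_set(minute = sat(c(20, 23000), 20)),
                        cfg, 5)
  expect_equal(c(fr$pleasantness, fr$eventfulness), c(-d, d))
  # second foreground above the 2300 Hz split -> calm diagonal
  fr <- appraise_second(make_layer_set(second = sat(c(2300, 23000), 25)),
                        cfg, 5)
  expect_equal(c(fr$pleasantness, fr$eventfulness), c(d, -d))
  # second foreground below the split -> lively diagonal
  fr <- appraise_second(make_layer_set(second = sat(c(20, 2300), 25)),
                        cfg, 5)
  expect_equal(c(fr$pleasantness, fr$eventfulness), c(d, d))
  # loud hour background -> boring diagonal
  fr <- appraise_second(make_layer_set(bg = matrix(-20, n, length(cf))),
                        cfg, 5)
  expect_equal(c(fr$pleasantness, fr$eventfulness), c(-d, -d))
})

test_that("the table band assignment switch swaps the second-foreground pull", {
  cfg_tab <- appraisal_config(table_band_assignment = TRUE)
  n <- 500
  ls_hi <- make_layer_set(second = {
    m <- matrix(0, n, 32)
    m[, make_layer_set()$center_freqs >= 2300] <- 25
    m
  })
  fr <- appraise_second(ls_hi, cfg_tab, 5)
  expect_equal(c(fr$pleasantness, fr$eventfulness),
               c(1, 1) / sqrt(2))  # lively under the table reading
})

test_that("center rows damp extremity but never pull from the origin", {
  cf <- make_layer_set()$center_freqs
  m <- matrix(0, 500, 32)
  m[, cf >= 2300] <- 25   # hour-foreground high band: quadrant 'center'
  fr <- appraise_second(make_layer_set(hour = m), cfg, 5)
  expect_identical(c(fr$pleasantness, fr$eventfulness), c(0, 0))
  # combined with a saturated chaotic row it halves the magnitude
  mm <- matrix(20, 500, 32)
  fr2 <- appraise_second(make_layer_set(hour = m, minute = mm), cfg, 5)
  expect_equal(sqrt(fr2$pleasantness^2 + fr2$eventfulness^2), 0.5)
})

test_that("every appraisal stays inside the unit disk", {
  for (seed in 1:5) {
    ls1 <- soniscape:::with_seed(seed, make_layer_set(
      n_frames = 250,
      second = matrix(runif(250 * 32, 0, 40), 250),
      minute = matrix(runif(250 * 32, 0, 30), 250),
      hour = matrix(runif(250 * 32, 0, 30), 250),
      bg = matrix(runif(250 * 32, -80, -20), 250)
    ))
    s <- appraise(ls1, cfg)
    expect_true(all(s$pleasantness^2 + s$eventfulness^2 <= 1 + 1e-12))
    expect_true(all(dplyr::select(s, dplyr::starts_with("w_")) >= 0 &
                      dplyr::select(s, dplyr::starts_with("w_")) <= 1))
  }
})

test_that("raising the minute foreground never raises pleasantness", {
  cf <- make_layer_set()$center_freqs
  base_second <- matrix(0, 250, 32)
  base_second[, cf >= 2300] <- 15
  prev_p <- Inf; prev_e <- -Inf
  for (a in seq(0, 15, by = 3)) {
    ls1 <- make_layer_set(n_frames = 250, second = base_second,
                          minute = matrix(a, 250, 32))
    fr <- appraise_second(ls1, cfg, 3)
    expect_lte(fr$pleasantness, prev_p + 1e-12)
    expect_gte(fr$eventfulness, prev_e - 1e-12)
    prev_p <- fr$pleasantness; prev_e <- fr$eventfulness
  }
})

test_that("the series has one frame per full second, in order", {
  ls1 <- make_layer_set(n_frames = 500, frame_rate = 50)  # 10 s
  s <- appraise(ls1, cfg)
  expect_identical(s$t, 1:10)
  empty <- appraise(make_layer_set(n_frames = 20, frame_rate = 50), cfg)
  expect_identical(nrow(empty), 0L)
})

test_that("a missing layer is reported as invalid input", {
  ls1 <- make_layer_set()
  ls1$minute_fg <- NULL
  expect_error(appraise_second(ls1, cfg, 1),
               class = "soniscape_error_input")
  expect_error(appraise_second(make_layer_set(), cfg, 99),
               class = "soniscape_error_index")
})

test_that("series round-trip and summary methods work", {
  ls1 <- soniscape:::with_seed(2, make_layer_set(
    n_frames = 250, second = matrix(runif(250 * 32, 0, 30), 250)))
  s <- appraise(ls1, cfg)
  path <- file.path(withr::local_tempdir(), "series.csv")
  write_appraisal_series(s, path)
  back <- read_appraisal_series(path)
  expect_equal(back$pleasantness, s$pleasantness, tolerance = 1e-12)
  g <- glance(s)
  expect_equal(g$n_seconds, 5)
  expect_equal(sum(g$frac_calm, g$frac_lively, g$frac_chaotic,
                   g$frac_boring, g$frac_center), 1)
  expect_s3_class(autoplot(s), "ggplot")
  expect_true("weight" %in% names(tidy(s)))
})
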