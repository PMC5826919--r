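test_that("rolling-ball subtraction removes what a ball can roll under", {
  expect_true(all(rolling_ball_subtract(matrix(7, 30, 30), 5) == 0))

  spike <- matrix(0, 120, 120); spike[60, 60] <- 500
  out <- rolling_ball_subtract(spike, 50)
  expect_lt(max(abs(out - spike)), 0.1)

  expect_error(rolling_ball_subtract(matrix(0, 10, 10), 50), "exceeds")
  expect_error(rolling_ball_subtract(matrix(0, 10, 10), 0.5), ">= 1")
})

test_that("rolling-ball matches the double-loop ball-opening oracle", {
  set.seed(17)
  for (radius in c(3, 8)) {
    img <- matrix(runif(48 * 40, 0, 80), 48, 40)
    img[20:24, 15:19] <- img[20:24, 15:19] + 300   # a bright feature
    expect_equal(rolling_ball_subtract(img, radius),
                 oracle_rolling_ball(img, radius), tolerance = 1e-12)
  }
})

test_that("isodata threshold separates a two-level image and matches its histogram oracle", {
  two <- matrix(c(rep(10, 50), rep(200, 14)), 8)
  at <- auto_threshold(two)
  expect_identical(at$mask, two == 200)
  expect_identical(at$n_selected, 14L)

  set.seed(23)
  img <- matrix(c(rnorm(3000, 30, 6), rnorm(600, 150, 20)), 60)
  expect_equal(auto_threshold(img)$threshold,
               oracle_isodata(as.numeric(img)), tolerance = 1e-9)

  expect_error(auto_threshold(matrix(5, 10, 10)), "constant")
})

test_that("M1 matches hand arithmetic and its per-pixel oracle exactly", {
  green <- matrix(c(10, 20, 30, 40), 2)
  red <- matrix(c(100, 0, 100, 0), 2)     # above-threshold flags 1,0,1,0
  sel <- matrix(TRUE, 2, 2)
  res <- manders_m1(green, red, selection = sel, red_threshold = 50)
  expect_equal(res$m1, 0.4)

  expect_equal(manders_m1(green, matrix(99, 2, 2), sel,
                          red_threshold = 50)$m1, 1)
  expect_equal(manders_m1(green, matrix(1, 2, 2), sel,
                          red_threshold = 50)$m1, 0)
  expect_error(manders_m1(matrix(0, 2, 2), red, sel, red_threshold = 50),
               "zero green")

  f <- render_coloc_pair(0.6, imaging = imaging_spec(seed = 19))
  res2 <- manders_m1(f$green, f$red)
  sel2 <- f$green > res2$green_threshold
  expect_identical(res2$m1, oracle_m1(f$green, f$red, sel2,
                                      res2$threshold_value))
  # intensity invariance of the green channel
  res3 <- manders_m1(f$green * 3.7, f$red, selection = sel2,
                     red_threshold = res2$threshold_value)
  expect_equal(res3$m1,
               manders_m1(f$green, f$red, selection = sel2,
                          red_threshold = res2$threshold_value)$m1,
               tolerance = 1e-12)
})

test_that("measured M1 rises monotonically with the generated overlap", {
  m1s <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(ov) {
    f <- render_coloc_pair(ov, imaging = noise_free_imaging())
    manders_m1(f$green, f$red)$m1
  }, numeric(1))
  expect_true(all(diff(m1s) > 0))
})

test_that("the field pipeline summarises replicates and tolerates smooth background", {
  f <- render_coloc_pair(0.75, imaging = imaging_spec(seed = 57))
  out3 <- coloc_pipeline(list(f, f, f))
  expect_equal(out3$summary$sd_m1, 0)
  expect_equal(out3$summary$n_fields, 3)
  out1 <- coloc_pipeline(list(f))
  expect_true(is.na(out1$summary$sd_m1))

  clean <- render_coloc_pair(0.5, imaging = imaging_spec(seed = 71))
  dirty <- render_coloc_pair(0.5, imaging = imaging_spec(seed = 71),
                             background_amplitude = 200)
  m_clean <- coloc_pipeline(list(clean))$summary$mean_m1
  m_dirty <- coloc_pipeline(list(dirty))$summary$mean_m1
  expect_lt(abs(m_clean - m_dirty), 0.02)
})
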