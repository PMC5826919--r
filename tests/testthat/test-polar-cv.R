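test_that("polar transform of a constant image is constant", {
  P <- polar_transform(matrix(7.5, 41, 41), c(20, 20), 15, 90)
  expect_true(all(abs(P - 7.5) < 1e-12))
})

test_that("a single bright pixel maps to the nearest (angle, radius) bin", {
  img <- matrix(0, 41, 41)
  px <- c(24, 16)   # (x, y), 0-based
  img[px[2] + 1, px[1] + 1] <- 100
  ctr <- c(20, 20)
  P <- polar_transform(img, ctr, 12, n_angle_bins = 72,
                       n_radial_samples = 25)
  hit <- which(P == max(P), arr.ind = TRUE)
  # brute force: the sample point closest to the bright pixel
  angles <- attr(P, "angles"); radii <- attr(P, "radii")
  d2 <- outer(seq_along(angles), seq_along(radii), function(i, j) {
    (ctr[1] + radii[j] * cos(angles[i]) - px[1])^2 +
      (ctr[2] + radii[j] * sin(angles[i]) - px[2])^2
  })
  nearest <- which(d2 == min(d2), arr.ind = TRUE)
  expect_identical(unname(hit[1, ]), unname(nearest[1, ]))
})

test_that("rotating the pattern by a quarter turn cyclically shifts the polar image", {
  ang <- c(0.3, 1.1, 2.0, 3.4, 4.4, 5.5)
  im0 <- noise_free_imaging()
  ctr <- c(31.5, 31.5)
  mk <- function(a) render_cell(
    cell_spec(ctr, 8, "punctate", n_puncta = 6, puncta_contrast = 3,
              puncta_angles = a), im0, 64)$ideal
  P1 <- polar_transform(mk(ang), ctr, 11.2, 360)
  P2 <- polar_transform(mk((ang + pi / 2) %% (2 * pi)), ctr, 11.2, 360)
  k <- 90
  shifted <- P1[((seq_len(360) - 1 - k) %% 360) + 1, ]
  expect_lt(max(abs(P2 - shifted)), 1e-6)
})

test_that("angular profiles average the requested radial band", {
  # uniform disc: profile constant at the disc value
  img <- matrix(0, 41, 41)
  xs <- matrix(rep(0:40, each = 41), 41); ys <- t(xs)
  img[(xs - 20)^2 + (ys - 20)^2 <= 18^2] <- 3
  prof <- angular_profile(polar_transform(img, c(20, 20), 15, 90))
  expect_true(all(abs(prof$intensities - 3) < 1e-9))

  # cytoplasm removal excludes a central disc of 20% area:
  # r_min = r_max * sqrt(0.2), i.e. ~4.47 px for r_max = 10 px
  P <- polar_transform(img, c(20, 20), 10, 90)
  prof2 <- angular_profile(P, cytoplasm_removal = TRUE)
  expect_true(prof2$cytoplasm_removed)
  expect_identical(prof2$n_radial_samples,
                   sum(attr(P, "radii") >= 4.4721360))
  manual <- angular_profile(P, r_min_px = 4.4721360)
  expect_equal(prof2$intensities, manual$intensities)
  expect_error(angular_profile(P, r_min_px = 9.9, r_max_px = 9.8), "r_min")
})

test_that("cytoplasm removal raises the CV of a cell with bright cytoplasm", {
  res <- seeded_punctate_cell(12, imaging = noise_free_imaging())
  sp <- res$spec; sp$cytoplasm_level <- 0.8
  r <- render_cell(sp, noise_free_imaging(), res$size)
  P <- polar_transform(r$ideal, res$centre, 1.4 * 8, 360)
  cv_with <- cv_factor(angular_profile(P, cytoplasm_removal = TRUE))$cv
  cv_without <- cv_factor(angular_profile(P))$cv
  expect_gt(cv_with, cv_without)
})

test_that("the CV factor matches hand arithmetic and closed forms", {
  expect_equal(cv_factor(rep(4, 100))$cv, 0)
  two <- cv_factor(c(1, 3))
  expect_equal(two$sigma, 1)
  expect_equal(two$mu, 2)
  expect_equal(two$cv, 50)
  th <- 2 * pi * (0:359) / 360
  expect_equal(cv_factor(1 + 0.2 * cos(th))$cv, 100 * 0.2 / sqrt(2),
               tolerance = 1e-6)
  expect_error(cv_factor(rep(0, 360)), "floor")
  expect_equal(cv_factor(c(1, 3), sd_type = "sample")$sigma, sd(c(1, 3)))
})

test_that("CV is invariant to intensity rescaling and monotone in punctum contrast", {
  res <- seeded_punctate_cell(14, imaging = noise_free_imaging())
  cv1 <- cv_for_cell(res$render$ideal, res$centre, 8)$cv
  cv2 <- cv_for_cell(res$render$ideal * 37.2, res$centre, 8)$cv
  expect_identical(cv1, cv2)

  cvs <- vapply(c(1.5, 2, 3, 4, 6), function(ct) {
    sp <- res$spec; sp$puncta_contrast <- ct
    r <- render_cell(sp, noise_free_imaging(), res$size)
    cv_for_cell(r$ideal, res$centre, 8)$cv
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
})

test_that("group comparison reproduces the pooled t-test by hand", {
  same <- cv_group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  cmp <- cv_group_compare(c(1, 2, 3), c(11, 12, 13))
  expect_equal(cmp$t, -10 / sqrt(2 / 3), tolerance = 1e-4) # t = -12.247
  expect_equal(cmp$p, 2 * pt(-10 / sqrt(2 / 3), df = 4), tolerance = 1e-6)
  expect_identical(cmp$stars, "***")
  expect_error(cv_group_compare(c(1), c(1, 2)), ">= 2")
  expect_identical(significance_stars(0.3), "ns")
  expect_identical(significance_stars(2e-5), "****")
})

test_that("ring radius is recovered within half a pixel and fails cleanly on blank images", {
  r <- render_cell(cell_spec(c(31.5, 31.5), 8, "homogeneous_ring"),
                   noise_free_imaging(), 64)
  expect_lt(abs(measure_cell_radius(r$ideal, c(31.5, 31.5)) - 8), 0.5)
  rn <- render_cell(cell_spec(c(31.5, 31.5), 8, "homogeneous_ring"),
                    imaging_spec(seed = 2), 64)
  expect_lt(abs(measure_cell_radius(rn$image, c(31.5, 31.5)) - 8), 0.5)
  expect_error(measure_cell_radius(matrix(0, 64, 64), c(31.5, 31.5)),
               "maximum")
})
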