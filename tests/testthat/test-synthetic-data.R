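test_that("cell specs enforce their geometric invariants", {
  expect_error(cell_spec(c(20, 20), 2), "radius")
  expect_error(cell_spec(c(20, 20), 8, "punctate", n_puncta = 0),
               "n_puncta >= 1")
  expect_error(cell_spec(c(20, 20), 8, "punctate", n_puncta = 3,
                         puncta_angles = c(0, 1)), "length")
  expect_error(cell_spec(c(20, 20), 8, "punctate", n_puncta = 2,
                         puncta_angles = c(0, 2 * pi)), "2\\*pi")
})

test_that("noise-free top-hat ring renders at exactly one on-ring value", {
  sp <- cell_spec(c(31.5, 31.5), 8, "homogeneous_ring",
                  cytoplasm_level = 0.4, amplitude = 600,
                  ring_profile = "tophat")
  im <- imaging_spec(psf_sigma_px = 0, photon_scale = Inf, read_noise_sd = 0)
  r <- render_cell(sp, im, 64)
  ring_vals <- r$image[r$masks$membrane_ring]
  expect_true(all(ring_vals == 600))
  cyto_vals <- r$image[r$masks$cytoplasm]
  expect_true(all(cyto_vals == 0.4 * 600))
  expect_true(all(r$image[!r$masks$membrane_ring & !r$masks$cytoplasm] == 0))
})

test_that("punctate ground-truth profile has exactly n_puncta maxima", {
  for (n in c(2, 4, 6)) {
    sp <- cell_spec(c(40, 40), 8, "punctate", n_puncta = n,
                    puncta_contrast = 3)
    prof <- ideal_angular_profile(sp, 2 * pi * (0:719) / 720)
    up <- prof > c(tail(prof, 1), head(prof, -1))
    dn <- prof > c(tail(prof, -1), head(prof, 1))
    expect_identical(sum(up & dn), as.integer(n))
  }
})

test_that("renders are bit-identical under the same seed and differ across seeds", {
  sp <- cell_spec(c(31.5, 31.5), 8, "punctate", n_puncta = 6,
                  puncta_contrast = 3)
  r1 <- render_cell(sp, imaging_spec(seed = 10), 64)
  r2 <- render_cell(sp, imaging_spec(seed = 10), 64)
  r3 <- render_cell(sp, imaging_spec(seed = 11), 64)
  expect_identical(r1$image, r2$image)
  expect_false(identical(r1$image, r3$image))
  t1 <- simulate_bleach_trace(bleach_spec(100, 1000, noise_sd = 5, seed = 4))
  t2 <- simulate_bleach_trace(bleach_spec(100, 1000, noise_sd = 5, seed = 4))
  expect_identical(t1$intensity, t2$intensity)
  f1 <- render_coloc_pair(0.5, imaging = imaging_spec(seed = 8))
  f2 <- render_coloc_pair(0.5, imaging = imaging_spec(seed = 8))
  expect_identical(f1$green, f2$green)
  expect_identical(f1$red, f2$red)
})

test_that("fields carry annotations, reject overlap, allow the empty case", {
  im <- imaging_spec(seed = 3)
  empty <- render_field(list(), im, 48)
  expect_identical(nrow(empty$annotations), 0L)
  expect_identical(dim(empty$image), c(48L, 48L))

  cells <- lapply(seq_len(20), function(i) {
    gx <- (i - 1) %% 5; gy <- (i - 1) %/% 5
    cell_spec(c(20 + 36 * gx, 20 + 36 * gy), 8, "homogeneous_ring")
  })
  fld <- render_field(cells, im, 180, groups = rep("wt", 20))
  expect_identical(nrow(fld$annotations), 20L)
  expect_equal(fld$annotations$centre_x,
               vapply(cells, function(s) s$centre[1], numeric(1)))

  expect_error(render_field(list(cell_spec(c(20, 20), 8),
                                 cell_spec(c(30, 20), 8)), im, 64),
               "overlap")
})

test_that("shot-noise variance grows linearly with ideal intensity", {
  ideal <- matrix(rep(c(50, 150, 400, 1000, 2000, 3500), each = 4), 4)
  im <- imaging_spec(psf_sigma_px = 0, photon_scale = 0.5, read_noise_sd = 0,
                     bit_depth = 16)
  reps <- vapply(seq_len(1000), function(i) {
    im$seed <- 50000 + i
    as.numeric(cocciq:::apply_imaging_noise(ideal, im))
  }, numeric(length(ideal)))
  v <- apply(reps, 1, var)
  slope <- coef(lm(v ~ 0 + as.numeric(ideal)))[[1]]
  expect_lt(abs(slope - 1 / 0.5) / (1 / 0.5), 0.10)
})

test_that("PSF convolution conserves total intensity away from the frame edge", {
  r <- seeded_punctate_cell(21, imaging = noise_free_imaging(2))$render
  expect_lt(abs(sum(r$ideal) / sum(r$unblurred) - 1), 0.01)
})

test_that("bleach traces follow the closed-form decay", {
  tr <- simulate_bleach_trace(bleach_spec(100, 1000, offset = 0,
                                          n_frames = 200))
  expect_equal(tr$intensity[1], 1000)
  expect_equal(tr$intensity[101], 1000 * exp(-1), tolerance = 1e-12)
  expect_true(all(diff(tr$intensity) < 0))
  # a tau pair of 100 vs 125 frames corresponds to a FRET efficiency of 0.2
  expect_equal(1 - 100 / 125, 0.2)
  expect_error(bleach_spec(100, 1000, n_frames = 5), "n_frames")
})

test_that("coloc pair ground truth matches the requested overlap", {
  im <- imaging_spec(seed = 31)
  f1 <- render_coloc_pair(1, imaging = im)
  expect_equal(f1$gt_m1, 1)
  f0 <- render_coloc_pair(0, imaging = im)
  expect_equal(f0$gt_m1, 0)
  f <- render_coloc_pair(0.75, imaging = im)
  sel <- f$ideal_green > 0
  m1 <- oracle_m1(f$ideal_green, f$ideal_red, sel,
                  red_threshold = max(f$ideal_red) / 2)
  expect_lt(abs(m1 - 0.75), 0.02)
})
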