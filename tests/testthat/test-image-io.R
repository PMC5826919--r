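test_that("TIFF round trips are lossless at all supported bit depths", {
  for (bits in c(8, 12, 16)) {
    img <- matrix(sample.int(2^bits, 300, replace = TRUE) - 1, 15, 20)
    path <- withr::local_tempfile(fileext = ".tif")
    write_image(img, path, bit_depth = bits)
    back <- read_image(path)
    expect_equal(unname(back[, ]), img, ignore_attr = TRUE)
  }
})

test_that("multi-frame stacks preserve the frame axis", {
  arr <- array(sample.int(4096, 720 * 8 * 8, replace = TRUE) - 1,
               c(720, 8, 8))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(arr, path, bit_depth = 12)
  back <- read_image(path)
  expect_identical(dim(back), c(720L, 8L, 8L))
  expect_equal(back[377, , ], arr[377, , ], ignore_attr = TRUE)
})

test_that("a non-TIFF payload is rejected with the offending path", {
  path <- withr::local_tempfile(fileext = ".tif")
  writeLines("not an image", path)
  expect_error(read_image(path), path, fixed = TRUE)
})

test_that("annotation round trips and row validation behave", {
  im <- imaging_spec(seed = 3)
  fld <- render_field(list(cell_spec(c(20, 20), 8),
                           cell_spec(c(44, 40), 8)), im, 64,
                      groups = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(fld$annotations, path)
  back <- read_annotations(path, image = fld$image)
  expect_equal(back$centre_x, fld$annotations$centre_x)
  expect_equal(back$group, fld$annotations$group)

  bad <- fld$annotations
  bad$radius_px[2] <- 0
  write_annotations(bad, path)
  expect_error(read_annotations(path), "row 2")

  ann0 <- fld$annotations[0, ]
  write_annotations(ann0, path)
  expect_identical(nrow(read_annotations(path)), 0L)

  bad2 <- fld$annotations
  bad2$centre_x[1] <- 500
  write_annotations(bad2, path)
  expect_error(read_annotations(path, image = fld$image), "cell_001")
})

test_that("centre refinement recovers ground truth within half a pixel", {
  errs <- vapply(1:50, function(i) {
    r <- render_cell(cell_spec(c(31.5, 31.5), 8, "homogeneous_ring"),
                     imaging_spec(seed = 700 + i), 64)
    est <- estimate_centre(r$image, c(33.5, 30.0), 8)
    sqrt(sum((est - c(31.5, 31.5))^2))
  }, numeric(1))
  expect_lt(max(errs), 0.5)
})

test_that("centre refinement is exact on a symmetric noise-free ring and equivariant under translation", {
  im0 <- noise_free_imaging()
  r <- render_cell(cell_spec(c(31.5, 31.5), 8, "homogeneous_ring"), im0, 64)
  expect_equal(estimate_centre(r$ideal, c(32.5, 31.0), 8), c(31.5, 31.5))
  r2 <- render_cell(cell_spec(c(36.5, 26.5), 8, "homogeneous_ring"), im0, 64)
  expect_equal(estimate_centre(r2$ideal, c(37.5, 26.0), 8), c(36.5, 26.5))
  expect_error(estimate_centre(matrix(0, 64, 64), c(31.5, 31.5), 8),
               "centring")
})
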