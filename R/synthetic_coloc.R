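# Two-channel colocalisation fields with controlled signal overlap.

#' Render a two-channel field with known signal overlap
#'
#' Places equal-intensity circular foci (uniform discs of radius
#' `focus_radius_px`) in two channels: a fraction `overlap_fraction` of the
#' green channel's foci coincide exactly with red foci, the rest of each
#' channel's foci are placed disjointly, all positions pairwise separated by
#' at least `min_separation_px`. On the ideal (unblurred, noise-free) images
#' the Manders M1 of green against the red-signal mask equals
#' `round(overlap_fraction * n_foci) / n_foci` exactly, so ground truth
#' matches `overlap_fraction` up to that quantisation. Both channels are
#' then blurred and passed through the imaging noise model; an optional
#' smooth background gradient exercises rolling-ball subtraction.
#'
#' @param overlap_fraction target fraction in `[0, 1]` of green signal
#'   intensity lying inside red's signal region.
#' @param n_foci foci per channel (default 20).
#' @param field_size field side in pixels (default 160).
#' @param focus_radius_px focus disc radius (default 4).
#' @param focus_intensity disc intensity in counts (default 1000).
#' @param min_separation_px minimum distance between distinct foci centres.
#' @param imaging an [imaging_spec()]; its `seed` drives both placement and
#'   noise (the red channel uses `seed + 1`).
#' @param background_amplitude peak of an added smooth diagonal background
#'   gradient in counts (0 disables).
#' @return Object of class `cocciq_coloc_field`: noisy `green`/`red`
#'   images, `ideal_green`/`ideal_red` (unblurred, background-free),
#'   logical signal `masks`, `gt_m1`, `overlap_fraction`.
#' @export
render_coloc_pair <- function(overlap_fraction, n_foci = 20, field_size = 160,
                              focus_radius_px = 4, focus_intensity = 1000,
                              min_separation_px = 14,
                              imaging = imaging_spec(),
                              background_amplitude = 0) {
  stopifnot(is_scalar_num(overlap_fraction), overlap_fraction >= 0,
            overlap_fraction <= 1, is_scalar_num(n_foci), n_foci >= 1,
            inherits(imaging, "cocciq_imaging_spec"))
  k <- round(overlap_fraction * n_foci)
  n_points <- 2L * n_foci - k     # shared + green-only + red-only
  margin <- focus_radius_px + 3 * imaging$psf_sigma_px + 2
  if (field_size - 2 * margin < min_separation_px) {
    stopf("field_size %d too small for the requested foci", field_size)
  }
  pts <- with_seed_if(imaging$seed, {
    acc <- matrix(numeric(0), ncol = 2)
    attempts <- 0
    while (nrow(acc) < n_points) {
      attempts <- attempts + 1
      if (attempts > 20000 * n_points) {
        stopf("could not place %d foci with separation %g in a %d px field",
              n_points, min_separation_px, field_size)
      }
      p <- runif(2, margin, field_size - 1 - margin)
      if (nrow(acc) == 0 ||
          min(sqrt((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2)) >
            min_separation_px) {
        acc <- rbind(acc, p)
      }
    }
    acc
  })
  shared <- pts[seq_len(k), , drop = FALSE]
  green_only <- pts[k + seq_len(n_foci - k), , drop = FALSE]
  red_only <- pts[n_foci + seq_len(n_foci - k), , drop = FALSE]
  xs <- matrix(rep(0:(field_size - 1), each = field_size), nrow = field_size)
  ys <- matrix(rep(0:(field_size - 1), times = field_size), nrow = field_size)
  paint <- function(centres) {
    img <- matrix(0, field_size, field_size)
    mask <- matrix(FALSE, field_size, field_size)
    for (i in seq_len(nrow(centres))) {
      inside <- (xs - centres[i, 1])^2 + (ys - centres[i, 2])^2 <=
        focus_radius_px^2
      img <- img + focus_intensity * inside
      mask <- mask | inside
    }
    list(img = img, mask = mask)
  }
  g <- paint(rbind(shared, green_only))
  r <- paint(rbind(shared, red_only))
  gt_m1 <- if (sum(g$img) > 0) sum(g$img[r$mask]) / sum(g$img) else NA_real_
  bg <- if (background_amplitude > 0) {
    background_amplitude * (0.3 + 0.7 * (xs + ys) / (2 * (field_size - 1)))
  } else 0
  channel <- function(ideal, seed_shift) {
    im <- imaging
    if (!is.null(im$seed)) im$seed <- im$seed + seed_shift
    apply_imaging_noise(gaussian_blur(ideal + bg, imaging$psf_sigma_px), im)
  }
  structure(list(green = channel(g$img, 0L), red = channel(r$img, 1L),
                 ideal_green = g$img, ideal_red = r$img,
                 masks = list(green = g$mask, red = r$mask),
                 gt_m1 = gt_m1, overlap_fraction = overlap_fraction,
                 n_foci = n_foci),
            class = "cocciq_coloc_field")
}
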