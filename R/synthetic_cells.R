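#' Specify a synthetic coccoid cell
#'
#' Describes the ground-truth fluorescence pattern of a single ~1 micron
#' coccoid cell imaged at its mid-plane: a membrane ring with optional
#' discrete puncta, a septal band, and a uniform cytoplasmic component. The
#' geometry is two-dimensional because that is what the downstream angular CV
#' statistic consumes.
#'
#' The membrane ring has a Gaussian radial cross-section of standard deviation
#' `ring_sigma_px` (default 1.5 px); `ring_profile = "tophat"` replaces it
#' with a uniform annulus of half-width `ring_sigma_px`, convenient for exact
#' noise-free identities. Puncta are angular Gaussian bumps (sd
#' `puncta_ang_sd` radians) multiplying the ring intensity so that the
#' punctum peak is `puncta_contrast` times the ring baseline. `uniform_mix`
#' linearly mixes the angular modulation towards a uniform ring
#' (0 = full pattern, 1 = uniform), emulating the collapse of punctate
#' localisation seen at protein over-expression.
#'
#' @param centre numeric length-2, cell centre `(x, y)` in 0-based pixel
#'   coordinates.
#' @param radius_px cell radius in pixels; must be at least 3 (below this the
#'   ring is unresolvable at unit pixel spacing).
#' @param pattern one of `"homogeneous_ring"`, `"punctate"`, `"septal"`,
#'   `"ring_plus_septum"`.
#' @param n_puncta number of puncta (required >= 1 for `pattern = "punctate"`).
#' @param puncta_contrast ratio >= 1 of punctum peak to ring baseline.
#' @param puncta_angles optional explicit punctum angles in radians, length
#'   `n_puncta`, all in `[0, 2*pi)`; when `NULL`, angles are equally spaced
#'   starting at a fixed phase.
#' @param cytoplasm_level fraction >= 0 of the ring amplitude present
#'   uniformly in the cell interior (inside the inner edge of the ring).
#' @param septum_angle orientation of the septal band in radians.
#' @param amplitude peak ring intensity in camera counts.
#' @param ring_sigma_px radial scale of the membrane ring in pixels.
#' @param puncta_ang_sd angular standard deviation of a punctum in radians.
#' @param uniform_mix mixing weight in `[0, 1]` towards a uniform ring.
#' @param ring_profile `"gaussian"` (default) or `"tophat"` radial profile.
#' @return An object of class `cocciq_cell_spec`.
#' @seealso [render_cell()], [ideal_angular_profile()]
#' @export
cell_spec <- function(centre, radius_px,
                      pattern = c("homogeneous_ring", "punctate", "septal",
                                  "ring_plus_septum"),
                      n_puncta = 0L, puncta_contrast = 1,
                      puncta_angles = NULL, cytoplasm_level = 0,
                      septum_angle = 0, amplitude = 1000,
                      ring_sigma_px = 1.5, puncta_ang_sd = 0.15,
                      uniform_mix = 0,
                      ring_profile = c("gaussian", "tophat")) {
  pattern <- match.arg(pattern)
  ring_profile <- match.arg(ring_profile)
  stopifnot(is.numeric(centre), length(centre) == 2L, all(is.finite(centre)),
            is_scalar_num(radius_px),
            is_scalar_num(puncta_contrast), puncta_contrast >= 1,
            is_scalar_num(cytoplasm_level), cytoplasm_level >= 0,
            is_scalar_num(amplitude), amplitude > 0,
            is_scalar_num(ring_sigma_px), ring_sigma_px > 0,
            is_scalar_num(puncta_ang_sd), puncta_ang_sd > 0,
            is_scalar_num(uniform_mix), uniform_mix >= 0, uniform_mix <= 1)
  if (radius_px < 3) {
    stopf("radius_px must be >= 3 px (got %g): ring unresolvable", radius_px)
  }
  n_puncta <- as.integer(n_puncta)
  if (n_puncta < 0) stopf("n_puncta must be >= 0")
  if (pattern == "punctate" && n_puncta < 1) {
    stopf("pattern = 'punctate' requires n_puncta >= 1")
  }
  if (!is.null(puncta_angles)) {
    if (length(puncta_angles) != n_puncta) {
      stopf("puncta_angles must have length n_puncta (%d)", n_puncta)
    }
    if (any(puncta_angles < 0 | puncta_angles >= 2 * pi)) {
      stopf("puncta_angles must lie in [0, 2*pi)")
    }
  } else if (n_puncta > 0) {
    puncta_angles <- wrap_angle(2 * pi * (seq_len(n_puncta) - 1) / n_puncta + 0.3)
  }
  structure(list(centre = as.numeric(centre), radius_px = radius_px,
                 pattern = pattern, n_puncta = n_puncta,
                 puncta_contrast = puncta_contrast,
                 puncta_angles = puncta_angles,
                 cytoplasm_level = cytoplasm_level,
                 septum_angle = septum_angle, amplitude = amplitude,
                 ring_sigma_px = ring_sigma_px,
                 puncta_ang_sd = puncta_ang_sd,
                 uniform_mix = uniform_mix, ring_profile = ring_profile),
            class = "cocciq_cell_spec")
}

#' Specify the imaging model
#'
#' Widefield camera model: the ideal (pattern) image is blurred with an
#' isotropic Gaussian PSF, photon shot noise is applied as
#' `Poisson(photon_scale * ideal) / photon_scale`, Gaussian read noise of
#' standard deviation `read_noise_sd` counts is added, and the result is
#' quantised (rounded) and clipped to `[0, 2^bit_depth - 1]`.
#'
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels (>= 0;
#'   0 disables blurring).
#' @param photon_scale expected photons per unit ideal intensity (> 0);
#'   `Inf` disables shot noise.
#' @param read_noise_sd camera read noise sd in counts (>= 0).
#' @param bit_depth one of 8, 12, 16.
#' @param seed integer seed making the render bit-reproducible; `NULL` uses
#'   the current RNG stream.
#' @return An object of class `cocciq_imaging_spec`.
#' @export
imaging_spec <- function(psf_sigma_px = 1.3, photon_scale = 1,
                         read_noise_sd = 3, bit_depth = 12, seed = NULL) {
  stopifnot(is_scalar_num(psf_sigma_px), psf_sigma_px >= 0,
            is.numeric(photon_scale), length(photon_scale) == 1L,
            photon_scale > 0,
            is_scalar_num(read_noise_sd), read_noise_sd >= 0)
  if (!bit_depth %in% c(8, 12, 16)) stopf("bit_depth must be 8, 12 or 16")
  structure(list(psf_sigma_px = psf_sigma_px, photon_scale = photon_scale,
                 read_noise_sd = read_noise_sd,
                 bit_depth = as.integer(bit_depth),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cocciq_imaging_spec")
}

# Angular modulation m(theta) of the ring intensity for a spec, closed form.
angular_modulation <- function(spec, theta) {
  m <- rep(1, length(theta))
  if (spec$n_puncta > 0 && spec$pattern %in% c("punctate")) {
    bump <- rep(0, length(theta))
    for (phi in spec$puncta_angles) {
      d <- ((theta - phi + pi) %% (2 * pi)) - pi
      bump <- pmax(bump, exp(-0.5 * (d / spec$puncta_ang_sd)^2))
    }
    m <- 1 + (spec$puncta_contrast - 1) * bump
  }
  (1 - spec$uniform_mix) * m + spec$uniform_mix
}

#' Ground-truth angular intensity profile of a cell spec
#'
#' Closed-form, pre-blur angular profile of the membrane signal: the ring
#' amplitude times the angular modulation (puncta bumps, uniform mixing).
#' Used as the oracle for profile shape, punctum counts and rotation tests.
#'
#' @param spec a [cell_spec()].
#' @param angles angles in radians at which to evaluate (default 360 equally
#'   spaced bin centres over `[0, 2*pi)`).
#' @return Numeric vector of intensities, same length as `angles`.
#' @export
ideal_angular_profile <- function(spec, angles = 2 * pi * (0:359) / 360) {
  spec$amplitude * angular_modulation(spec, angles)
}

# Evaluate the unblurred pattern and its geometry masks on a pixel grid.
# `xs`, `ys` are 0-based pixel coordinate vectors (columns / rows).
eval_cell_pattern <- function(spec, xs, ys) {
  X <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  Y <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  dx <- X - spec$centre[1]; dy <- Y - spec$centre[2]
  rho <- sqrt(dx^2 + dy^2)
  theta <- wrap_angle(atan2(dy, dx))
  s <- spec$ring_sigma_px
  ring_extent <- if (spec$ring_profile == "tophat") s else 2 * s
  radial <- if (spec$ring_profile == "tophat") {
    (abs(rho - spec$radius_px) <= s) * 1
  } else {
    exp(-0.5 * ((rho - spec$radius_px) / s)^2)
  }
  ideal <- matrix(0, length(ys), length(xs))
  masks <- list()
  has_ring <- spec$pattern %in% c("homogeneous_ring", "punctate",
                                  "ring_plus_septum")
  if (has_ring) {
    ideal <- ideal + spec$amplitude * radial * angular_modulation(spec, theta)
    masks$membrane_ring <- abs(rho - spec$radius_px) <= ring_extent
  }
  if (spec$pattern %in% c("septal", "ring_plus_septum")) {
    ca <- cos(spec$septum_angle); sa <- sin(spec$septum_angle)
    along <- dx * ca + dy * sa
    perp <- -dx * sa + dy * ca
    band <- exp(-0.5 * (perp / s)^2) * (abs(along) <= spec$radius_px)
    ideal <- ideal + spec$amplitude * band
    masks$septum <- abs(perp) <= ring_extent & abs(along) <= spec$radius_px
  }
  cyto <- rho <= spec$radius_px - ring_extent
  if (spec$cytoplasm_level > 0) {
    ideal <- ideal + spec$cytoplasm_level * spec$amplitude * cyto
  }
  masks$cytoplasm <- cyto
  if (spec$n_puncta > 0 && spec$pattern == "punctate") {
    pm <- vector("list", spec$n_puncta)
    for (k in seq_len(spec$n_puncta)) {
      d <- ((theta - spec$puncta_angles[k] + pi) %% (2 * pi)) - pi
      pm[[k]] <- (abs(d) <= 2 * spec$puncta_ang_sd) &
        (abs(rho - spec$radius_px) <= ring_extent)
    }
    masks$puncta <- pm
  }
  list(ideal = ideal, masks = masks)
}

# Shot noise, read noise, quantisation, clipping (imaging invariants).
apply_imaging_noise <- function(ideal, imaging) {
  with_seed_if(imaging$seed, {
    img <- ideal
    if (is.finite(imaging$photon_scale)) {
      img <- rpois(length(img), imaging$photon_scale * pmax(img, 0)) /
        imaging$photon_scale
      img <- matrix(img, nrow(ideal), ncol(ideal))
    }
    if (imaging$read_noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, imaging$read_noise_sd),
                          nrow(ideal), ncol(ideal))
    }
    pmin(pmax(round(img), 0), 2^imaging$bit_depth - 1)
  })
}

cell_margin <- function(spec, imaging) {
  extent <- if (spec$ring_profile == "tophat") spec$ring_sigma_px else
    2 * spec$ring_sigma_px
  spec$radius_px + extent + 3 * imaging$psf_sigma_px
}

#' Render a single synthetic cell image
#'
#' Evaluates the unblurred pattern at pixel centres, convolves with the
#' Gaussian PSF, then applies the imaging noise model. Ground-truth masks
#' (membrane ring, septum, cytoplasm, per-punctum) are computed on the
#' unblurred geometry.
#'
#' @param spec a [cell_spec()].
#' @param imaging an [imaging_spec()].
#' @param image_size integer image side in pixels (square frame); must
#'   contain the cell plus a 3-PSF-sigma margin.
#' @return A list of class `cocciq_cell_render` with elements `image`
#'   (noisy, quantised), `ideal` (PSF-blurred, pre-noise), `masks`, `spec`,
#'   `imaging`.
#' @export
render_cell <- function(spec, imaging, image_size) {
  stopifnot(inherits(spec, "cocciq_cell_spec"),
            inherits(imaging, "cocciq_imaging_spec"),
            is_scalar_num(image_size), image_size >= 4)
  m <- cell_margin(spec, imaging)
  if (spec$centre[1] - m < 0 || spec$centre[1] + m > image_size - 1 ||
      spec$centre[2] - m < 0 || spec$centre[2] + m > image_size - 1) {
    stopf("cell at (%g, %g) with radius %g px extends beyond the %dx%d frame",
          spec$centre[1], spec$centre[2], spec$radius_px,
          as.integer(image_size), as.integer(image_size))
  }
  pat <- eval_cell_pattern(spec, 0:(image_size - 1), 0:(image_size - 1))
  ideal <- gaussian_blur(pat$ideal, imaging$psf_sigma_px)
  structure(list(image = apply_imaging_noise(ideal, imaging),
                 ideal = ideal, unblurred = pat$ideal, masks = pat$masks,
                 spec = spec, imaging = imaging),
            class = "cocciq_cell_render")
}

#' Render a multi-cell field with ground-truth annotations
#'
#' Sums the ideal patterns of non-overlapping cells, blurs and applies noise
#' once for the whole field, and returns per-cell annotations carrying the
#' ground-truth centres and radii (usable as the oracle for centre
#' estimation).
#'
#' @param cells list of [cell_spec()] objects with pairwise non-overlapping
#'   footprints (centre distance greater than the sum of radii).
#' @param imaging an [imaging_spec()].
#' @param field_size integer field side in pixels.
#' @param groups optional character vector of group labels, one per cell.
#' @param division_states optional character vector
#'   (`non_dividing`/`dividing`/`unknown`), one per cell.
#' @return A list of class `cocciq_field` with `image`, `ideal` and
#'   `annotations` (a data.frame: cell_id, centre_x, centre_y, radius_px,
#'   group, division_state).
#' @export
render_field <- function(cells, imaging, field_size, groups = NULL,
                         division_states = NULL) {
  stopifnot(is.list(cells), inherits(imaging, "cocciq_imaging_spec"),
            is_scalar_num(field_size))
  n <- length(cells)
  groups <- groups %||% rep("unassigned", n)
  division_states <- division_states %||% rep("unknown", n)
  stopifnot(length(groups) == n, length(division_states) == n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((cells[[i]]$centre - cells[[j]]$centre)^2))
      if (d <= cells[[i]]$radius_px + cells[[j]]$radius_px) {
        stopf("cells %d and %d overlap (centre distance %.2f <= r1 + r2 = %.2f)",
              i, j, d, cells[[i]]$radius_px + cells[[j]]$radius_px)
      }
    }
  }
  ideal0 <- matrix(0, field_size, field_size)
  for (sp in cells) {
    stopifnot(inherits(sp, "cocciq_cell_spec"))
    m <- cell_margin(sp, imaging)
    if (sp$centre[1] - m < 0 || sp$centre[1] + m > field_size - 1 ||
        sp$centre[2] - m < 0 || sp$centre[2] + m > field_size - 1) {
      stopf("cell at (%g, %g) extends beyond the field", sp$centre[1],
            sp$centre[2])
    }
    ideal0 <- ideal0 + eval_cell_pattern(sp, 0:(field_size - 1),
                                         0:(field_size - 1))$ideal
  }
  ideal <- gaussian_blur(ideal0, imaging$psf_sigma_px)
  ann <- data.frame(
    cell_id = if (n > 0) sprintf("cell_%03d", seq_len(n)) else character(0),
    centre_x = vapply(cells, function(s) s$centre[1], numeric(1)),
    centre_y = vapply(cells, function(s) s$centre[2], numeric(1)),
    radius_px = vapply(cells, function(s) s$radius_px, numeric(1)),
    group = as.character(groups),
    division_state = as.character(division_states),
    stringsAsFactors = FALSE)
  structure(list(image = apply_imaging_noise(ideal, imaging), ideal = ideal,
                 annotations = ann, cells = cells, imaging = imaging),
            class = "cocciq_field")
}
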