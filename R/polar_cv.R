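# Heterogeneity statistic: polar transform, angular profile, CV factor,
# group comparison.

#' Polar transform of a cell image
#'
#' Resamples the image onto (angle, radius) coordinates about the cell
#' centre: row i, column j holds the bilinear interpolation of the image at
#' `centre + r_j * (cos(theta_i), sin(theta_i))` with
#' `theta_i = 2*pi*i/n_angle_bins` (i = 0..n-1) and
#' `r_j = j * max_radius_px / (n_radial_samples - 1)` (j = 0..m-1). The
#' membrane ring becomes a vertical band and angular variation becomes the
#' row direction.
#'
#' @param image numeric matrix `[y, x]`.
#' @param centre numeric `(x, y)` 0-based cell centre.
#' @param max_radius_px outermost sampled radius; the whole sampling disc
#'   must lie inside the image.
#' @param n_angle_bins number of angular rows (default 360).
#' @param n_radial_samples number of radial columns (default
#'   `max_radius_px + 1`, one sample per pixel of radius).
#' @return Matrix `n_angle_bins x n_radial_samples` with attributes
#'   `angles` (radians) and `radii` (pixels).
#' @export
polar_transform <- function(image, centre, max_radius_px,
                            n_angle_bins = 360, n_radial_samples = NULL) {
  stopifnot(is.matrix(image), length(centre) == 2L,
            is_scalar_num(max_radius_px), max_radius_px > 0,
            is_scalar_num(n_angle_bins), n_angle_bins >= 4)
  n_radial_samples <- n_radial_samples %||% (floor(max_radius_px) + 1)
  stopifnot(n_radial_samples >= 2)
  if (centre[1] - max_radius_px < 0 || centre[1] + max_radius_px > ncol(image) - 1 ||
      centre[2] - max_radius_px < 0 || centre[2] + max_radius_px > nrow(image) - 1) {
    stopf("sampling disc of radius %g at (%g, %g) exceeds image bounds",
          max_radius_px, centre[1], centre[2])
  }
  angles <- 2 * pi * (seq_len(n_angle_bins) - 1) / n_angle_bins
  radii <- (seq_len(n_radial_samples) - 1) * max_radius_px /
    (n_radial_samples - 1)
  xs <- centre[1] + outer(cos(angles), radii)
  ys <- centre[2] + outer(sin(angles), radii)
  P <- matrix(bilinear_sample(image, as.numeric(xs), as.numeric(ys)),
              n_angle_bins, n_radial_samples)
  attr(P, "angles") <- angles
  attr(P, "radii") <- radii
  P
}

#' Angular intensity profile from a polar image
#'
#' Averages the polar image over a radial band to give mean fluorescence per
#' angular bin. Cytoplasm removal excludes a central disc holding 20% of the
#' circle's area, i.e. sets `r_min_px = r_max_px * sqrt(0.2)`; it suppresses
#' the cytoplasmic contribution in non-deconvolved images.
#'
#' @param polar_image output of [polar_transform()].
#' @param r_min_px,r_max_px radial band in pixels (defaults: full range).
#' @param cytoplasm_removal logical; overrides `r_min_px` with
#'   `r_max_px * sqrt(0.2)`.
#' @return Object of class `cocciq_angular_profile`: list with `angles`,
#'   `intensities`, `n_radial_samples`, `cytoplasm_removed`.
#' @export
angular_profile <- function(polar_image, r_min_px = 0, r_max_px = NULL,
                            cytoplasm_removal = FALSE) {
  radii <- attr(polar_image, "radii")
  stopifnot(!is.null(radii))
  r_max_px <- r_max_px %||% max(radii)
  if (cytoplasm_removal) r_min_px <- r_max_px * sqrt(0.2)
  if (!(r_min_px >= 0 && r_min_px < r_max_px)) {
    stopf("need 0 <= r_min_px < r_max_px (got %g, %g)", r_min_px, r_max_px)
  }
  keep <- radii >= r_min_px & radii <= r_max_px
  if (!any(keep)) stopf("empty radial range [%g, %g]", r_min_px, r_max_px)
  structure(list(angles = attr(polar_image, "angles"),
                 intensities = rowMeans(polar_image[, keep, drop = FALSE]),
                 n_radial_samples = sum(keep),
                 cytoplasm_removed = isTRUE(cytoplasm_removal)),
            class = "cocciq_angular_profile")
}

#' The CV heterogeneity factor of an angular profile
#'
#' `CV = scale_factor * sigma / mu`, where sigma and mu are the standard
#' deviation and mean of the fluorescence-by-angle distribution. High values
#' indicate heterogeneous (punctate) membrane signal, low values a
#' homogeneous ring. The default scale factor of 100 makes the statistic a
#' percent coefficient of variation; the population (n-denominator) standard
#' deviation is used by default (with hundreds of angular bins the sample
#' version differs by under 0.2%).
#'
#' @param profile a [angular_profile()], or a bare numeric vector of
#'   per-angle intensities.
#' @param scale_factor multiplier applied to sigma/mu (default 100).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @param mu_floor smallest admissible mean intensity; dimmer profiles are
#'   rejected rather than returning unstable CVs.
#' @param cell_id optional identifier carried into the result.
#' @return Object of class `cocciq_cv_result`: list with `sigma`, `mu`,
#'   `cv`, `cytoplasm_removed`, `cell_id`.
#' @export
cv_factor <- function(profile, scale_factor = 100,
                      sd_type = c("population", "sample"),
                      mu_floor = 1e-9, cell_id = NA_character_) {
  sd_type <- match.arg(sd_type)
  cyto <- FALSE
  if (inherits(profile, "cocciq_angular_profile")) {
    cyto <- profile$cytoplasm_removed
    x <- profile$intensities
  } else {
    x <- as.numeric(profile)
  }
  if (!length(x)) stopf("empty profile")
  if (any(x < 0)) stopf("profile intensities must be non-negative")
  mu <- mean(x)
  if (mu <= mu_floor) {
    stopf("CV undefined: mean profile intensity %.3g at or below floor %.3g",
          mu, mu_floor)
  }
  n <- length(x)
  sigma <- if (sd_type == "population") {
    sqrt(sum((x - mu)^2) / n)
  } else {
    sd(x)
  }
  structure(list(sigma = sigma, mu = mu, cv = scale_factor * sigma / mu,
                 cytoplasm_removed = cyto, cell_id = cell_id),
            class = "cocciq_cv_result")
}

#' Significance stars for a p-value
#'
#' Conventional mapping: `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, else `ns`.
#' @param p p-value.
#' @return Character string.
#' @export
significance_stars <- function(p) {
  if (!is.finite(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

cv_values <- function(group) {
  if (is.numeric(group)) return(as.numeric(group))
  vapply(group, function(g) {
    if (inherits(g, "cocciq_cv_result")) g$cv else as.numeric(g)
  }, numeric(1))
}

#' Compare CV factors between two groups of cells
#'
#' Classic pooled-variance two-tailed unpaired Student's t-test between the
#' per-cell CV factors of two groups (conventionally 20 cells per group).
#'
#' @param group_a,group_b numeric CV vectors or lists of
#'   [cv_factor()] results; each of length >= 2.
#' @param label_a,label_b group labels for the report.
#' @return One-row data.frame: labels, n, means, sds, `t`, `df`, `p`,
#'   significance `stars`.
#' @export
cv_group_compare <- function(group_a, group_b, label_a = "A", label_b = "B") {
  a <- cv_values(group_a); b <- cv_values(group_b)
  if (length(a) < 2 || length(b) < 2) {
    stopf("each group needs >= 2 cells (got %d and %d)", length(a), length(b))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  data.frame(group_a = label_a, group_b = label_b,
             n_a = length(a), n_b = length(b),
             mean_a = mean(a), sd_a = sd(a),
             mean_b = mean(b), sd_b = sd(b),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, stars = significance_stars(tt$p.value),
             stringsAsFactors = FALSE)
}

#' Estimate the membrane-ring radius of a centred cell
#'
#' Scans candidate radii at 1 px steps, takes the radius of maximal mean
#' ring intensity (mean over angles at that radius), and refines it by
#' parabolic interpolation of the three surrounding samples.
#'
#' @param image numeric matrix containing a single cell near `centre`.
#' @param centre numeric `(x, y)` cell centre.
#' @param max_radius_px largest candidate radius; default reaches to 1 px
#'   short of the nearest image edge.
#' @return Radius estimate in pixels.
#' @export
measure_cell_radius <- function(image, centre, max_radius_px = NULL) {
  stopifnot(is.matrix(image), length(centre) == 2L)
  lim <- floor(min(centre[1], centre[2], ncol(image) - 1 - centre[1],
                   nrow(image) - 1 - centre[2]))
  max_radius_px <- max_radius_px %||% lim
  if (max_radius_px < 3) stopf("image too small around centre")
  P <- polar_transform(image, centre, max_radius_px,
                       n_angle_bins = 180,
                       n_radial_samples = max_radius_px + 1)
  v <- colMeans(P)
  j <- which.max(v)
  if (j == 1L || j == length(v) || max(v) <= 0 ||
      max(v) - min(v) < 1e-12 * max(abs(v), 1)) {
    stopf("no interior ring-intensity maximum: cannot estimate radius")
  }
  denom <- v[j - 1] - 2 * v[j] + v[j + 1]
  delta <- if (abs(denom) < 1e-12) 0 else 0.5 * (v[j - 1] - v[j + 1]) / denom
  radii <- attr(P, "radii")
  step <- radii[2] - radii[1]
  radii[j] + delta * step
}

#' CV factor of one annotated cell image
#'
#' Convenience wrapper: polar transform about the (optionally refined)
#' centre, angular profile over a radial band, CV factor.
#'
#' @param image numeric matrix containing the cell.
#' @param centre numeric `(x, y)` cell centre.
#' @param radius_px annotated cell radius.
#' @param n_angle_bins angular bins (default 360).
#' @param r_max_factor outer band edge as a multiple of `radius_px`
#'   (default 1.4, capped by the image bounds).
#' @param r_min_px inner band edge (default 0).
#' @param cytoplasm_removal logical, see [angular_profile()].
#' @param refine_centre logical; run [estimate_centre()] first.
#' @param scale_factor,cell_id passed to [cv_factor()].
#' @return A [cv_factor()] result.
#' @export
cv_for_cell <- function(image, centre, radius_px, n_angle_bins = 360,
                        r_max_factor = 1.4, r_min_px = 0,
                        cytoplasm_removal = FALSE, refine_centre = FALSE,
                        scale_factor = 100, cell_id = NA_character_) {
  if (refine_centre) centre <- estimate_centre(image, centre, radius_px)
  lim <- min(centre[1], centre[2], ncol(image) - 1 - centre[1],
             nrow(image) - 1 - centre[2])
  r_max <- min(r_max_factor * radius_px, lim)
  P <- polar_transform(image, centre, r_max, n_angle_bins = n_angle_bins)
  prof <- angular_profile(P, r_min_px = r_min_px,
                          cytoplasm_removal = cytoplasm_removal)
  cv_factor(prof, scale_factor = scale_factor, cell_id = cell_id)
}
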