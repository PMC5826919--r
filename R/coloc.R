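# Manders colocalisation workflow: rolling-ball background subtraction,
# isodata auto-threshold, intensity-weighted M1.

# Isodata (iterative intermeans) threshold on values discretised to n_bins
# bin midpoints: t <- (mean below t + mean above t) / 2 until fixed.
isodata_threshold <- function(values, n_bins = 256) {
  values <- as.numeric(values)
  lo <- min(values); hi <- max(values)
  if (!is.finite(lo) || !is.finite(hi) || lo == hi) {
    stopf("isodata threshold undefined: image is constant")
  }
  width <- (hi - lo) / n_bins
  mid <- lo + (findInterval(values, lo + width * seq_len(n_bins - 1)) + 0.5) *
    width
  t_cur <- mean(mid)
  for (iter in 1:500) {
    below <- mid[mid <= t_cur]
    above <- mid[mid > t_cur]
    if (!length(above) || !length(below)) break
    t_new <- (mean(below) + mean(above)) / 2
    if (abs(t_new - t_cur) < width * 1e-9) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur
}

#' Automatic isodata threshold of an image
#'
#' Iterative-intermeans (isodata) threshold on a 256-bin histogram; the
#' selection mask is the set of pixels strictly above the threshold.
#'
#' @param image numeric matrix.
#' @return List with `threshold`, logical `mask`, and `n_selected`.
#' @export
auto_threshold <- function(image) {
  stopifnot(is.matrix(image))
  th <- isodata_threshold(image)
  mask <- image > th
  list(threshold = th, mask = mask, n_selected = sum(mask))
}

ball_element <- function(radius_px) {
  r <- floor(radius_px)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  d2 <- off$dx^2 + off$dy^2
  keep <- d2 <= radius_px^2
  list(dx = as.integer(off$dx[keep]), dy = as.integer(off$dy[keep]),
       h = sqrt(radius_px^2 - d2[keep]))
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening of
#' the image with a ball (spherical-cap) structuring element of the given
#' radius — the surface traced by a ball rolled under the intensity
#' landscape — and subtracts it, flooring at zero. Features narrower than the
#' ball (cells, foci) pass through unchanged; broad gradients are removed.
#'
#' @param image numeric matrix of intensities.
#' @param radius_px ball radius in pixels (>= 1, and no larger than the
#'   smaller image dimension); 50 is the conventional choice for bacterial
#'   fields.
#' @param height_scale multiplies the ball height in intensity units per
#'   pixel; 1 uses a sphere.
#' @return Background-subtracted image (non-negative matrix).
#' @export
rolling_ball_subtract <- function(image, radius_px = 50, height_scale = 1) {
  stopifnot(is.matrix(image), is_scalar_num(radius_px),
            is_scalar_num(height_scale), height_scale > 0)
  if (radius_px < 1) stopf("rolling-ball radius must be >= 1 px")
  if (radius_px > min(dim(image))) {
    stopf("rolling-ball radius %g exceeds image size %dx%d", radius_px,
          nrow(image), ncol(image))
  }
  se <- ball_element(radius_px)
  h <- se$h * height_scale
  eroded <- cpp_gray_morph(image, se$dx, se$dy, h, FALSE)
  background <- cpp_gray_morph(eroded, se$dx, se$dy, h, TRUE)
  pmax(image - background, 0)
}

#' Manders M1 overlap coefficient
#'
#' Intensity-weighted fraction of the green channel's signal, within the
#' selection, that lies in pixels where the red channel is above its own
#' automatic threshold:
#' `M1 = sum(green[sel & red > thr]) / sum(green[sel])`.
#'
#' @param green,red co-registered intensity matrices of equal shape
#'   (background-subtracted).
#' @param selection logical mask of analysed pixels; `NULL` derives it from
#'   the green channel's isodata threshold.
#' @param red_threshold threshold applied to the red channel; `NULL` uses
#'   red's isodata threshold.
#' @return Object of class `cocciq_coloc_result`: list with `m1`,
#'   `threshold_value` (red), `green_threshold` (or NA), `n_selected_pixels`.
#' @export
manders_m1 <- function(green, red, selection = NULL, red_threshold = NULL) {
  stopifnot(is.matrix(green), is.matrix(red),
            all(dim(green) == dim(red)))
  green_threshold <- NA_real_
  if (is.null(selection)) {
    at <- auto_threshold(green)
    selection <- at$mask
    green_threshold <- at$threshold
  }
  stopifnot(is.logical(selection), all(dim(selection) == dim(green)))
  if (!any(selection)) stopf("selection mask is empty")
  if (is.null(red_threshold)) red_threshold <- isodata_threshold(red)
  denom <- sum(green[selection])
  if (denom <= 0) stopf("M1 undefined: zero green signal in selection")
  m1 <- sum(green[selection & (red > red_threshold)]) / denom
  structure(list(m1 = m1, threshold_value = red_threshold,
                 green_threshold = green_threshold,
                 n_selected_pixels = sum(selection)),
            class = "cocciq_coloc_result")
}

#' Colocalisation pipeline over replicate fields
#'
#' For each field pair: rolling-ball background subtraction of both channels,
#' selection from the green (reference) channel's isodata threshold, Manders
#' M1 against the red channel's threshold; then the mean and sd of M1 across
#' fields (conventionally three fields per strain).
#'
#' @param field_pairs list of `list(green =, red =)` intensity matrices (a
#'   `cocciq_coloc_field` from [render_coloc_pair()] is accepted directly).
#' @param background_radius_px rolling-ball radius; `0` skips background
#'   subtraction.
#' @param reference which channel defines the selection: `"green"` (default,
#'   FITC-style) or `"red"`.
#' @return List with `per_field` data.frame (field, m1, red_threshold,
#'   n_selected) and `summary` (mean_m1, sd_m1, n_fields).
#' @export
coloc_pipeline <- function(field_pairs, background_radius_px = 50,
                           reference = c("green", "red")) {
  reference <- match.arg(reference)
  if (inherits(field_pairs, "cocciq_coloc_field")) {
    field_pairs <- list(field_pairs)
  }
  stopifnot(is.list(field_pairs), length(field_pairs) >= 1)
  rows <- vector("list", length(field_pairs))
  for (i in seq_along(field_pairs)) {
    fp <- field_pairs[[i]]
    g <- fp$green; r <- fp$red
    if (background_radius_px > 0) {
      g <- rolling_ball_subtract(g, background_radius_px)
      r <- rolling_ball_subtract(r, background_radius_px)
    }
    if (reference == "red") { tmp <- g; g <- r; r <- tmp }
    res <- manders_m1(g, r)
    rows[[i]] <- data.frame(field = i, m1 = res$m1,
                            red_threshold = res$threshold_value,
                            n_selected = res$n_selected_pixels)
  }
  per_field <- do.call(rbind, rows)
  list(per_field = per_field,
       summary = list(mean_m1 = mean(per_field$m1),
                      sd_m1 = if (nrow(per_field) > 1) sd(per_field$m1)
                              else NA_real_,
                      n_fields = nrow(per_field)))
}
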