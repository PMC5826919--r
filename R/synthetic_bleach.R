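# Synthetic donor-photobleaching acquisitions: mono-exponential decay of ROI
# intensity over a continuous acquisition (default 720 frames, i.e. 6 min at
# a 0.5 s frame interval).

#' Specify a photobleaching acquisition
#'
#' @param tau_frames decay time constant in frames (> 0).
#' @param amplitude initial bleachable intensity (> 0, counts).
#' @param offset non-bleaching baseline (>= 0, counts).
#' @param n_frames number of frames (>= 10; default 720 = 6 min at 0.5 s).
#' @param noise_sd additive Gaussian noise sd on the ROI mean (>= 0).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return Object of class `cocciq_bleach_spec`.
#' @export
bleach_spec <- function(tau_frames, amplitude, offset = 0, n_frames = 720,
                        noise_sd = 0, seed = NULL) {
  stopifnot(is_scalar_num(tau_frames), tau_frames > 0,
            is_scalar_num(amplitude), amplitude > 0,
            is_scalar_num(offset), offset >= 0,
            is_scalar_num(n_frames),
            is_scalar_num(noise_sd), noise_sd >= 0)
  if (n_frames < 10) stopf("n_frames must be >= 10")
  structure(list(tau_frames = tau_frames, amplitude = amplitude,
                 offset = offset, n_frames = as.integer(n_frames),
                 noise_sd = noise_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cocciq_bleach_spec")
}

#' Construct a bleach trace
#'
#' @param intensity numeric vector (length >= 10) of per-frame ROI mean
#'   fluorescence, non-negative.
#' @param roi_label `"whole_cell"`, `"septum"` or `"periphery"`.
#' @param division_state `"non_dividing"` or `"dividing"`.
#' @param condition `"donor_only"` or `"donor_plus_acceptor"`.
#' @param cell_id optional identifier.
#' @param truth optional list of ground-truth generator parameters.
#' @return Object of class `cocciq_bleach_trace`: data.frame with columns
#'   `frame_index` (0-based) and `intensity`, labels as attributes.
#' @export
bleach_trace <- function(intensity,
                         roi_label = c("whole_cell", "septum", "periphery"),
                         division_state = c("non_dividing", "dividing"),
                         condition = c("donor_only", "donor_plus_acceptor"),
                         cell_id = NA_character_, truth = NULL) {
  roi_label <- match.arg(roi_label)
  division_state <- match.arg(division_state)
  condition <- match.arg(condition)
  intensity <- as.numeric(intensity)
  if (length(intensity) < 10) stopf("a bleach trace needs >= 10 frames")
  if (any(intensity < 0)) stopf("trace intensities must be >= 0")
  out <- data.frame(frame_index = seq_along(intensity) - 1L,
                    intensity = intensity)
  structure(out, roi_label = roi_label, division_state = division_state,
            condition = condition, cell_id = cell_id, truth = truth,
            class = c("cocciq_bleach_trace", "data.frame"))
}

#' Simulate a photobleaching trace
#'
#' `trace[t] = amplitude * exp(-t / tau_frames) + offset + noise`, clamped at
#' zero (the quantisation floor of a camera). The noise-free trace is
#' strictly decreasing towards the offset. Ground truth is stored in the
#' `truth` attribute for recovery tests.
#'
#' @param spec a [bleach_spec()].
#' @param roi_label,division_state,condition,cell_id labels, see
#'   [bleach_trace()].
#' @return A [bleach_trace()].
#' @export
simulate_bleach_trace <- function(spec, roi_label = "whole_cell",
                                  division_state = "non_dividing",
                                  condition = "donor_only",
                                  cell_id = NA_character_) {
  stopifnot(inherits(spec, "cocciq_bleach_spec"))
  t <- 0:(spec$n_frames - 1)
  ideal <- spec$amplitude * exp(-t / spec$tau_frames) + spec$offset
  intensity <- with_seed_if(spec$seed, {
    if (spec$noise_sd > 0) ideal + rnorm(length(t), 0, spec$noise_sd)
    else ideal
  })
  bleach_trace(pmax(intensity, 0), roi_label = roi_label,
               division_state = division_state, condition = condition,
               cell_id = cell_id,
               truth = list(tau_frames = spec$tau_frames,
                            amplitude = spec$amplitude,
                            offset = spec$offset))
}

#' Simulate a uniformly bleaching image stack
#'
#' Every pixel follows the spec's decay with independent per-pixel Gaussian
#' noise of sd `noise_sd`; the ROI mean over n pixels therefore tracks the
#' ideal decay with sd `noise_sd / sqrt(n)`. Used to exercise
#' [extract_trace()] against ground truth.
#'
#' @param spec a [bleach_spec()].
#' @param ny,nx frame dimensions in pixels.
#' @return 3-D array `[frame, y, x]` with the ideal trace in attribute
#'   `"ideal"`.
#' @export
simulate_bleach_stack <- function(spec, ny = 16, nx = 16) {
  stopifnot(inherits(spec, "cocciq_bleach_spec"))
  t <- 0:(spec$n_frames - 1)
  ideal <- spec$amplitude * exp(-t / spec$tau_frames) + spec$offset
  arr <- with_seed_if(spec$seed, {
    noise <- if (spec$noise_sd > 0) {
      rnorm(spec$n_frames * ny * nx, 0, spec$noise_sd)
    } else 0
    array(rep(ideal, times = ny * nx) + noise, c(spec$n_frames, ny, nx))
  })
  arr <- pmax(arr, 0)
  attr(arr, "ideal") <- ideal
  arr
}
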