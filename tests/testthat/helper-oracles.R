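# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Per-pixel angle binning: assign each pixel in the annulus to an angle bin
# by arctangent and average.
oracle_angular_profile <- function(img, centre, r_min, r_max, n_bins) {
  acc <- numeric(n_bins); cnt <- numeric(n_bins)
  for (row in seq_len(nrow(img))) {
    for (col in seq_len(ncol(img))) {
      dx <- (col - 1) - centre[1]; dy <- (row - 1) - centre[2]
      rho <- sqrt(dx^2 + dy^2)
      if (rho >= r_min && rho <= r_max) {
        b <- floor((atan2(dy, dx) %% (2 * pi)) / (2 * pi / n_bins)) + 1
        acc[b] <- acc[b] + img[row, col]
        cnt[b] <- cnt[b] + 1
      }
    }
  }
  acc / cnt
}

# Double-loop grayscale opening with a ball element, then subtraction.
oracle_rolling_ball <- function(img, radius) {
  r <- floor(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  hh <- sqrt(radius^2 - off$dx^2 - off$dy^2)
  n <- nrow(img); m <- ncol(img)
  pass <- function(src, dilate) {
    out <- matrix(NA_real_, n, m)
    for (cc in seq_len(m)) for (rr in seq_len(n)) {
      v <- if (dilate) -Inf else Inf
      for (k in seq_len(nrow(off))) {
        c2 <- cc + off$dx[k]; r2 <- rr + off$dy[k]
        if (c2 >= 1 && c2 <= m && r2 >= 1 && r2 <= n) {
          cand <- if (dilate) src[r2, c2] + hh[k] else src[r2, c2] - hh[k]
          v <- if (dilate) max(v, cand) else min(v, cand)
        }
      }
      out[rr, cc] <- v
    }
    out
  }
  pmax(img - pass(pass(img, FALSE), TRUE), 0)
}

# Isodata fixed point by direct iteration on a 256-bin histogram.
oracle_isodata <- function(v, n_bins = 256) {
  lo <- min(v); hi <- max(v); w <- (hi - lo) / n_bins
  idx <- pmin(floor((v - lo) / w), n_bins - 1)
  cnt <- tabulate(idx + 1, n_bins)
  mid <- lo + ((0:(n_bins - 1)) + 0.5) * w
  t_cur <- sum(cnt * mid) / sum(cnt)
  repeat {
    b <- mid <= t_cur
    if (!any(cnt[b] > 0) || !any(cnt[!b] > 0)) break
    t_new <- (sum(cnt[b] * mid[b]) / sum(cnt[b]) +
                sum(cnt[!b] * mid[!b]) / sum(cnt[!b])) / 2
    if (abs(t_new - t_cur) < 1e-12) break
    t_cur <- t_new
  }
  t_cur
}

# Per-pixel double loop Manders M1.
oracle_m1 <- function(green, red, selection, red_threshold) {
  num <- 0; den <- 0
  for (row in seq_len(nrow(green))) for (col in seq_len(ncol(green))) {
    if (selection[row, col]) {
      den <- den + green[row, col]
      if (red[row, col] > red_threshold) num <- num + green[row, col]
    }
  }
  num / den
}

# Fixture builders ----------------------------------------------------------

noise_free_imaging <- function(psf = 1.3) {
  imaging_spec(psf_sigma_px = psf, photon_scale = Inf, read_noise_sd = 0)
}

# A punctate cell render with seeded random punctum angles; returns the
# render plus the spec.
seeded_punctate_cell <- function(seed, radius_px = 8, contrast = 3,
                                 n_puncta = 6, imaging = NULL,
                                 puncta_ang_sd = 0.15, uniform_mix = 0,
                                 size = NULL) {
  angles <- withr::with_seed(seed, sort(runif(n_puncta, 0, 2 * pi - 1e-9)))
  size <- size %||% (2 * ceiling(1.5 * radius_px) + 21)
  ctr <- rep((size - 1) / 2, 2)
  spec <- cell_spec(ctr, radius_px, "punctate", n_puncta = n_puncta,
                    puncta_contrast = contrast, puncta_angles = angles,
                    puncta_ang_sd = puncta_ang_sd, uniform_mix = uniform_mix)
  imaging <- imaging %||% imaging_spec(seed = seed + 1)
  list(render = render_cell(spec, imaging, size), spec = spec, centre = ctr,
       size = size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
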