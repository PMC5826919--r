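# Internal helpers shared across modules.
#
# Image convention (stated once, used everywhere): images are numeric matrices
# indexed [row, col] = [y + 1, x + 1]; x = column, y = row; the origin is the
# centre of the top-left pixel, coordinates are 0-based and angles are
# measured counter-clockwise from the +x axis, in radians.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a reproducible sub-stream seed for a named pipeline stage
#'
#' All randomness in the pipeline flows from one top-level seed; each stage
#' (generation, noise, bootstrap, ...) draws from its own sub-stream so stages
#' are reproducible independently of one another.
#'
#' @param seed integer top-level seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
seed_for_stage <- function(seed, stage) {
  stopifnot(is_scalar_num(seed), is.character(stage), length(stage) == 1L)
  h <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL leaves the RNG alone.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Bilinear interpolation of image `img` at 0-based continuous (x, y).
# Callers guarantee the points are inside the image.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  if (any(x < 0 | x > nc - 1 | y < 0 | y > nr - 1)) {
    stopf("sample point outside image bounds")
  }
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i <- y0 + 1; j <- x0 + 1
  v00 <- img[cbind(i, j)];     v01 <- img[cbind(i, j + 1)]
  v10 <- img[cbind(i + 1, j)]; v11 <- img[cbind(i + 1, j + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Separable Gaussian blur with a kernel truncated at 4 sigma and zero padding.
# The kernel is symmetric and identical along both axes, so blurring commutes
# exactly with 90-degree rotations of the image; it sums to 1, so total
# intensity is conserved up to boundary truncation.
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), is_scalar_num(sigma), sigma >= 0)
  if (sigma == 0) return(img)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m) {
    # convolve each column with k, zero padding
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (d in -r:r) {
      w <- k[d + r + 1]
      src <- (1 + max(0, -d)):(nr - max(0, d))
      dst <- src + d
      out[dst, ] <- out[dst, ] + w * m[src, ]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

# Wrap angles into [0, 2*pi).
wrap_angle <- function(a) a %% (2 * pi)
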