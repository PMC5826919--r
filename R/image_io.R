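#' Read a TIFF image or stack
#'
#' Reads single- or multi-page 8/12/16-bit TIFF losslessly as integer
#' intensities. Single-page files become a numeric matrix `[y, x]`;
#' multi-page files become a 3-D array `[frame, y, x]`. The sample bit depth
#' is recorded in the `"bit_depth"` attribute.
#'
#' @param path path to a TIFF file.
#' @return Matrix or 3-D array of intensities (counts).
#' @export
read_image <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                   info = TRUE),
                    error = function(e) stopf("cannot read TIFF '%s': %s",
                                              path, conditionMessage(e)))
  bits <- attr(pages[[1]], "bits.per.sample") %||% NA_integer_
  out <- if (length(pages) == 1L) {
    pages[[1]]
  } else {
    arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    arr
  }
  attr(out, "bit_depth") <- as.integer(bits)
  out
}

#' Write an image or stack to TIFF
#'
#' Integer intensities are stored losslessly. 12-bit data is carried in a
#' 16-bit container (values 0..4095), matching common camera files.
#'
#' @param image numeric matrix `[y, x]`, or 3-D array `[frame, y, x]`, of
#'   non-negative integer counts.
#' @param path output path.
#' @param bit_depth nominal bit depth (8, 12 or 16); values must fit.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 16) {
  if (!bit_depth %in% c(8, 12, 16)) stopf("bit_depth must be 8, 12 or 16")
  container <- if (bit_depth == 8) 8L else 16L
  maxval <- 2^container - 1
  to_page <- function(m) {
    if (any(m < 0) || any(m > 2^bit_depth - 1)) {
      stopf("image values outside [0, %d] for bit depth %d",
            2^bit_depth - 1, bit_depth)
    }
    round(m) / maxval
  }
  pages <- if (length(dim(image)) == 3L) {
    lapply(seq_len(dim(image)[1]), function(i) to_page(image[i, , ]))
  } else {
    to_page(image)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = container,
                  compression = "none")
  invisible(path)
}

annotation_columns <- c("cell_id", "centre_x", "centre_y", "radius_px",
                        "group", "division_state")

#' Write per-cell annotations as a delimited table
#'
#' @param annotations data.frame with columns cell_id, centre_x, centre_y,
#'   radius_px, group, division_state (as produced by [render_field()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(is.data.frame(annotations),
            all(annotation_columns %in% names(annotations)))
  write.csv(annotations[annotation_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate per-cell annotations
#'
#' Reads the delimited annotation table written by [write_annotations()] (or
#' user-authored with the same columns) and validates each record; when an
#' image is supplied, centres must lie inside its bounds. Invalid rows are
#' reported with their row numbers and cell ids.
#'
#' @param path CSV path.
#' @param image optional image matrix the annotations refer to.
#' @return data.frame of validated cell records (possibly empty).
#' @export
read_annotations <- function(path, image = NULL) {
  ann <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stopf("cannot read annotations '%s': %s",
                                            path, conditionMessage(e)))
  if (nrow(ann) == 0L) {
    for (col in annotation_columns) if (is.null(ann[[col]])) ann[[col]] <- character(0)
    return(ann[annotation_columns])
  }
  missing_cols <- setdiff(annotation_columns, names(ann))
  if (length(missing_cols)) {
    stopf("annotation table '%s' lacks columns: %s", path,
          paste(missing_cols, collapse = ", "))
  }
  bad <- character(0)
  for (i in seq_len(nrow(ann))) {
    r <- ann[i, ]
    ok <- is.finite(r$radius_px) && r$radius_px > 0 &&
      is.finite(r$centre_x) && is.finite(r$centre_y)
    if (ok && !is.null(image)) {
      ok <- r$centre_x >= 0 && r$centre_x <= ncol(image) - 1 &&
        r$centre_y >= 0 && r$centre_y <= nrow(image) - 1
    }
    if (!ok) bad <- c(bad, sprintf("row %d (cell '%s')", i, r$cell_id))
  }
  if (length(bad)) {
    stopf("invalid annotation records: %s", paste(bad, collapse = "; "))
  }
  ann
}

#' Refine an approximate cell centre
#'
#' Within a window of half-width `1.5 * radius_px` around the approximate
#' centre, thresholds the pixels with the isodata rule and returns the
#' intensity-weighted centroid of the above-threshold pixels. The polar
#' transform assumes a well-centred cell, so annotations are typically passed
#' through this refinement first.
#'
#' @param image numeric matrix `[y, x]`.
#' @param approximate_centre numeric `(x, y)`, within `radius_px` of the true
#'   centre.
#' @param radius_px approximate cell radius in pixels.
#' @return Numeric `(x, y)` refined centre, 0-based pixel coordinates.
#' @export
estimate_centre <- function(image, approximate_centre, radius_px) {
  stopifnot(is.matrix(image), length(approximate_centre) == 2L,
            is_scalar_num(radius_px), radius_px > 0)
  w <- 1.5 * radius_px
  x0 <- max(0, round(approximate_centre[1] - w))
  x1 <- min(ncol(image) - 1, round(approximate_centre[1] + w))
  y0 <- max(0, round(approximate_centre[2] - w))
  y1 <- min(nrow(image) - 1, round(approximate_centre[2] + w))
  if (x1 <= x0 || y1 <= y0) stopf("centring window outside image")
  win <- image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  if (max(win) == min(win)) {
    stopf("centring failed: window is constant, no pixels above threshold")
  }
  th <- isodata_threshold(as.numeric(win))
  sel <- win > th
  if (!any(sel)) stopf("centring failed: no pixels above isodata threshold")
  ys <- matrix(rep(y0:y1, times = ncol(win)), nrow = nrow(win))
  xs <- matrix(rep(x0:x1, each = nrow(win)), nrow = nrow(win))
  wgt <- win[sel]
  c(sum(xs[sel] * wgt) / sum(wgt), sum(ys[sel] * wgt) / sum(wgt))
}
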