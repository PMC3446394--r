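#' Grayscale image with physical pixel spacing
#'
#' The raw mammogram surrogate: a 2-D grid of 8-bit gray values (0-255)
#' together with an isotropic pixel spacing in cm/pixel. Pixel spacing is
#' what ties the multiscale texture rule (0.5 cm and 1.0 cm blocks) to the
#' pixel grid.
#'
#' @param values integer matrix with entries in 0..255 (rows x cols)
#' @param spacing pixel spacing in cm/pixel, > 0
#' @return an object of class `gray_image` with fields `values` and `spacing`
#' @export
gray_image <- function(values, spacing = 0.02) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (anyNA(values)) stop("gray values must not contain NA")
  v <- round(values)
  if (min(v) < 0 || max(v) > 255) stop("gray values must lie in [0, 255]")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number (cm/pixel)")
  storage.mode(v) <- "integer"
  structure(list(values = v, spacing = as.numeric(spacing)),
            class = "gray_image")
}

#' Binary breast mask aligned to a grayscale image
#'
#' Defines the region of interest (ROI) within which all texture features
#' are computed. `provenance` records whether the mask came out of the
#' automatic four-step delineation or was supplied externally (the analogue
#' of a manually corrected segmentation).
#'
#' @param values logical (or 0/1) matrix, same shape as the image
#' @param provenance `"automatic"` or `"corrected"`
#' @export
breast_mask <- function(values, provenance = c("automatic", "corrected")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  v <- values != 0
  if (anyNA(v)) stop("mask must not contain NA")
  if (!any(v)) stop("mask has no foreground pixels")
  structure(list(values = v, provenance = provenance), class = "breast_mask")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, spacing %.4g cm/px, range [%d, %d]>\n",
              nrow(x$values), ncol(x$values), x$spacing,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.breast_mask <- function(x, ...) {
  cat(sprintf("<breast_mask %d x %d, %d fg px (%.1f%%), %s>\n",
              nrow(x$values), ncol(x$values), sum(x$values),
              100 * mean(x$values), x$provenance))
  invisible(x)
}

#' Read / write 8-bit grayscale PNG images
#'
#' Images are stored as plain 8-bit grayscale PNG; masks as 0/255 PNG.
#'
#' @param path file path
#' @param spacing pixel spacing (cm/pixel) to attach on read
#' @rdname png-io
#' @export
read_gray_png <- function(path, spacing = 0.02) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  gray_image(round(v * 255), spacing = spacing)
}

#' @param image a `gray_image`
#' @rdname png-io
#' @export
write_gray_png <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  png::writePNG(image$values / 255, target = path)
  invisible(path)
}

#' @param mask a `breast_mask`
#' @rdname png-io
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "breast_mask"))
  png::writePNG(mask$values * 1, target = path)
  invisible(path)
}

#' @param provenance provenance tag to attach on read
#' @rdname png-io
#' @export
read_mask_png <- function(path, provenance = "corrected") {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  breast_mask(v > 0.5, provenance = provenance)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; 1 for identical masks.
#'
#' @param a,b `breast_mask` objects or logical matrices
#' @export
dice <- function(a, b) {
  av <- if (inherits(a, "breast_mask")) a$values else a != 0
  bv <- if (inherits(b, "breast_mask")) b$values else b != 0
  stopifnot(identical(dim(av), dim(bv)))
  2 * sum(av & bv) / (sum(av) + sum(bv))
}
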