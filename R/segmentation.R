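#' Remove white border stripes from a scanned mammogram
#'
#' Digitized films often carry saturated white stripes along the scan
#' borders. Any complete row or column lying within `margin_frac` of an
#' image edge whose fraction of near-white pixels (gray >= 250) exceeds
#' `bright_frac` is set to 0. Interior pixels are never touched; an image
#' with no near-white pixel is returned unchanged. Detection is performed
#' on the input image, and all detected rows/columns are zeroed jointly.
#'
#' @param image a [gray_image()]
#' @param margin_frac fraction of each dimension counted as border margin
#'   (0 < margin_frac <= 0.1)
#' @param bright_frac minimum fraction of near-white pixels for a row/column
#'   to count as a stripe
#' @return a `gray_image` with stripe rows/columns zeroed
#' @export
remove_border_stripes <- function(image, margin_frac = 0.05, bright_frac = 0.8) {
  stopifnot(inherits(image, "gray_image"))
  if (!(margin_frac > 0 && margin_frac <= 0.1))
    stop("`margin_frac` must be in (0, 0.1]")
  v <- image$values
  nr <- nrow(v); nc <- ncol(v)
  mr <- floor(margin_frac * nr); mc <- floor(margin_frac * nc)
  bright <- v >= 250L
  row_frac <- rowMeans(bright)
  col_frac <- colMeans(bright)
  rows <- unique(c(seq_len(mr), nr - seq_len(mr) + 1L))
  cols <- unique(c(seq_len(mc), nc - seq_len(mc) + 1L))
  bad_rows <- rows[row_frac[rows] > bright_frac]
  bad_cols <- cols[col_frac[cols] > bright_frac]
  if (length(bad_rows)) v[bad_rows, ] <- 0L
  if (length(bad_cols)) v[, bad_cols] <- 0L
  gray_image(v, image$spacing)
}

#' Otsu threshold of an 8-bit image
#'
#' Chooses the gray level `t` in 0..255 that minimizes the within-class
#' intensity variance of the two classes `{<= t}` and `{> t}` (equivalently
#' maximizes the between-class variance). Foreground is defined as pixels
#' strictly above the threshold. Ties are broken toward the smallest `t`.
#'
#' @param image a [gray_image()] with at least two distinct gray values
#' @return a list with `threshold` (integer) and `binary` (logical matrix,
#'   `TRUE` = foreground)
#' @export
otsu_threshold <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  v <- image$values
  counts <- tabulate(as.vector(v) + 1L, nbins = 256L)
  if (sum(counts > 0) < 2L) stop("degenerate histogram: image is constant")
  n <- sum(counts)
  p <- counts / n
  levels <- 0:255
  w0 <- cumsum(p)                       # P(gray <= t), t = 0..255
  m0 <- cumsum(p * levels)              # partial means
  mT <- m0[256]
  # within-class variance for t = 0..254 (both classes must be nonempty)
  tt <- 1:255                           # index of t in w0 (t = tt - 1)
  sigma_tot <- sum(p * (levels - mT)^2)
  w1 <- 1 - w0[tt]
  valid <- w0[tt] > 0 & w1 > 0
  mu0 <- m0[tt] / w0[tt]
  mu1 <- (mT - m0[tt]) / w1
  between <- w0[tt] * w1 * (mu0 - mu1)^2
  within <- sigma_tot - between
  within[!valid] <- Inf
  t <- which.min(within) - 1L           # smallest t on ties
  list(threshold = t, binary = v > t,
       within_class_variance = within[t + 1L])
}

# exact discrete disk structuring element: offsets with i^2 + j^2 <= r^2
disk_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  outer(-r:r, -r:r, function(i, j) as.numeric(i * i + j * j <= r * r))
}

#' Morphological opening with a discrete disk
#'
#' Erosion followed by dilation with the disk `{(i,j): i^2 + j^2 <= r^2}`
#' (pixels beyond the image border count as background). Opening can only
#' remove foreground: the output is asserted to be a subset of the input
#' on every call.
#'
#' @param mask logical/0-1 matrix
#' @param radius_px disk radius in pixels (>= 1)
#' @return logical matrix
#' @export
open_binary <- function(mask, radius_px = 5L) {
  stopifnot(radius_px >= 1)
  m <- mask != 0
  r <- as.integer(radius_px)
  offs <- which(disk_kernel(r) > 0, arr.ind = TRUE) - (r + 1L)
  storage.mode(offs) <- "integer"
  out <- morph_cpp(morph_cpp(m * 1L, offs, 0L), offs, 1L) != 0
  if (any(out & !m))
    stop("internal error: opening added foreground pixels")
  out
}

#' Keep only the largest connected component of a binary mask
#'
#' Component areas are compared in pixels; ties are broken toward the
#' component whose first pixel comes earliest in column-major scan order.
#'
#' @param mask logical/0-1 matrix with at least one foreground pixel
#' @param connectivity 4 or 8 (default 8)
#' @return logical matrix containing only the largest component
#' @export
largest_component <- function(mask, connectivity = 8L) {
  m <- (mask != 0) * 1L
  if (!any(m == 1L)) stop("empty mask: no foreground pixels")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- cc_label_cpp(m, as.integer(connectivity))
  n <- attr(lab, "n_components")
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which.max(areas)              # first max = earliest scan order
  lab == keep
}

#' Four-step breast delineation
#'
#' Composes the four segmentation steps in order: (1) border-stripe
#' removal, (2) Otsu thresholding, (3) morphological opening with a disk,
#' (4) retention of the largest connected component (assumed to be the
#' breast; film labels and residual artifacts are discarded). The result
#' carries provenance `"automatic"`. A warning is issued when the final
#' mask covers less than 1% of the image.
#'
#' @param image a [gray_image()]
#' @param margin_frac,bright_frac stripe-removal parameters
#'   (see [remove_border_stripes()])
#' @param radius_px opening disk radius in pixels (default 5, i.e. 1 mm at
#'   0.02 cm/pixel)
#' @param connectivity component connectivity, 4 or 8
#' @return a [breast_mask()] with provenance `"automatic"`
#' @export
delineate_breast <- function(image, margin_frac = 0.05, bright_frac = 0.8,
                             radius_px = 5L, connectivity = 8L) {
  stopifnot(inherits(image, "gray_image"))
  destriped <- remove_border_stripes(image, margin_frac, bright_frac)
  th <- otsu_threshold(destriped)
  opened <- open_binary(th$binary, radius_px)
  if (!any(opened))
    stop("opening removed all foreground; no breast candidate remains")
  m <- largest_component(opened, connectivity)
  if (sum(m) < 0.01 * length(m))
    warning("delineated breast covers < 1% of the image")
  breast_mask(m, provenance = "automatic")
}
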