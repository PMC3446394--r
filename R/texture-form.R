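# Form-based features of the binary breast mask: 5 shape scalars,
# 6 normalized-radial-length (NRL) features, 3 Fourier-descriptor band
# energies, and 72 binary-mask moments (16 NCM + 7 Hu + 49 Zernike computed
# on the mask as a 0/1 intensity image). Form features describe only the
# shape of the ROI and are computed once per subject, at full resolution.

#' Ordered outer boundary of a mask
#'
#' Traces the closed outer boundary of the (single-component) mask and
#' returns the ordered boundary points together with the mask's pixel
#' centroid.
#'
#' @param mask a [breast_mask()] or logical matrix
#' @return a `contour` object: list with `points` (K x 2 matrix of
#'   (row, col)) and `centroid`
#' @export
mask_contour <- function(mask) {
  mv <- if (inherits(mask, "breast_mask")) mask$values else mask != 0
  pts <- trace_contour_cpp(mv * 1L)
  if (nrow(pts) < 8L) stop("degenerate contour: fewer than 8 boundary points")
  idx <- which(mv, arr.ind = TRUE)
  structure(list(points = pts,
                 centroid = c(mean(idx[, 1]), mean(idx[, 2]))),
            class = "contour")
}

shape_scalar_names <- function() {
  c("area", "perimeter", "compactness", "rectangularity", "circularity")
}

#' Five scalar shape features of the breast mask
#'
#' * area: pixel count x spacing^2 (cm^2)
#' * perimeter: chain-code boundary length, diagonal steps weighted
#'   sqrt(2), x spacing (cm)
#' * compactness: `P^2 / (4 pi A)` (1 for an ideal disk)
#' * rectangularity: area / axis-aligned bounding-box area
#' * circularity: `4 A / (pi d_max^2)` with `d_max` the maximal pairwise
#'   boundary distance
#'
#' @param mask a [breast_mask()] (must be a single connected component)
#' @param spacing pixel spacing in cm/pixel
#' @return named numeric vector of length 5
#' @export
shape_scalars5 <- function(mask, spacing = 0.02) {
  mv <- if (inherits(mask, "breast_mask")) mask$values else mask != 0
  lab <- cc_label_cpp(mv * 1L, 8L)
  if (attr(lab, "n_components") != 1L)
    stop("mask must be a single connected component")
  npix <- sum(mv)
  area <- npix * spacing^2
  ct <- mask_contour(mv)
  p <- ct$points
  d <- rbind(diff(p), p[1, ] - p[nrow(p), ])        # closed chain
  steps <- sqrt(rowSums(d^2))
  # chain-code weighting: unit for axis steps, sqrt(2) for diagonal steps
  perim <- sum(ifelse(abs(d[, 1]) + abs(d[, 2]) == 2, sqrt(2),
                      pmax(abs(d[, 1]), abs(d[, 2])))) * spacing
  compactness <- perim^2 / (4 * pi * area)
  idx <- which(mv, arr.ind = TRUE)
  bb <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  rectangularity <- npix / bb
  hull <- p[unique(grDevices::chull(p[, 1], p[, 2])), , drop = FALSE]
  dmax <- max(stats::dist(hull)) * spacing
  circularity <- 4 * area / (pi * dmax^2)
  out <- c(area, perim, compactness, rectangularity, circularity)
  names(out) <- shape_scalar_names()
  out
}

nrl_names <- function() {
  c("mean", "sd", "entropy", "area_ratio", "zero_crossings", "roughness")
}

#' Normalized radial length features of a contour
#'
#' The radial length `r(k)` is the distance from the mask centroid to
#' boundary point `k`, normalized by its maximum. Features: mean, standard
#' deviation, entropy of the 16-bin histogram of `r`, fraction of boundary
#' points above the mean, count of sign changes of `r - mean` along the
#' (circular) boundary, and roughness (mean absolute successive
#' difference).
#'
#' @param contour a `contour` from [mask_contour()]
#' @return named numeric vector of length 6
#' @export
radial_length_features6 <- function(contour) {
  stopifnot(inherits(contour, "contour"))
  p <- contour$points
  if (nrow(p) < 8L) stop("degenerate contour: fewer than 8 boundary points")
  r <- sqrt((p[, 1] - contour$centroid[1])^2 + (p[, 2] - contour$centroid[2])^2)
  r <- r / max(r)
  mu <- mean(r)
  bins <- pmin(floor(r * 16) + 1L, 16L)
  h <- tabulate(bins, nbins = 16L) / length(r)
  s <- sign(r - mu)
  s <- s[s != 0]
  zc <- sum(s[-1] != s[-length(s)])
  rough <- mean(abs(diff(c(r, r[1]))))
  out <- c(mu, stats::sd(r), sum(nlog2(h)), mean(r > mu), zc, rough)
  names(out) <- nrl_names()
  out
}

# resample a closed contour to n points equally spaced in arc length
resample_contour <- function(p, n = 128L) {
  q <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(q)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  t_out <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  cbind(stats::approx(s, q[, 1], xout = t_out)$y,
        stats::approx(s, q[, 2], xout = t_out)$y)
}

fd_names <- function() c("fd_low", "fd_mid", "fd_high")

#' Fourier descriptor band energies of a contour
#'
#' The boundary, resampled to 128 equidistant points, is treated as a
#' complex sequence; its DFT is made translation invariant by dropping the
#' DC coefficient and scale invariant by normalizing with the fundamental
#' `|c1|` (the contour is re-oriented if needed so the fundamental sits at
#' +1). Features are the normalized spectral energies in the low
#' (`|k|` in 2..5), mid (6..16) and high (17..64) bands; all three vanish
#' for an ideal circle.
#'
#' @param contour a `contour`
#' @return named numeric vector of length 3
#' @export
fourier_descriptor_features3 <- function(contour) {
  stopifnot(inherits(contour, "contour"))
  p <- resample_contour(contour$points, 128L)
  z <- complex(real = p[, 2], imaginary = p[, 1])
  co <- stats::fft(z) / length(z)
  if (Mod(co[128]) > Mod(co[2])) {       # canonical orientation
    z <- z[c(1L, 128:2)]
    co <- stats::fft(z) / length(z)
  }
  c1 <- co[2]
  if (Mod(c1) < 1e-12) stop("degenerate contour: |c1| = 0")
  k <- c(0:64, -63:-1)                   # signed frequency per DFT bin
  e <- Mod(co / Mod(c1))^2
  out <- c(sum(e[abs(k) >= 2 & abs(k) <= 5]),
           sum(e[abs(k) >= 6 & abs(k) <= 16]),
           sum(e[abs(k) >= 17 & abs(k) <= 64]))
  names(out) <- fd_names()
  out
}

#' Binary-mask moment features (72 values)
#'
#' The moment machinery applied to the mask itself as a 0/1 intensity
#' image: 16 normalized central moments, 7 Hu invariants and 49 Zernike
#' magnitudes, describing the morphology of the ROI independent of its
#' gray-level content.
#'
#' @param mask a [breast_mask()]
#' @return named numeric vector of length 72
#' @export
binary_moment_features72 <- function(mask) {
  stopifnot(inherits(mask, "breast_mask"))
  bin <- gray_image(mask$values * 1L, spacing = 1)
  ncm <- normalized_central_moments16(bin, mask)
  c(ncm, hu7(ncm), zernike49(bin, mask))
}
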