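# Moment-based features of the gray-level ROI: 4 central moments of the
# gray-value distribution, 16 normalized spatial central moments (eta_pq,
# p,q in 0..3), the 7 Hu rotation invariants and 49 Zernike moment
# magnitudes (orders n = 0..12). The same machinery is reused on the 0/1
# mask image for the form-based binary moments.

#' Central moments of the gray values inside the mask
#'
#' Population mean, variance, skewness (`mu3 / sigma^3`) and non-excess
#' kurtosis (`mu4 / sigma^4`) of the gray-value distribution. A constant
#' ROI has variance 0 and, by convention, skewness = kurtosis = 0.
#'
#' @param image a [gray_image()]
#' @param mask a [breast_mask()]
#' @return named numeric vector `c(mean, variance, skewness, kurtosis)`
#' @export
central_moments4 <- function(image, mask) {
  stopifnot(inherits(image, "gray_image"), inherits(mask, "breast_mask"))
  v <- as.numeric(image$values[mask$values])
  if (length(v) == 0L) stop("empty mask")
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  if (m2 > 0) {
    skew <- mean((v - mu)^3) / m2^1.5
    kurt <- mean((v - mu)^4) / m2^2
  } else skew <- kurt <- 0
  c(mean = mu, variance = m2, skewness = skew, kurtosis = kurt)
}

ncm_names <- function() {
  as.vector(t(outer(0:3, 0:3, function(p, q) sprintf("eta%d%d", p, q))))
}

#' Normalized spatial central moments eta_pq, p,q in 0..3
#'
#' Intensity-weighted spatial central moments about the intensity centroid,
#' restricted to the mask, normalized as
#' `eta_pq = mu_pq / mu_00^(1 + (p+q)/2)`. By construction `eta00 = 1` and
#' `eta10 = eta01 = 0`; these constants are retained so the moment group
#' counts 16 entries, and are removed downstream by the zero-variance
#' preselection. The first coordinate is the row index, the second the
#' column index.
#'
#' @inheritParams central_moments4
#' @return named numeric vector of length 16 (`eta00`, `eta01`, ..., `eta33`,
#'   p-major order)
#' @export
normalized_central_moments16 <- function(image, mask) {
  stopifnot(inherits(image, "gray_image"), inherits(mask, "breast_mask"))
  idx <- which(mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  f <- as.numeric(image$values[mask$values])
  m00 <- sum(f)
  if (m00 <= 0) stop("zero total intensity inside the mask")
  x <- idx[, 1]; y <- idx[, 2]
  xb <- sum(f * x) / m00; yb <- sum(f * y) / m00
  dx <- x - xb; dy <- y - yb
  xp <- cbind(1, dx, dx^2, dx^3)
  yp <- cbind(1, dy, dy^2, dy^3)
  out <- numeric(16)
  k <- 1L
  for (p in 0:3) for (q in 0:3) {
    mu_pq <- sum(f * xp[, p + 1] * yp[, q + 1])
    out[k] <- mu_pq / m00^(1 + (p + q) / 2)
    k <- k + 1L
  }
  names(out) <- ncm_names()
  # exact definitional identities, not subject to round-off accumulation
  out["eta00"] <- 1
  out["eta10"] <- 0
  out["eta01"] <- 0
  out
}

#' Hu's seven rotation-invariant moments
#'
#' Standard algebraic combinations of the second- and third-order
#' normalized central moments, invariant to translation, scale and
#' rotation of the ROI.
#'
#' @param ncm named vector from [normalized_central_moments16()]
#' @return named numeric vector `phi1` .. `phi7`
#' @export
hu7 <- function(ncm) {
  e <- function(p, q) ncm[[sprintf("eta%d%d", p, q)]]
  n20 <- e(2, 0); n02 <- e(0, 2); n11 <- e(1, 1)
  n30 <- e(3, 0); n03 <- e(0, 3); n21 <- e(2, 1); n12 <- e(1, 2)
  a <- n30 + n12; b <- n21 + n03
  phi <- c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    a^2 + b^2,
    (n30 - 3 * n12) * a * (a^2 - 3 * b^2) + (3 * n21 - n03) * b * (3 * a^2 - b^2),
    (n20 - n02) * (a^2 - b^2) + 4 * n11 * a * b,
    (3 * n21 - n03) * a * (a^2 - 3 * b^2) - (n30 - 3 * n12) * b * (3 * a^2 - b^2))
  names(phi) <- paste0("phi", 1:7)
  phi
}

# (n, m) index pairs with n = 0..12, 0 <= m <= n, n - m even: exactly 49
zernike_index_table <- function(n_max = 12L) {
  out <- do.call(rbind, lapply(0:n_max, function(n) {
    m <- seq(n %% 2L, n, by = 2L)
    cbind(n = rep(n, length(m)), m = m)
  }))
  as.data.frame(out)
}

# radial polynomial R_nm evaluated at rho (vector), exact integer coefficients
zernike_radial <- function(n, m, rho_pow) {
  k <- 0:((n - m) / 2)
  coef <- (-1)^k * factorial(n - k) /
    (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k))
  pw <- n - 2 * k
  as.vector(rho_pow[, pw + 1L, drop = FALSE] %*% coef)
}

# 13 x 49 matrix of radial-polynomial coefficients: column k gives the
# coefficients of rho^0..rho^12 for the k-th (n, m) pair
.zernike_coef <- local({
  tab <- zernike_index_table()
  cm <- matrix(0, 13, nrow(tab))
  for (kk in seq_len(nrow(tab))) {
    n <- tab$n[kk]; m <- tab$m[kk]
    k <- 0:((n - m) / 2)
    coef <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k))
    cm[n - 2 * k + 1L, kk] <- coef
  }
  cm
})

zernike_names <- function() {
  tab <- zernike_index_table()
  sprintf("z%02d_%02d", tab$n, tab$m)
}

#' Zernike moment magnitudes up to order 12
#'
#' Magnitudes `|A_nm|` of the Zernike moments of the masked intensity,
#' computed on the smallest unit disk containing the whole mask, centered
#' at the intensity centroid; all 49 index pairs with
#' `n = 0..12`, `0 <= m <= n`, `n - m` even. Magnitudes are invariant to
#' rotations of the ROI.
#'
#' @inheritParams central_moments4
#' @return named numeric vector of length 49 (`z00_00` .. `z12_12`)
#' @export
zernike49 <- function(image, mask) {
  stopifnot(inherits(image, "gray_image"), inherits(mask, "breast_mask"))
  idx <- which(mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  f <- as.numeric(image$values[mask$values])
  tot <- sum(f)
  if (tot <= 0) { xb <- mean(idx[, 1]); yb <- mean(idx[, 2]) }
  else { xb <- sum(f * idx[, 1]) / tot; yb <- sum(f * idx[, 2]) / tot }
  # disk radius: smallest centroid-centered circle containing every mask
  # pixel, so the mask exactly fills the unit disk
  R <- max(sqrt((idx[, 1] - xb)^2 + (idx[, 2] - yb)^2))
  if (R <= 0) R <- 1
  dx <- (idx[, 1] - xb) / R; dy <- (idx[, 2] - yb) / R
  rho <- sqrt(dx^2 + dy^2)
  keep <- rho <= 1
  rho <- rho[keep]; theta <- atan2(dy[keep], dx[keep]); fv <- f[keep]
  npix <- length(rho)
  rho_pow <- matrix(1, npix, 13)
  for (k in 2:13) rho_pow[, k] <- rho_pow[, k - 1] * rho
  tab <- zernike_index_table()
  Rnm <- rho_pow %*% .zernike_coef               # npix x 49
  # cos(m theta), sin(m theta) for m = 0..12 by Chebyshev recurrence
  cth <- cos(theta); sth <- sin(theta)
  cosb <- sinb <- matrix(0, npix, 13)
  cosb[, 1] <- 1; cosb[, 2] <- cth; sinb[, 2] <- sth
  for (k in 3:13) {
    cosb[, k] <- 2 * cth * cosb[, k - 1] - cosb[, k - 2]
    sinb[, k] <- 2 * cth * sinb[, k - 1] - sinb[, k - 2]
  }
  dA <- 1 / R^2                      # pixel area element in unit-disk coords
  re <- im <- numeric(nrow(tab))
  for (mv in unique(tab$m)) {        # group columns sharing the harmonic
    cols <- which(tab$m == mv)
    re[cols] <- crossprod(Rnm[, cols, drop = FALSE], fv * cosb[, mv + 1L])
    im[cols] <- -crossprod(Rnm[, cols, drop = FALSE], fv * sinb[, mv + 1L])
  }
  out <- (tab$n + 1) / pi * sqrt(re^2 + im^2) * dA
  names(out) <- zernike_names()
  out
}
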