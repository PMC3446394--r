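# First- and second-order statistical texture features: 16-bin histogram,
# 13 Haralick GLCM features and 25 sum/difference-histogram features.
# All second-order statistics use the same fixed 16-level quantization
# (level = floor(gray/16)) and pool pixel pairs over four distance-1
# directions (0, 45, 90, 135 degrees), accumulated in both orders so the
# co-occurrence matrix is symmetric.

G_LEVELS <- 16L

# distance-1 displacement vectors (dr, dc) for the four pooled directions
default_offsets <- function() list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

#' Quantize a masked image to 16 gray-level categories
#'
#' The full 0-255 spectrum is divided into 16 equal categories with the
#' fixed map `level = floor(gray / 16)`. Off-mask pixels are flagged
#' invalid (NA) and never contribute to any pair, run or region statistic.
#'
#' @param image a [gray_image()]
#' @param mask a [breast_mask()] aligned to the image
#' @return a `quantized_roi`: integer level matrix (NA off-mask) with
#'   spacing and level count attached
#' @export
quantize <- function(image, mask) {
  stopifnot(inherits(image, "gray_image"), inherits(mask, "breast_mask"))
  stopifnot(identical(dim(image$values), dim(mask$values)))
  if (!any(mask$values)) stop("empty mask")
  lev <- image$values %/% 16L
  lev[!mask$values] <- NA_integer_
  structure(list(levels = lev, spacing = image$spacing, G = G_LEVELS),
            class = "quantized_roi")
}

quantized_roi <- function(levels, spacing) {
  stopifnot(is.matrix(levels))
  structure(list(levels = levels, spacing = spacing, G = G_LEVELS),
            class = "quantized_roi")
}

#' Histogram features: relative frequency of the 16 gray-level categories
#'
#' Computed at full resolution only. The 16 frequencies sum to 1.
#'
#' @param roi a `quantized_roi`
#' @return named numeric vector of length 16 (`bin01` .. `bin16`)
#' @export
histogram_features <- function(roi) {
  stopifnot(inherits(roi, "quantized_roi"))
  v <- roi$levels[!is.na(roi$levels)]
  if (length(v) == 0L) stop("empty ROI")
  h <- tabulate(v + 1L, nbins = G_LEVELS) / length(v)
  names(h) <- sprintf("bin%02d", 1:G_LEVELS)
  h
}

# shifted-overlap view of a level matrix for one displacement:
# returns cbind(a, b) of co-occurring levels (one order), NA rows dropped
pair_levels <- function(lev, off) {
  nr <- nrow(lev); nc <- ncol(lev)
  dr <- off[1]; dc <- off[2]
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r1) == 0L || length(c1) == 0L) return(NULL)
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  cbind(a[ok], b[ok])
}

#' Accumulate a gray-level co-occurrence matrix over pooled offsets
#'
#' Pairs with both endpoints inside the mask are counted for every offset
#' and in both orders, then normalized, giving a symmetric 16 x 16
#' probability matrix summing to 1.
#'
#' @param roi a `quantized_roi`
#' @param offsets list of integer `(dr, dc)` displacement vectors
#' @return a `glcm` object: list with `p` (16 x 16 matrix) and `n_pairs`
#' @export
glcm_accumulate <- function(roi, offsets = default_offsets()) {
  stopifnot(inherits(roi, "quantized_roi"), length(offsets) > 0)
  counts <- matrix(0, G_LEVELS, G_LEVELS)
  for (off in offsets) {
    ab <- pair_levels(roi$levels, off)
    if (is.null(ab)) next
    idx <- ab[, 1] * G_LEVELS + ab[, 2] + 1L
    tb <- tabulate(idx, nbins = G_LEVELS * G_LEVELS)
    m <- matrix(tb, G_LEVELS, G_LEVELS, byrow = TRUE)
    counts <- counts + m + t(m)         # both orders -> symmetric
  }
  n <- sum(counts)
  if (n == 0) stop("no valid pixel pairs inside the mask")
  structure(list(p = counts / n, n_pairs = n), class = "glcm")
}

glcm_feature_names <- function() {
  c("asm", "contrast", "correlation", "variance", "idm",
    "sum_average", "sum_variance", "sum_entropy", "entropy",
    "diff_variance", "diff_entropy", "imc1", "imc2")
}

# -x * log2(x) with the 0 log 0 = 0 convention
nlog2 <- function(x) ifelse(x > 0, -x * log2(x), 0)

#' The 13 Haralick features of a co-occurrence matrix
#'
#' Fixed order: angular second moment, contrast, correlation, sum of
#' squares variance, inverse difference moment, sum average, sum variance,
#' sum entropy, entropy, difference variance, difference entropy, and the
#' two information measures of correlation. Logs are base 2 with
#' `0 log 0 = 0`. Sum variance is centred on the sum average; difference
#' variance is the variance of the folded `|i - j|` histogram. A degenerate
#' matrix (all mass on one level) yields correlation 0 with a warning.
#'
#' @param g a `glcm`
#' @return named numeric vector of length 13
#' @export
haralick13 <- function(g) {
  stopifnot(inherits(g, "glcm"))
  p <- g$p
  Gn <- nrow(p)
  i <- matrix(0:(Gn - 1), Gn, Gn)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  lev <- 0:(Gn - 1)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sdx <- sqrt(sum((lev - mux)^2 * px)); sdy <- sqrt(sum((lev - muy)^2 * py))
  # sum and difference marginals of the same pairs
  ps <- vapply(0:(2 * Gn - 2), function(k) sum(p[i + j == k]), numeric(1))
  pd <- vapply(0:(Gn - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 0:(2 * Gn - 2); kd <- 0:(Gn - 1)
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  if (sdx == 0 || sdy == 0) {
    warning("degenerate GLCM: correlation undefined, returning 0")
    correlation <- 0
  } else {
    correlation <- (sum(i * j * p) - mux * muy) / (sdx * sdy)
  }
  variance <- sum((i - mux)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  sum_average <- sum(ks * ps)
  sum_variance <- sum((ks - sum_average)^2 * ps)
  sum_entropy <- sum(nlog2(ps))
  entropy <- sum(nlog2(p))
  mu_d <- sum(kd * pd)
  diff_variance <- sum((kd - mu_d)^2 * pd)
  diff_entropy <- sum(nlog2(pd))
  hx <- sum(nlog2(px)); hy <- sum(nlog2(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- sum(nlog2(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(1 - exp(-2 * max(hxy2 - entropy, 0)))
  out <- c(asm, contrast, correlation, variance, idm, sum_average,
           sum_variance, sum_entropy, entropy, diff_variance, diff_entropy,
           imc1, imc2)
  names(out) <- glcm_feature_names()
  out
}

#' Accumulate sum and difference histograms over pooled offsets
#'
#' For the same masked pixel pairs as [glcm_accumulate()], the normalized
#' histograms of `s = i + j` (support 0..30) and `d = i - j` (support
#' -15..15; symmetric because both orders are counted).
#'
#' @inheritParams glcm_accumulate
#' @return an `sdh` object with `sum_hist` (31), `diff_hist` (31), `n_pairs`
#' @export
sdh_accumulate <- function(roi, offsets = default_offsets()) {
  stopifnot(inherits(roi, "quantized_roi"), length(offsets) > 0)
  sh <- numeric(2 * G_LEVELS - 1)
  dh <- numeric(2 * G_LEVELS - 1)
  n <- 0
  for (off in offsets) {
    ab <- pair_levels(roi$levels, off)
    if (is.null(ab)) next
    s <- ab[, 1] + ab[, 2]
    d <- ab[, 1] - ab[, 2]
    sh <- sh + 2 * tabulate(s + 1L, nbins = 31L)       # both orders: same s
    dh <- dh + tabulate(d + 16L, nbins = 31L) +
      tabulate(-d + 16L, nbins = 31L)                  # both orders: +/- d
    n <- n + 2 * nrow(ab)
  }
  if (n == 0) stop("no valid pixel pairs inside the mask")
  structure(list(sum_hist = sh / n, diff_hist = dh / n, n_pairs = n),
            class = "sdh")
}

hist_moments <- function(p, support) {
  mu <- sum(support * p)
  v <- sum((support - mu)^2 * p)
  if (v > 0) {
    skew <- sum((support - mu)^3 * p) / v^1.5
    kurt <- sum((support - mu)^4 * p) / v^2
  } else skew <- kurt <- 0
  c(mean = mu, variance = v, skewness = skew, kurtosis = kurt,
    energy = sum(p^2), entropy = sum(nlog2(p)))
}

# one-pass accumulation of both second-order structures over the same pairs
# (used by the feature bank so pairs are enumerated once per scale)
second_order_features <- function(roi, offsets = default_offsets()) {
  counts <- matrix(0, G_LEVELS, G_LEVELS)
  for (off in offsets) {
    ab <- pair_levels(roi$levels, off)
    if (is.null(ab)) next
    tb <- tabulate(ab[, 1] * G_LEVELS + ab[, 2] + 1L,
                   nbins = G_LEVELS * G_LEVELS)
    m <- matrix(tb, G_LEVELS, G_LEVELS, byrow = TRUE)
    counts <- counts + m + t(m)
  }
  n <- sum(counts)
  if (n == 0) stop("no valid pixel pairs inside the mask")
  p <- counts / n
  i <- matrix(0:(G_LEVELS - 1), G_LEVELS, G_LEVELS); j <- t(i)
  sh <- vapply(0:30, function(k) sum(p[i + j == k]), numeric(1))
  dh <- vapply(-15:15, function(k) sum(p[i - j == k]), numeric(1))
  g <- structure(list(p = p, n_pairs = n), class = "glcm")
  h <- structure(list(sum_hist = sh, diff_hist = dh, n_pairs = n),
                 class = "sdh")
  c(haralick13(g), sdh_features25(h))
}

sdh_feature_names <- function() {
  c(paste0("sum_", c("mean", "variance", "skewness", "kurtosis", "energy", "entropy")),
    paste0("diff_", c("mean", "variance", "skewness", "kurtosis", "energy", "entropy")),
    paste0("u_", glcm_feature_names()))
}

#' The 25 sum/difference-histogram features
#'
#' 12 direct statistics — mean, variance, skewness, kurtosis, energy and
#' entropy of the sum histogram ("sum of X") and of the difference
#' histogram ("difference of X") — plus 13 Unser-style estimates of the
#' Haralick features, in the same order as [haralick13()], computed from
#' the sum and difference histograms alone. Entries with an exact identity
#' (contrast, sum average/variance/entropy, difference variance/entropy)
#' equal the corresponding GLCM feature; the information measures use the
#' joint reconstructed under Unser's sum/difference independence
#' assumption. Zero-variance histograms give skewness = kurtosis = 0.
#'
#' @param h an `sdh`
#' @return named numeric vector of length 25
#' @export
sdh_features25 <- function(h) {
  stopifnot(inherits(h, "sdh"))
  ps <- h$sum_hist; pd <- h$diff_hist
  s_sup <- 0:30; d_sup <- -15:15
  ms <- hist_moments(ps, s_sup)
  md <- hist_moments(pd, d_sup)
  # folded |d| histogram for the difference-variance analogue
  pda <- numeric(G_LEVELS)
  pda[1] <- pd[16]
  for (k in 1:15) pda[k + 1] <- pd[16 + k] + pd[16 - k]
  kd <- 0:15
  mu_da <- sum(kd * pda)
  sigma_s2 <- ms[["variance"]]; sigma_d2 <- sum(d_sup^2 * pd) - sum(d_sup * pd)^2
  hs <- ms[["entropy"]]; hd <- md[["entropy"]]
  u <- numeric(13)
  u[1] <- sum(ps^2) * sum(pd^2)                               # asm
  u[2] <- sum(d_sup^2 * pd)                                   # contrast (exact)
  u[3] <- if (sigma_s2 + sigma_d2 > 0)
    (sigma_s2 - sigma_d2) / (sigma_s2 + sigma_d2) else 0      # correlation
  u[4] <- (sigma_s2 + sigma_d2) / 4                           # variance
  u[5] <- sum(pd / (1 + d_sup^2))                             # idm
  u[6] <- ms[["mean"]]                                        # sum average (exact)
  u[7] <- sigma_s2                                            # sum variance (exact)
  u[8] <- hs                                                  # sum entropy (exact)
  u[9] <- hs + hd                                             # entropy estimate
  u[10] <- sum((kd - mu_da)^2 * pda)                          # diff variance (exact)
  u[11] <- hd                                                 # diff entropy (exact)
  # information measures from the independence-reconstructed joint
  i <- matrix(0:(G_LEVELS - 1), G_LEVELS, G_LEVELS); j <- t(i)
  q <- ps[i + j + 1L] * pd[i - j + 16L]
  q <- matrix(q, G_LEVELS, G_LEVELS)
  tq <- sum(q)
  if (tq > 0) {
    q <- q / tq
    qx <- rowSums(q); qy <- colSums(q)
    hq <- sum(nlog2(q)); hqx <- sum(nlog2(qx)); hqy <- sum(nlog2(qy))
    qxy <- outer(qx, qy)
    hxy1 <- -sum(q[qxy > 0] * log2(qxy[qxy > 0]))
    hxy2 <- sum(nlog2(qxy))
    u[12] <- if (max(hqx, hqy) > 0) (hq - hxy1) / max(hqx, hqy) else 0
    u[13] <- sqrt(1 - exp(-2 * max(hxy2 - hq, 0)))
  }
  out <- c(ms, md, u)
  names(out) <- sdh_feature_names()
  out
}
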