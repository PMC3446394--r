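# Synthetic mammogram surrogate: a bright half-elliptical breast attached
# to the left image edge on a dark background, with optional saturated
# border stripes and a film-label blob, a smooth low-frequency "fatty"
# field inside the breast, and dense-tissue blobs occupying a prescribed
# fraction of the breast area. Case status shifts two second-order texture
# parameters chosen to drive decoupled feature carriers: the local
# micro-texture contrast (film-grain amplitude; raises the co-occurrence
# contrast and lowers lag-1 spatial correlation, independent of the
# dense-area fraction) and the fatty-field correlation length (raises
# lag-1 correlation). Physical parameters are in cm so images can be
# rendered at any pixel spacing.

# separable Gaussian smoothing with edge replication
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-h:h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(x) {        # along rows (dim 1)
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    for (o in -h:h) {
      rows <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- out + k[o + h + 1L] * x[rows, , drop = FALSE]
    }
    out
  }
  t(smooth1(t(smooth1(m))))
}

default_image_params <- function() {
  list(shape = c(256L, 208L), spacing = 0.02, pmd = 20,
       contrast_amp = 35, edge_sigma_cm = 0.06, corr_len_cm = 0.12,
       grain_sd = 5, stripe_prob = 0.5, label_prob = 0.7)
}

#' Generate one synthetic mammogram-like image with ground truth
#'
#' Renders a dark background, a half-elliptical breast region attached to
#' the left edge with a low-order harmonic boundary perturbation, a smooth
#' fatty texture field (Gaussian random field with correlation length
#' `corr_len_cm`), dense blobs covering `pmd`% of the breast area with
#' amplitude `contrast_amp` and edge profile width `edge_sigma_cm` (small
#' values = sharp, high-contrast blob edges), plus (optionally) saturated
#' white border stripes and a bright film-label blob disjoint from the
#' breast. Deterministic given `seed`.
#'
#' @param params list; see `default_image_params()` for fields and
#'   defaults: `shape` (rows, cols), `spacing` (cm/px), `pmd` (dense-area
#'   percent 0-100), `contrast_amp` (gray levels), `edge_sigma_cm`,
#'   `corr_len_cm`, `grain_sd` (local micro-texture contrast, gray
#'   levels), `stripe_prob`, `label_prob`
#' @param seed integer seed
#' @return list with `image` ([gray_image()]), `mask` ([breast_mask()]
#'   ground truth), `dense_mask` (logical), `pmd_achieved` (percent)
#' @export
generate_image <- function(params = list(), seed = 1L) {
  p <- utils::modifyList(default_image_params(), params)
  nr <- p$shape[1]; nc <- p$shape[2]
  if (nr < 128L || nc < 128L)
    stop("image_shape must be at least 128 x 128 pixels")
  stopifnot(p$spacing > 0, p$pmd >= 0, p$pmd <= 100)
  with_seed(seed, {
    img <- matrix(pmin(pmax(round(rnorm(nr * nc, 8, 2)), 0), 30), nr, nc)
    # breast geometry: half ellipse attached to the left edge
    r0 <- nr * runif(1, 0.45, 0.55)
    a <- nr * runif(1, 0.34, 0.44)
    b <- nc * runif(1, 0.50, 0.68)
    eps <- runif(3, 0, 0.04)
    phs <- runif(3, 0, 2 * pi)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    dx <- (cols - 1) / b
    dy <- (rows - r0) / a
    theta <- atan2(dy, pmax(dx, 1e-12))
    pert <- eps[1] * cos(2 * theta + phs[1]) + eps[2] * cos(3 * theta + phs[2]) +
      eps[3] * cos(4 * theta + phs[3])
    breast <- (dx^2 + dy^2) <= (1 + pert)^2
    touches <- c(any(breast[1, ]), any(breast[nr, ]),
                 any(breast[, 1]), any(breast[, nc]))
    if (all(touches)) stop("breast region touches all four image edges")
    nB <- sum(breast)
    # fatty field: smoothed white noise, correlation length in cm
    sigma_px <- p$corr_len_cm / p$spacing
    field <- gauss_smooth(matrix(rnorm(nr * nc), nr, nc), sigma_px)
    field <- (field - mean(field)) / stats::sd(field)
    # dense blobs up to the target area fraction (within one pixel)
    dense <- matrix(FALSE, nr, nc)
    target <- round(p$pmd / 100 * nB)
    b_idx <- which(breast)
    guard <- 0L
    while (sum(dense) < target && guard < 500L) {
      guard <- guard + 1L
      need <- target - sum(dense)
      r_px <- runif(1, 0.06, 0.35) / p$spacing
      if (pi * r_px^2 > need) r_px <- max(sqrt(need / pi), 1)
      ctr <- b_idx[sample.int(length(b_idx), 1L)]
      cr <- ((ctr - 1L) %% nr) + 1L
      cc <- ((ctr - 1L) %/% nr) + 1L
      d2 <- (rows - cr)^2 + (cols - cc)^2
      cand <- which(d2 <= r_px^2 & breast & !dense)
      if (length(cand) > need)
        cand <- cand[order(d2[cand])[seq_len(need)]]
      dense[cand] <- TRUE
    }
    pmd_achieved <- 100 * sum(dense) / nB
    dense_field <- gauss_smooth(dense * 1, max(p$edge_sigma_cm / p$spacing, 0.3))
    interior <- 110 + 18 * field + p$contrast_amp * dense_field +
      rnorm(nr * nc, 0, p$grain_sd)
    img[breast] <- interior[breast]
    # saturated border stripes (never on the left edge, where the breast sits)
    if (runif(1) < p$stripe_prob) {
      for (edge in sample(c("top", "bottom", "right"), sample(1:2, 1))) {
        w <- sample(2:4, 1)
        if (edge == "top") img[seq_len(w), ] <- 255
        if (edge == "bottom") img[nr - seq_len(w) + 1L, ] <- 255
        if (edge == "right") img[, nc - seq_len(w) + 1L] <- 255
      }
    }
    # film-label blob disjoint from the breast
    if (runif(1) < p$label_prob) {
      right_extent <- max(cols[breast])
      if (right_extent + 20L < nc - 6L) {
        h <- sample(8:14, 1); w <- sample(12:20, 1)
        cc0 <- sample((right_extent + 8L):(nc - w - 2L), 1)
        rr0 <- sample(3:(nr - h - 2L), 1)
        img[rr0:(rr0 + h), cc0:(cc0 + w)] <-
          pmin(pmax(round(230 + rnorm((h + 1) * (w + 1), 0, 5)), 200), 250)
      }
    }
    img <- pmin(pmax(round(img), 0), 255)
    list(image = gray_image(img, p$spacing),
         mask = breast_mask(breast, provenance = "automatic"),
         dense_mask = dense,
         pmd_achieved = pmd_achieved)
  })
}
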