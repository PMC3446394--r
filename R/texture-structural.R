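# Structural microtexture features: Chen's 16 statistical-geometrical
# features (SGF) computed from a stack of threshold binarizations of the
# quantized ROI, and 20 run-length features (Galloway's 5 statistics in 4
# scan directions). Both families are computed at three scales via the
# block-mean downscaling in the feature bank.

sgf_feature_names <- function() {
  as.vector(t(outer(c("noc1", "noc0", "irgl1", "irgl0"),
                    c("max", "avg", "smean", "ssd"), paste, sep = "_")))
}

# area-weighted mean irregularity of the regions in a label matrix;
# irregularity = sqrt(pi) * max-centroid-distance / sqrt(area) - 1,
# clamped at 0 (exactly 0 for a continuous disk)
region_irregularity <- function(lab) {
  n <- attr(lab, "n_components")
  if (n == 0L) return(0)
  st <- region_stats_cpp(lab, n)
  irr <- pmax(sqrt(pi) * st[, 2] / sqrt(st[, 1]) - 1, 0)
  sum(st[, 1] * irr) / sum(st[, 1])
}

#' Chen's 16 statistical-geometrical features
#'
#' For each threshold `alpha = 1..15` the ROI is binarized into
#' `B_alpha = (level >= alpha)` and its within-mask complement. Four curves
#' over alpha are formed: the number of 8-connected regions of each stack
#' (NOC1, NOC0) and the area-weighted mean irregularity of those regions
#' (IRGL1, IRGL0). Each curve is summarized by its maximum, its average,
#' its sample mean (treating the curve as a distribution over alpha) and
#' the corresponding sample standard deviation: 4 curves x 4 statistics =
#' 16 features.
#'
#' @param roi a `quantized_roi`
#' @return named numeric vector of length 16
#' @export
sgf16 <- function(roi) {
  stopifnot(inherits(roi, "quantized_roi"))
  lev <- roi$levels
  if (!any(!is.na(lev))) stop("empty ROI")
  alphas <- 1:15
  curves <- sgf_curves_cpp(lev)
  noc1 <- curves[, 1]; noc0 <- curves[, 2]
  irgl1 <- curves[, 3]; irgl0 <- curves[, 4]
  curve_stats <- function(g) {
    tot <- sum(g)
    smean <- if (tot > 0) sum(alphas * g) / tot else 0
    ssd <- if (tot > 0) sqrt(sum((alphas - smean)^2 * g) / tot) else 0
    c(max = max(g), avg = mean(g), smean = smean, ssd = ssd)
  }
  out <- c(curve_stats(noc1), curve_stats(noc0),
           curve_stats(irgl1), curve_stats(irgl0))
  names(out) <- sgf_feature_names()
  out
}

rl_directions <- function() c(0L, 45L, 90L, 135L)

# scan-direction displacement (dr, dc) per direction
rl_step <- function(direction) {
  switch(as.character(direction),
         "0" = c(0L, 1L), "45" = c(-1L, 1L),
         "90" = c(1L, 0L), "135" = c(1L, 1L))
}

#' Run-length matrix for one scan direction
#'
#' Counts of maximal runs of equal quantized level along the given
#' direction, indexed by (gray level 0..15, run length). Runs end where
#' the mask ends, so background never contributes.
#'
#' @param roi a `quantized_roi`
#' @param direction one of 0, 45, 90, 135 (degrees)
#' @return integer matrix, 16 rows (levels) x max run length columns
#' @export
runlength_matrix <- function(roi, direction = 0L) {
  stopifnot(inherits(roi, "quantized_roi"),
            direction %in% rl_directions())
  st <- rl_step(direction)
  m <- rl_counts_cpp(roi$levels, st[1], st[2])
  dimnames(m) <- list(level = 0:15, length = seq_len(ncol(m)))
  m
}

rl_feature_names <- function() {
  as.vector(t(outer(sprintf("d%03d", rl_directions()),
                    c("sre", "lre", "gln", "rln", "rp"),
                    function(d, s) paste(s, d, sep = "_"))))
}

#' Galloway's run-length features, per direction (20 values)
#'
#' Short-run emphasis, long-run emphasis, gray-level nonuniformity,
#' run-length nonuniformity and run percentage, computed separately for
#' each of the four scan directions (4 x 5 = 20 features).
#'
#' @param roi a `quantized_roi`
#' @return named numeric vector of length 20
#' @export
runlength_features20 <- function(roi) {
  stopifnot(inherits(roi, "quantized_roi"))
  npix <- sum(!is.na(roi$levels))
  out <- numeric(0)
  for (d in rl_directions()) {
    m <- runlength_matrix(roi, d)
    N <- sum(m)
    if (N == 0L) {
      f <- c(sre = 0, lre = 0, gln = 0, rln = 0, rp = 0)
    } else {
      lens <- seq_len(ncol(m))
      per_len <- colSums(m)
      f <- c(sre = sum(per_len / lens^2) / N,
             lre = sum(per_len * lens^2) / N,
             gln = sum(rowSums(m)^2) / N,
             rln = sum(per_len^2) / N,
             rp = N / npix)
    }
    out <- c(out, f)
  }
  names(out) <- rl_feature_names()
  out
}
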