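# Wavelet-energy features: a 3-level separable periodized 2-D wavelet
# pyramid is computed for seven fixed bases, and the mean squared
# coefficient of each subband (3 detail orientations x 3 levels + final
# approximation = 10 subbands) is recorded, giving 70 catalog entries.
# Filters are the standard published decomposition coefficients.

wavelet_bases <- function() names(.wavelet_filters)

.wavelet_filters <- local({
  orth <- function(lo) {
    L <- length(lo)
    hi <- rev(lo) * (-1)^(seq_len(L) - 1)  # quadrature mirror
    list(lo = lo, hi = hi, orthogonal = TRUE)
  }
  s2 <- sqrt(2) / 2
  list(
    haar = orth(c(s2, s2)),
    db2 = orth(c(-0.1294095225512604, 0.2241438680420134,
                 0.8365163037378079, 0.4829629131445342)),
    db3 = orth(c(0.0352262918857095, -0.0854412738820267,
                 -0.1350110200102546, 0.4598775021184915,
                 0.8068915093110925, 0.3326705529500826)),
    db4 = orth(c(-0.0105974017850690, 0.0328830116668852,
                 0.0308413818355608, -0.1870348117190931,
                 -0.0279837694168599, 0.6308807679298589,
                 0.7148465705529157, 0.2303778133088965)),
    sym4 = orth(c(-0.0757657147892733, -0.0296355276459985,
                  0.4976186676320155, 0.8037387518059161,
                  0.2978577956052774, -0.0992195435768472,
                  -0.0126039672620378, 0.0322231006040427)),
    sym5 = orth(c(0.0273330683450780, 0.0295194909257746,
                  -0.0391342493023831, 0.1993975339773936,
                  0.7234076904024206, 0.6339789634582119,
                  0.0166021057645223, -0.1753280899084505,
                  -0.0211018340247589, 0.0195388827352867)),
    bior2.2 = list(
      lo = c(0, -0.1767766952966369, 0.3535533905932738,
             1.0606601717798212, 0.3535533905932738, -0.1767766952966369),
      hi = c(0, 0.3535533905932738, -0.7071067811865476,
             0.3535533905932738, 0, 0),
      orthogonal = FALSE))
})

dwt2_level <- function(x, lo, hi) {
  # LH: detail along dim 2 (horizontal); HL: detail along dim 1 (vertical)
  dwt2_level_cpp(x, lo, hi)
}

# pad a matrix to dimensions divisible by 2^levels by edge replication
pad_to_multiple <- function(x, mult) {
  nr <- nrow(x); nc <- ncol(x)
  pr <- (mult - nr %% mult) %% mult
  pc <- (mult - nc %% mult) %% mult
  if (pr > 0) x <- rbind(x, x[rep(nr, pr), , drop = FALSE])
  if (pc > 0) x <- cbind(x, x[, rep(nc, pc), drop = FALSE])
  x
}

subband_names <- function(levels = 3L) {
  c(as.vector(t(outer(sprintf("L%d", seq_len(levels)), c("H", "V", "D"),
                      paste, sep = "_"))),
    sprintf("L%d_A", levels))
}

#' Subband energies of a 3-level wavelet pyramid
#'
#' Standard pyramid decomposition: each level splits the previous
#' approximation into four subbands by separable periodized filtering.
#' The horizontal (H), vertical (V) and diagonal (D) detail energies at
#' each level plus the final approximation energy give 10 values; energy
#' is the mean squared coefficient. "Horizontal" detail responds to
#' intensity variation along the column axis (vertical stripes). Inputs
#' whose dimensions are not divisible by `2^levels` are edge-padded first;
#' for an orthogonal basis and unpadded input the total sum of squared
#' coefficients equals the sum of squared pixels (Parseval).
#'
#' @param crop numeric matrix (gray values), both dimensions >= `2^levels`
#' @param basis basis id, one of `wavelet_bases()`
#' @param levels number of pyramid levels (default 3)
#' @return named numeric vector of length `3 * levels + 1` with attribute
#'   `ss` (per-subband sums of squares) and `total_ss`
#' @export
pyramid_energies <- function(crop, basis = "haar", levels = 3L) {
  stopifnot(is.matrix(crop), basis %in% wavelet_bases())
  if (min(dim(crop)) < 2^levels)
    stop("crop too small for a ", levels, "-level pyramid")
  f <- .wavelet_filters[[basis]]
  x <- pad_to_multiple(crop, 2L^levels)
  total_ss <- sum(x^2)
  energies <- ss <- numeric(0)
  for (l in seq_len(levels)) {
    w <- dwt2_level(x, f$lo, f$hi)
    energies <- c(energies, mean(w$LH^2), mean(w$HL^2), mean(w$HH^2))
    ss <- c(ss, sum(w$LH^2), sum(w$HL^2), sum(w$HH^2))
    x <- w$LL
  }
  energies <- c(energies, mean(x^2))
  ss <- c(ss, sum(x^2))
  names(energies) <- subband_names(levels)
  structure(energies, ss = ss, total_ss = total_ss)
}

spectral_feature_names <- function() {
  unlist(lapply(wavelet_bases(), function(b)
    paste(gsub("\\.", "", b), subband_names(), sep = "_")))
}

#' The 70 wavelet-energy features of a masked image
#'
#' The mask's bounding-box crop is taken, off-mask pixels are replaced by
#' the mean interior gray value (so background content can never leak into
#' the features), and [pyramid_energies()] is evaluated for each of the
#' seven fixed bases: 7 x 10 = 70 features, full resolution only.
#'
#' @param image a [gray_image()]
#' @param mask a [breast_mask()]
#' @return named numeric vector of length 70
#' @export
spectral_features70 <- function(image, mask) {
  stopifnot(inherits(image, "gray_image"), inherits(mask, "breast_mask"))
  idx <- which(mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  rr <- range(idx[, 1]); cr <- range(idx[, 2])
  crop <- image$values[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE] * 1.0
  sub <- mask$values[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  crop[!sub] <- mean(crop[sub])
  out <- unlist(lapply(wavelet_bases(), function(b)
    as.numeric(pyramid_energies(crop, b))))
  names(out) <- spectral_feature_names()
  out
}
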