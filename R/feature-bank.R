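# Registry of the 470 features, the multiscale (full / 0.5 cm / 1.0 cm)
# orchestration and the per-subject feature vector. Canonical ordering:
# group (moment, form, statistical, structural, spectral), then family,
# then scale (full, 0.5cm, 1.0cm), then formula order. The catalog and the
# extractors share the same name vectors, so catalog order and extracted
# vector order cannot drift apart.

feature_scales <- function() c("full", "0.5cm", "1.0cm")

fid <- function(group, family, names, scale = "full") {
  sprintf("%s.%s.%s@%s", group, family, names, scale)
}

catalog_rows <- function(group, family, names, scale = "full") {
  data.frame(feature_id = fid(group, family, names, scale),
             group = group, family = family, scale = scale,
             stringsAsFactors = FALSE)
}

#' The canonical catalog of all 470 texture features
#'
#' Deterministic enumeration of every feature the bank computes, with
#' group subtotals 76 (moment), 86 (form), 130 (statistical),
#' 108 (structural) and 70 (spectral). Only the GLCM, SDH, SGF and
#' run-length families carry the coarse 0.5 cm and 1.0 cm scales.
#'
#' @return data.frame with columns `feature_id`, `group`, `family`,
#'   `scale`, `ordinal` (1..470)
#' @export
feature_catalog <- function() {
  multiscale <- function(group, family, names)
    do.call(rbind, lapply(feature_scales(), function(s)
      catalog_rows(group, family, names, s)))
  cat <- rbind(
    # moment-based: 4 + 16 + 7 + 49 = 76
    catalog_rows("moment", "cm", c("mean", "variance", "skewness", "kurtosis")),
    catalog_rows("moment", "ncm", ncm_names()),
    catalog_rows("moment", "hu", paste0("phi", 1:7)),
    catalog_rows("moment", "zernike", zernike_names()),
    # form-based: 5 + 6 + 3 + 72 = 86
    catalog_rows("form", "shape", shape_scalar_names()),
    catalog_rows("form", "nrl", nrl_names()),
    catalog_rows("form", "fd", fd_names()),
    catalog_rows("form", "bm", c(ncm_names(), paste0("phi", 1:7), zernike_names())),
    # statistical: 16 + 3 x (13 + 25) = 130
    catalog_rows("stat", "hist", sprintf("bin%02d", 1:16)),
    multiscale("stat", "glcm", glcm_feature_names()),
    multiscale("stat", "sdh", sdh_feature_names()),
    # structural: 3 x (16 + 20) = 108
    multiscale("struct", "sgf", sgf_feature_names()),
    multiscale("struct", "rl", rl_feature_names()),
    # spectral: 7 x 10 = 70
    catalog_rows("spec", "wav", spectral_feature_names()))
  cat$ordinal <- seq_len(nrow(cat))
  rownames(cat) <- NULL
  cat
}

#' Downscale a masked image to a coarse physical resolution
#'
#' Non-overlapping square blocks of side `target_cm` (which must be a
#' whole number of pixels) are reduced to the mean gray value of their
#' masked pixels; blocks with less than 50% mask coverage are marked
#' invalid. The block means are re-quantized to 16 levels, yielding a
#' coarse `quantized_roi` for the multiscale GLCM/SDH/SGF/run-length
#' features.
#'
#' @param image a [gray_image()]
#' @param mask a [breast_mask()]
#' @param target_cm coarse block side in cm (0.5 or 1.0)
#' @param min_coverage minimum mask fraction for a block to be valid
#' @return a `quantized_roi` on the coarse grid
#' @export
downscale <- function(image, mask, target_cm, min_coverage = 0.5) {
  stopifnot(inherits(image, "gray_image"), inherits(mask, "breast_mask"))
  b <- target_cm / image$spacing
  if (abs(b - round(b)) > 1e-8)
    stop("target_cm / spacing must be a whole number of pixels")
  b <- as.integer(round(b))
  if (!any(mask$values)) stop("empty mask")
  nr2 <- nrow(image$values) %/% b
  nc2 <- ncol(image$values) %/% b
  if (nr2 < 1L || nc2 < 1L) stop("image smaller than one block")
  block_sum <- function(m) {
    m <- m[seq_len(nr2 * b), seq_len(nc2 * b), drop = FALSE]
    cs <- colSums(matrix(m, nrow = b))              # nr2 x (nc2*b), flattened
    m2 <- matrix(cs, nrow = nr2)                    # nr2 x (nc2*b)
    t(matrix(colSums(matrix(t(m2), nrow = b)), nrow = nc2))
  }
  gs <- block_sum(image$values * (mask$values * 1))
  cnt <- block_sum(mask$values * 1)
  valid <- cnt / b^2 >= min_coverage
  if (!any(valid)) stop("no valid blocks at ", target_cm, " cm")
  lev <- matrix(NA_integer_, nr2, nc2)
  lev[valid] <- pmin(as.integer(gs[valid] / cnt[valid]) %/% 16L, 15L)
  quantized_roi(lev, spacing = target_cm)
}

#' Extract the full 470-feature vector for one image + mask
#'
#' Evaluates all five feature families in canonical catalog order, with
#' the GLCM, SDH, SGF and run-length families computed at full resolution
#' and on the 0.5 cm and 1.0 cm block grids. The result is deterministic
#' and independent of anything outside the mask. Any non-finite feature is
#' an error naming the feature.
#'
#' @param image a [gray_image()]
#' @param mask a [breast_mask()]
#' @return named numeric vector of length 470 in catalog order
#' @export
extract_features <- function(image, mask) {
  stopifnot(inherits(image, "gray_image"), inherits(mask, "breast_mask"))
  q <- list(full = quantize(image, mask),
            `0.5cm` = downscale(image, mask, 0.5),
            `1.0cm` = downscale(image, mask, 1.0))
  per_scale <- function(fun) unlist(lapply(q, fun), use.names = FALSE)
  ncm <- normalized_central_moments16(image, mask)
  ct <- mask_contour(mask)
  bm <- binary_moment_features72(mask)
  vals <- c(
    central_moments4(image, mask), ncm, hu7(ncm), zernike49(image, mask),
    shape_scalars5(mask, image$spacing), radial_length_features6(ct),
    fourier_descriptor_features3(ct), bm,
    histogram_features(q$full),
    {
      so <- lapply(q, second_order_features)   # pairs enumerated once/scale
      c(unlist(lapply(so, function(x) x[seq_len(13)]), use.names = FALSE),
        unlist(lapply(so, function(x) x[13 + seq_len(25)]), use.names = FALSE))
    },
    per_scale(sgf16),
    per_scale(runlength_features20),
    spectral_features70(image, mask))
  cat <- feature_catalog()
  vals <- unname(vals)
  if (length(vals) != nrow(cat))
    stop("internal error: extracted ", length(vals), " values, expected ",
         nrow(cat))
  names(vals) <- cat$feature_id
  bad <- !is.finite(vals)
  if (any(bad))
    stop("non-finite feature value(s): ",
         paste(utils::head(names(vals)[bad], 5), collapse = ", "))
  vals
}

#' Extract the feature table for a whole cohort
#'
#' One row per subject, columns `subject_id` followed by the 470 features
#' in catalog order. Masks are taken from the cohort's ground truth or
#' re-delineated from the images.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()], or a list
#'   with elements `images` (list of `gray_image`) and `subjects`
#'   (data.frame with `subject_id`)
#' @param masks `"delineate"` (run [delineate_breast()] on each image) or
#'   `"truth"` (use the generator's ground-truth masks)
#' @param verbose print progress every 50 subjects
#' @return data.frame (`feature_table`): `subject_id` + 470 feature columns
#' @export
extract_cohort <- function(cohort, masks = c("delineate", "truth"),
                           verbose = FALSE) {
  masks <- match.arg(masks)
  n <- nrow(cohort$subjects)
  cat_ids <- feature_catalog()$feature_id
  out <- matrix(NA_real_, n, length(cat_ids),
                dimnames = list(NULL, cat_ids))
  for (i in seq_len(n)) {
    img <- cohort$images[[i]]
    if (is.null(img))
      img <- read_gray_png(cohort$subjects$image_path[i],
                           spacing = cohort$config$pixel_spacing)
    m <- if (masks == "truth") cohort$masks[[i]] else delineate_breast(img)
    out[i, ] <- extract_features(img, m)
    if (verbose && i %% 50L == 0L)
      message("extracted ", i, "/", n, " subjects")
  }
  ft <- data.frame(subject_id = cohort$subjects$subject_id, out,
                   check.names = FALSE, stringsAsFactors = FALSE)
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Write / read a feature table as CSV
#'
#' Header row of feature ids preceded by `subject_id`; one row per subject.
#'
#' @param ft a `feature_table`
#' @param path file path
#' @rdname feature-table-io
#' @export
write_feature_csv <- function(ft, path) {
  utils::write.csv(ft, path, row.names = FALSE)
  invisible(path)
}

#' @rdname feature-table-io
#' @export
read_feature_csv <- function(path) {
  ft <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(ft) <- c("feature_table", "data.frame")
  ft
}
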