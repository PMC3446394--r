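# First- and second-order statistical features: quantization, histogram,
# GLCM/Haralick and sum/difference histograms.

test_that("quantization uses the fixed floor(gray/16) map", {
  v <- matrix(c(0L, 15L, 16L, 255L), 2, 2)
  m <- breast_mask(matrix(TRUE, 2, 2))
  q <- quantize(gray_image(v, 0.02), m)
  expect_identical(q$levels, matrix(c(0L, 0L, 1L, 15L), 2, 2))
  # off-mask pixels are invalid
  m2 <- breast_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
  q2 <- quantize(gray_image(v, 0.02), m2)
  expect_true(is.na(q2$levels[2, 1]))
  # per-level counts equal a brute-force tally
  img <- rand_image(20, 20, seed = 4)
  mm <- breast_mask(matrix(TRUE, 20, 20))
  q3 <- quantize(img, mm)
  expect_identical(tabulate(q3$levels + 1L, 16),
                   tabulate(as.vector(img$values) %/% 16L + 1L, 16))
})

test_that("histogram features are relative frequencies summing to one", {
  lev0 <- matrix(0L, 4, 4)
  h <- histogram_features(roi_from_levels(lev0))
  expect_equal(unname(h), c(1, rep(0, 15)))
  # all 256 grays equally often: every bin 1/16
  v <- matrix(rep(0:255, 4), 32, 32)
  h2 <- histogram_features(quantize(gray_image(v, 0.02),
                                    breast_mask(matrix(TRUE, 32, 32))))
  expect_equal(unname(h2), rep(1 / 16, 16))
  # random ROI equals counting oracle
  roi <- rand_roi(14, 14, seed = 7)
  h3 <- histogram_features(roi)
  cnt <- tabulate(roi$levels[!is.na(roi$levels)] + 1L, 16)
  expect_equal(unname(h3), cnt / sum(cnt))
  expect_equal(sum(h3), 1)
})

test_that("GLCM accumulation is symmetric, normalized, and matches the oracle", {
  # hand-enumerated strip: levels 0,1,0,1 with offset (0,1)
  strip <- roi_from_levels(matrix(c(0L, 1L, 0L, 1L), 1, 4))
  g <- glcm_accumulate(strip, offsets = list(c(0L, 1L)))
  expect_equal(g$p[1, 2], 0.5)
  expect_equal(g$p[2, 1], 0.5)
  expect_equal(sum(g$p), 1)
  # constant ROI: single entry
  g2 <- glcm_accumulate(roi_from_levels(matrix(5L, 4, 4)))
  expect_equal(g2$p[6, 6], 1)
  # random masked ROIs equal the pair-enumeration oracle
  for (s in 1:6) {
    roi <- rand_roi(10, 10, seed = s)
    g3 <- glcm_accumulate(roi)
    expect_equal(g3$p, oracle_glcm(roi$levels, mammotex:::default_offsets()),
                 tolerance = 1e-12)
    expect_equal(g3$p, t(g3$p))
    expect_equal(sum(g3$p), 1, tolerance = 1e-12)
  }
  expect_error(glcm_accumulate(roi_from_levels(matrix(NA_integer_, 3, 3))),
               "pair")
})

test_that("the 13 co-occurrence features match closed forms and the oracle", {
  # constant ROI: ASM 1, entropy 0, contrast 0
  g <- glcm_accumulate(roi_from_levels(matrix(3L, 5, 5)))
  f <- suppressWarnings(haralick13(g))
  expect_equal(unname(f[c("asm", "entropy", "contrast")]), c(1, 0, 0))
  # two-level checkerboard: contrast = (delta level)^2
  chk <- roi_from_levels(outer(1:8, 1:8, function(i, j) ((i + j) %% 2L) * 4L))
  f2 <- haralick13(glcm_accumulate(chk, offsets = list(c(0L, 1L), c(1L, 0L))))
  expect_equal(unname(f2["contrast"]), 16)
  # random ROIs: all 13 match the literal-transcription oracle
  for (s in 1:5) {
    roi <- rand_roi(12, 12, seed = s + 20)
    g3 <- glcm_accumulate(roi)
    expect_equal(unname(haralick13(g3)), oracle_haralick(g3$p),
                 tolerance = 1e-9)
  }
})

test_that("degenerate GLCM returns correlation 0 with a warning", {
  g <- glcm_accumulate(roi_from_levels(matrix(3L, 4, 4)))
  expect_warning(f <- haralick13(g), "degenerate")
  expect_equal(unname(f["correlation"]), 0)
})

test_that("sum/difference histograms match the pair-enumeration oracle", {
  # constant ROI level l: sum mass at 2l, diff mass at 0
  h <- sdh_accumulate(roi_from_levels(matrix(4L, 4, 4)))
  expect_equal(h$sum_hist[9], 1)     # s = 8
  expect_equal(h$diff_hist[16], 1)   # d = 0
  for (s in 1:6) {
    roi <- rand_roi(10, 10, seed = s + 40)
    h2 <- sdh_accumulate(roi)
    orc <- oracle_sdh(roi$levels, mammotex:::default_offsets())
    expect_equal(h2$sum_hist, orc$sum_hist, tolerance = 1e-12)
    expect_equal(h2$diff_hist, orc$diff_hist, tolerance = 1e-12)
    expect_equal(sum(h2$sum_hist), 1, tolerance = 1e-12)
    expect_equal(sum(h2$diff_hist), 1, tolerance = 1e-12)
    # mean of sum histogram = 2 x mean level over paired pixels
    g <- glcm_accumulate(roi)
    mean_lvl <- sum((0:15) * rowSums(g$p))
    expect_equal(sum((0:30) * h2$sum_hist), 2 * mean_lvl, tolerance = 1e-12)
  }
})

test_that("the 25 SDH features include exact Haralick identities", {
  # constant ROI: difference of entropies = 0 (point mass)
  f <- sdh_features25(sdh_accumulate(roi_from_levels(matrix(7L, 4, 4))))
  expect_equal(unname(f["diff_entropy"]), 0)
  # checkerboard: difference-of-contrast closed form (delta level)^2
  chk <- roi_from_levels(outer(1:8, 1:8, function(i, j) ((i + j) %% 2L) * 4L))
  f2 <- sdh_features25(sdh_accumulate(chk, offsets = list(c(0L, 1L), c(1L, 0L))))
  expect_equal(unname(f2["u_contrast"]), 16)
  # cross-module identity: Unser contrast == Haralick contrast exactly
  for (s in 1:6) {
    roi <- rand_roi(11, 11, seed = s + 60)
    fh <- suppressWarnings(haralick13(glcm_accumulate(roi)))
    fs <- sdh_features25(sdh_accumulate(roi))
    expect_equal(unname(fs["u_contrast"]), unname(fh["contrast"]),
                 tolerance = 1e-9)
    expect_equal(unname(fs["u_sum_average"]), unname(fh["sum_average"]),
                 tolerance = 1e-9)
    expect_equal(unname(fs["u_sum_entropy"]), unname(fh["sum_entropy"]),
                 tolerance = 1e-9)
    expect_equal(unname(fs["u_diff_variance"]), unname(fh["diff_variance"]),
                 tolerance = 1e-9)
  }
  expect_length(f, 25)
})
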