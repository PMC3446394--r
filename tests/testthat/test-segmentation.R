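# Four-step breast delineation: stripe removal, Otsu threshold,
# morphological opening, largest connected component.

test_that("border stripe removal zeroes exactly the saturated bands", {
  img <- rand_image(60, 60, seed = 2)
  v <- img$values
  v[v >= 250L] <- 249L                      # no accidental near-white
  clean <- gray_image(v, img$spacing)
  # no near-white pixel: identity
  expect_identical(remove_border_stripes(clean)$values, clean$values)
  # stripe bands at two edges: exactly those rows/columns zeroed
  v2 <- v
  v2[, 1:2] <- 255L                          # left columns
  v2[58:60, ] <- 255L                        # bottom rows
  out <- remove_border_stripes(gray_image(v2, 0.02))$values
  # direct scan oracle
  expect_true(all(out[, 1:2] == 0L))
  expect_true(all(out[58:60, ] == 0L))
  expect_identical(out[1:57, 3:60], v[1:57, 3:60])
  # interior saturated block is untouched
  v3 <- v
  v3[20:30, 20:30] <- 255L
  expect_identical(remove_border_stripes(gray_image(v3, 0.02))$values, v3)
})

test_that("stripe margin parameter is validated", {
  img <- rand_image(20, 20)
  expect_error(remove_border_stripes(img, margin_frac = 0.5), "margin_frac")
})

test_that("Otsu threshold separates a two-point histogram exactly", {
  v <- matrix(c(rep(0L, 128), rep(200L, 128)), 16, 16)
  res <- otsu_threshold(gray_image(v, 0.02))
  expect_true(res$threshold >= 0 && res$threshold <= 199)
  expect_identical(res$binary, v > res$threshold)
  expect_identical(sum(res$binary), 128L)
})

test_that("Otsu threshold matches exhaustive minimization on random images", {
  for (s in 1:25) {
    img <- rand_image(16, 16, seed = s)
    res <- otsu_threshold(img)
    orc <- oracle_otsu(img$values)
    expect_equal(res$within_class_variance, orc$min_wcv, tolerance = 1e-10)
  }
})

test_that("Otsu errors on a constant image", {
  expect_error(otsu_threshold(gray_image(matrix(7L, 8, 8), 0.02)),
               "degenerate histogram")
})

test_that("opening removes small features and preserves large shapes", {
  m <- matrix(FALSE, 60, 60)
  m[30, 30] <- TRUE                          # isolated pixel
  expect_false(any(open_binary(m, 2)))
  m2 <- matrix(FALSE, 60, 60)
  m2[6:55, 6:55] <- TRUE                     # large square
  out <- open_binary(m2, 2)
  # a disk element rounds the four corners; everything else is preserved
  expect_true(all(out[8:53, 8:53]))
  expect_false(any(out & !m2))
  expect_gt(sum(out) / sum(m2), 0.995)
  # idempotence: opening an opened mask changes nothing
  expect_identical(open_binary(out, 2), out)
})

test_that("opening equals the brute-force min/max disk filter", {
  for (s in 1:4) {
    set.seed(s)
    m <- matrix(runif(24 * 24) < 0.55, 24, 24)
    for (r in c(1, 2)) {
      expect_identical(open_binary(m, r), oracle_opening(m, r))
    }
  }
})

test_that("opening never adds foreground", {
  set.seed(9)
  m <- matrix(runif(40 * 40) < 0.6, 40, 40)
  out <- open_binary(m, 3)
  expect_false(any(out & !m))
})

test_that("largest component keeps the maximal blob and respects connectivity", {
  m <- matrix(FALSE, 20, 20)
  m[2:7, 2:6] <- TRUE                        # area 30
  m[12:14, 12:14] <- TRUE                    # area 9 (gap > 1 px away)
  out <- largest_component(m)
  expect_identical(sum(out), 30L)
  expect_true(all(out[2:7, 2:6]))
  # single blob: identity
  expect_identical(largest_component(out), out)
  # diagonal touch: one component under 8-connectivity, two under 4
  d <- matrix(FALSE, 6, 6)
  d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_identical(sum(largest_component(d, 8)), 2L)
  expect_identical(sum(largest_component(d, 4)), 1L)
  expect_error(largest_component(matrix(FALSE, 4, 4)), "empty")
})

test_that("component labeling matches the flood-fill oracle", {
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(runif(15 * 15) < 0.45, 15, 15)
    for (conn in c(4L, 8L)) {
      lab <- mammotex:::cc_label_cpp(m * 1L, conn)
      orc <- oracle_label(m, conn)
      expect_identical(attr(lab, "n_components"), max(orc))
      # same partition (labels may be permuted)
      expect_identical(outer(lab[m], lab[m], "=="),
                       outer(orc[m], orc[m], "=="))
    }
  }
})

test_that("delineation is deterministic, excludes labels and stripes", {
  g <- test_gen_image(seed = 11)
  m1 <- delineate_breast(g$image)
  m2 <- delineate_breast(g$image)
  expect_identical(m1$values, m2$values)     # byte-identical
  expect_identical(m1$provenance, "automatic")
  # a synthetic film label far from the breast never enters the mask
  v <- g$image$values
  v[5:15, 110:125] <- 235L
  m3 <- delineate_breast(gray_image(v, g$image$spacing))
  expect_false(any(m3$values[5:15, 110:125]))
  # saturated stripe band contributes no mask pixels
  v[, 126:128] <- 255L
  m4 <- delineate_breast(gray_image(v, g$image$spacing))
  expect_false(any(m4$values[, 126:128]))
})

test_that("delineation recovers the generator ground truth (Dice)", {
  ds <- vapply(1:10, function(s) {
    g <- test_gen_image(seed = s, pmd = runif(1, 5, 45))
    dice(delineate_breast(g$image), g$mask)
  }, numeric(1))
  expect_gt(mean(ds), 0.95)
})
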