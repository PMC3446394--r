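# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures are stored.

# deterministic random gray image
rand_image <- function(nr = 16, nc = 16, seed = 1, spacing = 0.02) {
  set.seed(seed)
  gray_image(matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc),
             spacing = spacing)
}

# quantized ROI from an explicit level matrix (NA = off-mask)
roi_from_levels <- function(lev, spacing = 0.02) {
  mammotex:::quantized_roi(lev, spacing)
}

# random quantized ROI with a random mask
rand_roi <- function(nr = 12, nc = 12, seed = 1, mask_frac = 0.8) {
  set.seed(seed)
  lev <- matrix(sample(0:15, nr * nc, replace = TRUE), nr, nc)
  lev[matrix(runif(nr * nc) > mask_frac, nr, nc)] <- NA_integer_
  roi_from_levels(lev)
}

# filled disk mask of radius r in a square image
disk_mask <- function(r = 40, pad = 6) {
  n <- 2 * r + 2 * pad + 1
  ctr <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])

# small generator image used across tests (fast: 128x128 at 0.05 cm/px)
test_gen_image <- function(seed = 3, pmd = 20, ...) {
  generate_image(list(shape = c(128, 128), spacing = 0.05, pmd = pmd, ...),
                 seed = seed)
}
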