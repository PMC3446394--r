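# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use the most literal, slowest
# formulation of each definition (double loops, exhaustive search,
# flood fill) and share no code with the package internals.

# exhaustive Otsu: within-class variance for every candidate threshold
oracle_otsu <- function(v) {
  v <- as.vector(v)
  cand <- 0:254
  wcv <- vapply(cand, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) return(Inf)
    (length(lo) * mean((lo - mean(lo))^2) +
       length(hi) * mean((hi - mean(hi))^2)) / length(v)
  }, numeric(1))
  list(threshold = cand[which.min(wcv)], min_wcv = min(wcv))
}

# morphological opening = min-filter then max-filter over a disk
oracle_opening <- function(mask, r) {
  offs <- which(outer((-r):r, (-r):r, function(i, j) i^2 + j^2 <= r^2),
                arr.ind = TRUE) - (r + 1)
  nr <- nrow(mask); nc <- ncol(mask)
  filt <- function(m, f) {
    out <- matrix(NA, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      ii <- i + offs[, 1]; jj <- j + offs[, 2]
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      vals <- rep(0, nrow(offs))          # outside image = background
      vals[ok] <- m[cbind(ii[ok], jj[ok])]
      out[i, j] <- f(vals)
    }
    out
  }
  filt(filt(mask * 1, min), max) > 0.5
}

# connected components by queue-based flood fill
oracle_label <- function(mask, connectivity = 8) {
  nbr <- if (connectivity == 8)
    rbind(c(-1,-1),c(-1,0),c(-1,1),c(0,-1),c(0,1),c(1,-1),c(1,0),c(1,1))
  else rbind(c(-1,0),c(1,0),c(0,-1),c(0,1))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        q <- p + nbr[k, ]
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- nxt
          queue <- c(queue, list(q))
        }
      }
    }
  }
  lab
}

# GLCM by explicit pair enumeration (both orders)
oracle_glcm <- function(lev, offsets) {
  G <- 16L
  counts <- matrix(0, G, G)
  nr <- nrow(lev); nc <- ncol(lev)
  for (off in offsets) for (i in seq_len(nr)) for (j in seq_len(nc)) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
    a <- lev[i, j]; b <- lev[i2, j2]
    if (is.na(a) || is.na(b)) next
    counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
    counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
  }
  counts / sum(counts)
}

# sum/difference histograms by explicit pair enumeration
oracle_sdh <- function(lev, offsets) {
  sh <- numeric(31); dh <- numeric(31)
  nr <- nrow(lev); nc <- ncol(lev); n <- 0
  for (off in offsets) for (i in seq_len(nr)) for (j in seq_len(nc)) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
    a <- lev[i, j]; b <- lev[i2, j2]
    if (is.na(a) || is.na(b)) next
    sh[a + b + 1] <- sh[a + b + 1] + 2
    dh[a - b + 16] <- dh[a - b + 16] + 1
    dh[b - a + 16] <- dh[b - a + 16] + 1
    n <- n + 2
  }
  list(sum_hist = sh / n, diff_hist = dh / n)
}

# literal transcription of the 13 co-occurrence features, direct summation
oracle_haralick <- function(p) {
  G <- nrow(p)
  lg2 <- function(x) ifelse(x > 0, log2(x), 0)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((0:(G-1)) * px); muy <- sum((0:(G-1)) * py)
  sx <- sqrt(sum(((0:(G-1)) - mux)^2 * px)); sy <- sqrt(sum(((0:(G-1)) - muy)^2 * py))
  f <- numeric(13)
  for (i in 0:(G-1)) for (j in 0:(G-1)) {
    pij <- p[i+1, j+1]
    f[1] <- f[1] + pij^2
    f[2] <- f[2] + (i - j)^2 * pij
    if (sx > 0 && sy > 0) f[3] <- f[3] + (i * j * pij - mux * muy / G^2) / (sx * sy)
    f[4] <- f[4] + (i - mux)^2 * pij
    f[5] <- f[5] + pij / (1 + (i - j)^2)
    f[9] <- f[9] - pij * lg2(pij)
  }
  if (sx > 0 && sy > 0)
    f[3] <- (sum(outer(0:(G-1), 0:(G-1)) * p) - mux * muy) / (sx * sy)
  ps <- numeric(2 * G - 1)
  pdd <- numeric(G)
  for (i in 0:(G-1)) for (j in 0:(G-1)) {
    ps[i + j + 1] <- ps[i + j + 1] + p[i+1, j+1]
    pdd[abs(i - j) + 1] <- pdd[abs(i - j) + 1] + p[i+1, j+1]
  }
  f[6] <- sum((0:(2*G-2)) * ps)
  f[7] <- sum(((0:(2*G-2)) - f[6])^2 * ps)
  f[8] <- -sum(ps * lg2(ps))
  mud <- sum((0:(G-1)) * pdd)
  f[10] <- sum(((0:(G-1)) - mud)^2 * pdd)
  f[11] <- -sum(pdd * lg2(pdd))
  hx <- -sum(px * lg2(px)); hy <- -sum(py * lg2(py))
  hxy1 <- 0; hxy2 <- 0
  for (i in 0:(G-1)) for (j in 0:(G-1)) {
    q <- px[i+1] * py[j+1]
    hxy1 <- hxy1 - p[i+1, j+1] * lg2(q)
    hxy2 <- hxy2 - q * lg2(q)
  }
  f[12] <- if (max(hx, hy) > 0) (f[9] - hxy1) / max(hx, hy) else 0
  f[13] <- sqrt(1 - exp(-2 * max(hxy2 - f[9], 0)))
  f
}

# run-length matrix by per-line walking
oracle_runlength <- function(lev, direction) {
  nr <- nrow(lev); nc <- ncol(lev)
  step <- switch(as.character(direction),
                 "0" = c(0, 1), "90" = c(1, 0),
                 "45" = c(-1, 1), "135" = c(1, 1))
  starts <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    pr <- c(i, j) - step
    if (pr[1] < 1 || pr[1] > nr || pr[2] < 1 || pr[2] > nc)
      starts <- c(starts, list(c(i, j)))
  }
  runs <- list()
  for (s in starts) {
    pos <- s; cur <- NA; len <- 0
    while (pos[1] >= 1 && pos[1] <= nr && pos[2] >= 1 && pos[2] <= nc) {
      v <- lev[pos[1], pos[2]]
      if (!is.na(v) && !is.na(cur) && v == cur) len <- len + 1
      else {
        if (!is.na(cur)) runs <- c(runs, list(c(cur, len)))
        cur <- v; len <- 1
      }
      pos <- pos + step
    }
    if (!is.na(cur)) runs <- c(runs, list(c(cur, len)))
  }
  if (!length(runs)) return(matrix(0L, 16, 1))
  rm_ <- do.call(rbind, runs)
  m <- matrix(0L, 16, max(rm_[, 2]))
  for (k in seq_len(nrow(rm_)))
    m[rm_[k, 1] + 1, rm_[k, 2]] <- m[rm_[k, 1] + 1, rm_[k, 2]] + 1L
  m
}

# SGF by literal threshold/label/aggregate
oracle_sgf <- function(lev) {
  noc1 <- noc0 <- irgl1 <- irgl0 <- numeric(15)
  region_irr <- function(lab) {
    n <- max(lab)
    if (n == 0) return(0)
    tot <- 0; wsum <- 0
    for (l in seq_len(n)) {
      px <- which(lab == l, arr.ind = TRUE)
      A <- nrow(px)
      ctr <- colMeans(px)
      md <- sqrt(max((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2))
      irr <- max(sqrt(pi) * md / sqrt(A) - 1, 0)
      wsum <- wsum + A * irr; tot <- tot + A
    }
    wsum / tot
  }
  for (a in 1:15) {
    b1 <- !is.na(lev) & lev >= a
    b0 <- !is.na(lev) & lev < a
    l1 <- oracle_label(b1, 8); l0 <- oracle_label(b0, 8)
    noc1[a] <- max(l1); noc0[a] <- max(l0)
    irgl1[a] <- region_irr(l1); irgl0[a] <- region_irr(l0)
  }
  stats4 <- function(g) {
    tot <- sum(g)
    sm <- if (tot > 0) sum((1:15) * g) / tot else 0
    sd_ <- if (tot > 0) sqrt(sum(((1:15) - sm)^2 * g) / tot) else 0
    c(max(g), mean(g), sm, sd_)
  }
  c(stats4(noc1), stats4(noc0), stats4(irgl1), stats4(irgl0))
}

# AUC by all-pairs counting
oracle_auc <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls)
    s <- s + (x > y) + 0.5 * (x == y)
  s / (length(cases) * length(controls))
}
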