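# Brute-force reference implementations used as independent oracles.
# These favour transparency over speed and are only run on tiny inputs.

# Otsu by definition: try every unique value as the threshold, compute the
# between-class variance from explicit subsets, return the first maximizer.
oracle_otsu <- function(v) {
  v <- v[is.finite(v)]
  u <- sort(unique(v))
  if (length(u) < 2) return(NA_real_)
  cand <- u[-length(u)]
  bcv <- vapply(cand, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

# Set-operation morphology with a k x k box kernel. Matching the pipeline's
# conventions: erosion requires every in-image kernel position to be
# foreground (positions outside the image are ignored); dilation marks any
# pixel covered by the kernel placed on a foreground pixel.
oracle_erode <- function(m, k = 3) {
  r <- (k - 1) %/% 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- max(1, i - r):min(nrow(m), i + k - 1 - r)
    jj <- max(1, j - r):min(ncol(m), j + k - 1 - r)
    out[i, j] <- as.numeric(all(m[ii, jj] != 0))
  }
  out
}

oracle_dilate <- function(m, k = 3) {
  r <- (k - 1) %/% 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- max(1, i - r):min(nrow(m), i + k - 1 - r)
    jj <- max(1, j - r):min(ncol(m), j + k - 1 - r)
    out[i, j] <- as.numeric(any(m[ii, jj] != 0))
  }
  out
}

oracle_opening <- function(m, k = 3) oracle_dilate(oracle_erode(m, k), k)

# Fill holes: flood the background 4-connectedly from the image border;
# unreachable background becomes foreground.
oracle_fill_holes <- function(m) {
  bg <- m == 0
  reach <- matrix(FALSE, nrow(m), ncol(m))
  queue <- which(bg & (row(m) %in% c(1, nrow(m)) | col(m) %in% c(1, ncol(m))))
  reach[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    r <- (i - 1) %% nrow(m) + 1; c <- (i - 1) %/% nrow(m) + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m)) {
        j <- (cc - 1) * nrow(m) + rr
        if (bg[j] && !reach[j]) {
          reach[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  out <- (m != 0) | (bg & !reach)
  out * 1
}

# 4-connected labelling by flood fill.
oracle_label <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  for (start in which(m != 0)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      r <- (i - 1) %% nrow(m) + 1; c <- (i - 1) %/% nrow(m) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m)) {
          j <- (cc - 1) * nrow(m) + rr
          if (m[j] != 0 && lab[j] == 0L) {
            lab[j] <- nxt
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  lab
}

# Full segmentation reference on a single small frame: Otsu by enumeration,
# then opening / hole filling / labelling by direct set operations, then the
# minimum-area filter.
oracle_segment_frame <- function(frame, opening_kernel = 3, min_area = 1) {
  thr <- oracle_otsu(as.numeric(frame))
  if (is.na(thr)) return(matrix(0L, nrow(frame), ncol(frame)))
  bin <- oracle_fill_holes(oracle_opening((frame > thr) * 1, opening_kernel))
  lab <- oracle_label(bin)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas < min_area)
    lab[lab %in% drop] <- 0L
  }
  lab
}

# Naive median filter with the same even-window origin convention and
# replicate padding as the compiled implementation.
oracle_median_filter <- function(m, w) {
  br <- (w - 1) %/% 2
  ar <- w - 1 - br
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- pmin(pmax((i - br):(i + ar), 1), nrow(m))
    jj <- pmin(pmax((j - br):(j + ar), 1), ncol(m))
    out[i, j] <- median(m[ii, jj])
  }
  out
}

# Rasterize an axis-aligned (or rotated) ellipse: semi-axes a (cols), b
# (rows), rotation theta, on an n x n canvas; pixel centres inside count.
raster_ellipse <- function(a, b, theta = 0, n = NULL, ctr = NULL) {
  n <- n %||% (2 * ceiling(max(a, b)) + 11)
  ctr <- ctr %||% ((n + 1) / 2)
  xs <- seq_len(n) - ctr
  X <- outer(rep(1, n), xs) # column offsets
  Y <- outer(xs, rep(1, n)) # row offsets
  Xr <- X * cos(theta) + Y * sin(theta)
  Yr <- -X * sin(theta) + Y * cos(theta)
  ((Xr / a)^2 + (Yr / b)^2 <= 1) * 1
}

`%||%` <- function(x, y) if (is.null(x)) y else x

withr_local_tempfile <- function(fileext = ".tif") tempfile(fileext = fileext)

# Same-labelling comparison up to label permutation.
expect_same_labelling <- function(got, want) {
  expect_equal(got > 0, want > 0)
  expect_equal(max(got), max(want))
  if (max(want) > 0) {
    for (l in seq_len(max(want))) {
      px <- which(want == l)
      expect_length(unique(got[px]), 1)
    }
  }
}
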