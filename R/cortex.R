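#' Boundary pixels of a binary mask
#'
#' A boundary pixel is a foreground pixel with at least one background
#' 4-neighbour (image borders count as background).
#'
#' @param mask Binary matrix.
#' @return Logical matrix marking boundary pixels.
#' @export
boundary_pixels <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  inner <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  m & !inner
}

#' Fraction of the cell edge positive for a cortical signal
#'
#' Reconstruction of the "proportion of cell edge positive" measurement:
#' every boundary pixel of the cell mask is scored by the mean signal in the
#' inward band around it (band pixels — mask pixels within `band_width_um`
#' of the edge — lying within `band_width_um` of the boundary pixel), and is
#' positive when that mean exceeds a threshold. The default threshold is
#' Otsu's over all band pixels, which makes the fraction invariant to
#' rescaling the signal by a positive constant; an absolute threshold mode
#' is provided. If the band signal is constant no threshold exists and all
#' boundary pixels are positive when the constant is nonzero, none when it
#' is zero.
#'
#' @param mask Binary cell mask (matrix).
#' @param signal Signal image, same shape.
#' @param pixel_size_um Pixel size, um/px.
#' @param band_width_um Inward band width, um (default 1).
#' @param threshold `"otsu"` (default) or a single numeric absolute
#'   threshold.
#' @return A list: `fraction` in \[0, 1\], `n_boundary`, `threshold`.
#' @export
edge_positive_fraction <- function(mask, signal, pixel_size_um,
                                   band_width_um = 1, threshold = "otsu") {
  stopifnot(is.matrix(mask), is.matrix(signal),
            all(dim(mask) == dim(signal)), band_width_um > 0)
  if (!any(mask != 0)) stop("empty mask")
  band_px <- band_width_um / pixel_size_um
  D <- edge_distance_px(mask)
  if (max(D) <= band_px)
    warning("band is wider than the cell radius: the whole cell is edge band")
  band <- mask != 0 & D <= band_px
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(signal[band])
  } else {
    as.numeric(threshold)
  }
  bnd <- which(boundary_pixels(mask), arr.ind = TRUE)
  # disc of offsets of radius band_px around each boundary pixel
  rad <- ceiling(band_px)
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  off <- off[off$dr^2 + off$dc^2 <= band_px^2, ]
  nr <- nrow(mask); nc <- ncol(mask)
  pos <- logical(nrow(bnd))
  for (i in seq_len(nrow(bnd))) {
    rr <- bnd[i, 1] + off$dr; cc <- bnd[i, 2] + off$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    ii <- cbind(rr[ok], cc[ok])
    inband <- band[ii]
    if (!any(inband)) { pos[i] <- FALSE; next }
    mval <- mean(signal[ii][inband])
    pos[i] <- if (is.na(thr)) mval > 0 else mval > thr
  }
  list(fraction = mean(pos), n_boundary = nrow(bnd), threshold = thr)
}

# Euclidean distance (px) from each mask pixel to the nearest background
# pixel; 0 outside the mask.
edge_distance_px <- function(mask) {
  as.matrix(EBImage::imageData(EBImage::distmap((mask != 0) * 1)))
}

#' Intensity profile by distance from the cell edge
#'
#' Bins every mask pixel by its exact Euclidean distance to the cell edge
#' and reports the mean signal per bin up to `max_distance_um` — the
#' measurement behind "signal distribution within 15 um of the cell edge".
#' Bins are `[lo, hi)` from 0; a bin with no pixels (beyond the cell's
#' inradius) has an undefined mean (`NA`).
#'
#' @inheritParams edge_positive_fraction
#' @param max_distance_um Profile extent, um (default 15).
#' @param bin_width_um Bin width, um (default 1).
#' @param normalize If `TRUE`, divide bin means by the whole-cell mean
#'   signal.
#' @return A data frame of class `edge_profile`: `bin_lo_um, bin_hi_um,
#'   mean_intensity, n_pixels`.
#' @export
edge_distance_profile <- function(mask, signal, pixel_size_um,
                                  max_distance_um = 15, bin_width_um = 1,
                                  normalize = FALSE) {
  stopifnot(is.matrix(mask), is.matrix(signal),
            all(dim(mask) == dim(signal)))
  if (!any(mask != 0)) stop("empty mask")
  d_um <- edge_distance_px(mask) * pixel_size_um
  inside <- mask != 0
  edges <- seq(0, max_distance_um, by = bin_width_um)
  if (edges[length(edges)] < max_distance_um)
    edges <- c(edges, max_distance_um)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  sel <- inside & d_um <= max_distance_um
  bin <- findInterval(d_um[sel], edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(lo))
  sums <- rep(0, length(lo))
  agg <- tapply(signal[sel], bin, sum)
  sums[as.integer(names(agg))] <- as.numeric(agg)
  mean_int <- ifelse(counts > 0, sums / counts, NA_real_)
  if (normalize) mean_int <- mean_int / mean(signal[inside])
  structure(data.frame(bin_lo_um = lo, bin_hi_um = hi,
                       mean_intensity = mean_int, n_pixels = counts),
            class = c("edge_profile", "data.frame"))
}

#' Extract a kymograph along a line
#'
#' Samples intensity along a fixed line in every frame (bilinear
#' interpolation, averaged across `width` parallel lines) and stacks the
#' samples as rows: time runs down the image, position along the line runs
#' across. Protrusion-retraction cycles of the cell edge appear as an
#' oscillating boundary trace.
#'
#' @param movie A [movie_stack].
#' @param p0,p1 Line endpoints, 0-based `(row, col)` pixel coordinates.
#' @param width Averaging width perpendicular to the line, px (default 1).
#' @return A list of class `kymograph`: `mat` (time x position), `p0`, `p1`,
#'   `width`, `pixel_size_um`, `frame_interval_s`.
#' @export
make_kymograph <- function(movie, p0, p1, width = 1) {
  stopifnot(inherits(movie, "movie_stack"), length(p0) == 2L,
            length(p1) == 2L, width >= 1)
  d <- dim(movie$frames)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("line endpoints coincide")
  ns <- ceiling(len) + 1L
  tt <- seq(0, 1, length.out = ns)
  u <- (p1 - p0) / len
  nv <- c(-u[2], u[1])
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = max(width, 1))
  base_r <- p0[1] + tt * (p1[1] - p0[1])
  base_c <- p0[2] + tt * (p1[2] - p0[2])
  rs <- outer(base_r, offs * nv[1], "+") # ns x width
  cs <- outer(base_c, offs * nv[2], "+")
  if (any(rs < 0) || any(rs > d[2] - 1) || any(cs < 0) || any(cs > d[3] - 1))
    stop("sampling line (with width) extends outside the image")
  mat <- matrix(0, d[1], ns)
  for (f in seq_len(d[1])) {
    fr <- matrix(movie$frames[f, , ], d[2], d[3])
    vals <- bilinear_sample(fr, as.numeric(rs), as.numeric(cs))
    mat[f, ] <- rowMeans(matrix(vals, ns, length(offs)))
  }
  structure(list(mat = mat, p0 = p0, p1 = p1, width = width,
                 pixel_size_um = movie$pixel_size_um,
                 frame_interval_s = movie$frame_interval_s),
            class = "kymograph")
}

# Bilinear interpolation at 0-based continuous (r, c) positions.
bilinear_sample <- function(img, r, c) {
  r0 <- pmin(floor(r), nrow(img) - 2); c0 <- pmin(floor(c), ncol(img) - 2)
  r0 <- pmax(r0, 0); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1); i10 <- cbind(r0 + 2, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2); i11 <- cbind(r0 + 2, c0 + 2)
  img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d positions, width %d px\n",
              nrow(x$mat), ncol(x$mat), x$width))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(t(x$mat)[, nrow(x$mat):1],
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "position along line", ylab = "time", axes = FALSE,
                  ...)
  invisible(x)
}

#' Dominant protrusion-retraction period from a kymograph
#'
#' Extracts the cell-boundary position in each kymograph row (last
#' above-threshold sample along the line, refined to sub-pixel precision by
#' linear interpolation of the threshold crossing; Otsu threshold over the
#' whole kymograph), removes a linear drift, and looks for the first
#' positive-lag local maximum of the position autocorrelation that exceeds
#' the white-noise significance band `1.96/sqrt(n)`. Static or purely
#' drifting boundaries have no period and return `NULL`. Residual
#' oscillations smaller than `min_amplitude_px` (default 1 px, the
#' quantization scale) are ignored: a smooth sub-pixel drift otherwise
#' leaves a periodic pixel-rounding sawtooth that is an imaging artifact,
#' not a protrusion-retraction cycle.
#'
#' @param kym A [make_kymograph()] result.
#' @param min_amplitude_px Minimum residual standard deviation (px) for a
#'   detectable oscillation.
#' @return A list (`period_s`, `lag_frames`, `acf_peak`) or `NULL` when no
#'   periodicity is detected.
#' @export
protrusion_period <- function(kym, min_amplitude_px = 1) {
  stopifnot(inherits(kym, "kymograph"))
  m <- kym$mat
  if (nrow(m) < 16L) stop("need at least 16 frames")
  thr <- otsu_threshold(as.numeric(m))
  if (is.na(thr)) {
    warning("kymograph is constant: boundary undetectable")
    return(NULL)
  }
  pos <- apply(m, 1, function(row) {
    ab <- which(row > thr)
    if (length(ab) == 0L) return(NA_real_)
    i <- max(ab)
    if (i < length(row) && row[i] > row[i + 1]) {
      # sub-pixel crossing between the last above-threshold sample and next
      i + (row[i] - thr) / (row[i] - row[i + 1])
    } else {
      as.numeric(i)
    }
  })
  if (sum(is.finite(pos)) < 16L) {
    warning("boundary undetectable in most frames")
    return(NULL)
  }
  t_idx <- which(is.finite(pos))
  res <- stats::residuals(lm(pos[t_idx] ~ t_idx))
  if (sd(res) < min_amplitude_px) return(NULL) # static, drift or sub-pixel
  n <- length(res)
  a <- acf(res, lag.max = floor(n / 2), plot = FALSE)$acf[, 1, 1]
  band <- 1.96 / sqrt(n)
  # local maxima at positive lags (acf index 1 = lag 0)
  lag <- NA_integer_
  for (k in 2:(length(a) - 1)) {
    if (a[k] > a[k - 1] && a[k] >= a[k + 1] && a[k] > band) {
      lag <- k - 1L
      break
    }
  }
  if (is.na(lag)) return(NULL)
  list(period_s = lag * kym$frame_interval_s, lag_frames = lag,
       acf_peak = a[lag + 1])
}
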