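#' Moment-based ellipse fit of a binary region
#'
#' Fits the ellipse with the same normalized second central moments as the
#' foreground region — the classical "Fit Ellipse" construction. The aspect
#' ratio (AR), the ratio of the long over the short axis, is the shape
#' descriptor underlying the volatility statistic. When the mask contains
#' several connected components the largest (4-connected) one is used.
#'
#' @param x Binary matrix (nonzero = foreground), or an n x 2 matrix /
#'   data frame of polygon vertices `(row, col)` describing a closed outline,
#'   which is rasterized by even-odd scanline filling before fitting.
#' @return A list of class `ellipse_fit`: `centroid` (0-based `(row, col)`
#'   px), `major_axis` and `minor_axis` (full axis lengths, px),
#'   `orientation` (radians of the major axis from the column axis),
#'   `aspect_ratio` (>= 1) and `area_px` of the region.
#' @examples
#' m <- matrix(0, 64, 64)
#' m[outer((1:64 - 32)^2, (1:64 - 32)^2, "+") <= 20^2] <- 1
#' fit_ellipse(m)$aspect_ratio # ~1 for a disk
#' @export
fit_ellipse <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x) && ncol(x) == 2L && !all(x %in% c(0, 1))) {
    # two columns of non-binary numbers: a closed (row, col) outline
    if (nrow(x) < 3L) stop("a polygon outline needs at least 3 vertices")
    x <- rasterize_polygon(x)
  }
  if (!is.matrix(x)) stop("`x` must be a binary matrix or a polygon")
  lab <- EBImage::bwlabel(x != 0)
  nlab <- max(lab)
  if (nlab == 0L) stop("empty mask: no foreground pixels")
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which.max(areas)
  idx <- which(lab == keep, arr.ind = TRUE)
  if (nrow(idx) < 5L) stop("region too small for an ellipse fit (< 5 px)")
  r <- idx[, 1] - 1; c <- idx[, 2] - 1 # 0-based pixel coordinates
  mu_r <- mean(r); mu_c <- mean(c)
  # second central moments of the pixel-centre cloud
  m20 <- mean((c - mu_c)^2); m02 <- mean((r - mu_r)^2)
  m11 <- mean((c - mu_c) * (r - mu_r))
  common <- sqrt(pmax(0, ((m20 - m02) / 2)^2 + m11^2))
  l1 <- (m20 + m02) / 2 + common
  l2 <- (m20 + m02) / 2 - common
  if (l2 <= 1e-9) stop("degenerate region: zero minor axis")
  structure(list(
    centroid = c(row = mu_r, col = mu_c),
    major_axis = 4 * sqrt(l1), minor_axis = 4 * sqrt(l2),
    orientation = 0.5 * atan2(2 * m11, m20 - m02),
    aspect_ratio = sqrt(l1 / l2), area_px = nrow(idx)
  ), class = "ellipse_fit")
}

# Even-odd scanline rasterization of a closed polygon given as (row, col)
# vertices; returns a binary matrix covering the polygon bounding box.
rasterize_polygon <- function(v) {
  r <- v[, 1]; c <- v[, 2]
  nr <- ceiling(max(r)) + 2L; nc <- ceiling(max(c)) + 2L
  out <- matrix(0, nr, nc)
  n <- length(r)
  for (i in seq_len(nr)) {
    y <- i - 0.5
    xi <- numeric(0)
    j <- n
    for (k in seq_len(n)) {
      if ((r[k] > y) != (r[j] > y)) {
        xi <- c(xi, c[k] + (y - r[k]) / (r[j] - r[k]) * (c[j] - c[k]))
      }
      j <- k
    }
    xi <- sort(xi)
    if (length(xi) >= 2L) {
      for (k in seq(1L, length(xi) - 1L, by = 2L)) {
        cols <- which(seq_len(nc) - 0.5 >= xi[k] & seq_len(nc) - 0.5 <= xi[k + 1])
        out[i, cols] <- 1
      }
    }
  }
  out
}

#' Track the shape and position of a single cell through a mask movie
#'
#' Fits the moment-equivalent ellipse in every frame of a binary movie
#' (largest connected component per frame) and returns the aspect-ratio and
#' centroid time series in physical units — the substrate for
#' [shape_volatility()], [migration_speed()] and
#' [directional_persistence()].
#'
#' @param movie A binary [movie_stack] (`is_mask = TRUE`) containing one cell.
#' @param cell_id Identifier carried into result tables.
#' @return A `shape_track`: `times_h` (hours from 0), `aspect_ratio`,
#'   `x_um`/`y_um` (centroid, micrometres, x = column direction).
#' @export
track_shape <- function(movie, cell_id = "cell1") {
  stopifnot(inherits(movie, "movie_stack"))
  if (!movie$is_mask) stop("`movie` must be a mask movie (is_mask = TRUE)")
  nt <- n_frames(movie)
  ar <- numeric(nt); xr <- numeric(nt); yr <- numeric(nt)
  for (i in seq_len(nt)) {
    f <- tryCatch(fit_ellipse(get_frame(movie, i)), error = function(e)
      stop("frame ", i, ": ", conditionMessage(e)))
    ar[i] <- f$aspect_ratio
    xr[i] <- f$centroid[["col"]] * movie$pixel_size_um
    yr[i] <- f$centroid[["row"]] * movie$pixel_size_um
  }
  shape_track(cell_id, (seq_len(nt) - 1) * movie$frame_interval_s / 3600,
              ar, xr, yr)
}

#' Construct a shape track
#'
#' @param cell_id Cell identifier.
#' @param times_h Strictly increasing sample times, hours.
#' @param aspect_ratio Aspect ratios (>= 1), one per time point.
#' @param x_um,y_um Centroid coordinates, micrometres.
#' @return An object of class `shape_track`.
#' @export
shape_track <- function(cell_id, times_h, aspect_ratio, x_um, y_um) {
  n <- length(times_h)
  if (length(aspect_ratio) != n || length(x_um) != n || length(y_um) != n)
    stop("all shape_track fields must share one length")
  if (n < 1L) stop("empty track")
  if (any(diff(times_h) <= 0)) stop("`times_h` must be strictly increasing")
  if (any(aspect_ratio < 1 - 1e-9))
    stop("aspect ratios must be >= 1")
  structure(list(cell_id = cell_id, times_h = times_h,
                 aspect_ratio = aspect_ratio, x_um = x_um, y_um = y_um),
            class = "shape_track")
}

#' @export
print.shape_track <- function(x, ...) {
  cat(sprintf("shape_track '%s': %d samples over %.2f h, AR %.2f..%.2f\n",
              x$cell_id, length(x$times_h), diff(range(x$times_h)),
              min(x$aspect_ratio), max(x$aspect_ratio)))
  invisible(x)
}

#' @export
as.data.frame.shape_track <- function(x, ...) {
  data.frame(cell_id = x$cell_id, time_h = x$times_h,
             aspect_ratio = x$aspect_ratio,
             centroid_x_um = x$x_um, centroid_y_um = x$y_um)
}

#' Shape volatility: the standard deviation of relative AR changes
#'
#' The shape change over one sampling interval is the relative aspect-ratio
#' increment `dAR_n = AR_n / AR_(n-1) - 1`, a construction adapted from the
#' volatility measure of finance; the shape volatility of a cell is the
#' sample standard deviation (n-1 denominator) of those hourly changes over
#' the whole experiment. The statistic is scale-free: multiplying the AR
#' series by any positive constant leaves it unchanged.
#'
#' @param track A [shape_track], or a plain numeric AR series (then
#'   `sampling_interval_h` is taken in samples of that series).
#' @param sampling_interval_h Interval between the samples entering the
#'   difference, hours; must be an integer multiple of the track's frame
#'   spacing. The default 1 h takes every second frame of a
#'   2-frames-per-hour movie.
#' @return A list of class `volatility_result`: `delta_ar`, `sigma_ar`,
#'   `sampling_interval_h`, `n_intervals`.
#' @examples
#' shape_volatility(c(1, 2, 1, 2), sampling_interval_h = 1)$sigma_ar # 0.866
#' @export
shape_volatility <- function(track, sampling_interval_h = 1) {
  if (inherits(track, "shape_track")) {
    ar <- track$aspect_ratio
    dt <- diff(track$times_h)
    if (diff(range(dt)) > 1e-8 * mean(dt))
      stop("track must be regularly sampled")
    step <- sampling_interval_h / dt[1]
  } else {
    ar <- as.numeric(track)
    step <- sampling_interval_h
  }
  if (abs(step - round(step)) > 1e-6 || round(step) < 1)
    stop("`sampling_interval_h` must be a positive integer multiple of the frame spacing")
  step <- as.integer(round(step))
  if (any(!is.finite(ar)) || any(ar <= 0))
    stop("aspect ratios must be positive and finite")
  sub <- ar[seq(1L, length(ar), by = step)]
  if (length(sub) < 3L)
    stop("need at least 3 samples at the requested interval")
  delta <- sub[-1] / sub[-length(sub)] - 1
  structure(list(delta_ar = delta, sigma_ar = sd(delta),
                 sampling_interval_h = sampling_interval_h,
                 n_intervals = length(delta)),
            class = "volatility_result")
}

#' @export
print.volatility_result <- function(x, ...) {
  cat(sprintf("shape volatility sigma_AR = %.4f over %d intervals of %.3g h\n",
              x$sigma_ar, x$n_intervals, x$sampling_interval_h))
  invisible(x)
}

#' Migration speed of a cell
#'
#' Total path length of the centroid polyline divided by elapsed time —
#' the speed obtained by tracing the geometric centre of the cell through
#' the movie.
#'
#' @param track A [shape_track].
#' @return Speed in micrometres per hour.
#' @export
migration_speed <- function(track) {
  xy <- track_xy(track)
  if (nrow(xy) < 2L) stop("need at least 2 centroid samples")
  el <- if (inherits(track, "shape_track"))
    diff(range(track$times_h)) else nrow(xy) - 1
  if (el <= 0) stop("zero elapsed time")
  sum(sqrt(rowSums(diff(xy)^2))) / el
}

#' Directional persistence of a migration track
#'
#' Net displacement divided by total path length: 1 for a straight monotone
#' path, 0 for a closed loop. A zero-length path has no defined direction
#' and yields `NA` with a warning rather than a silent 0.
#'
#' @param track A [shape_track], or an n x 2 matrix of `(x, y)` positions.
#' @return Persistence in \[0, 1\], or `NA` for a degenerate track.
#' @export
directional_persistence <- function(track) {
  xy <- track_xy(track)
  if (nrow(xy) < 2L) stop("need at least 2 positions")
  path <- sum(sqrt(rowSums(diff(xy)^2)))
  if (path == 0) {
    warning("zero path length: persistence undefined")
    return(NA_real_)
  }
  net <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  net / path
}

track_xy <- function(track) {
  if (inherits(track, "shape_track")) {
    cbind(track$x_um, track$y_um)
  } else {
    xy <- as.matrix(track)
    if (ncol(xy) != 2L) stop("positions must be an n x 2 matrix")
    xy
  }
}

#' Rayleigh test of directional uniformity
#'
#' Tests whether a set of angles (e.g. chemotaxis endpoint directions) is
#' uniformly distributed on the circle. The mean resultant length
#' `Rbar = |mean(exp(i theta))|` gives the statistic `Z = n Rbar^2`; the
#' p-value uses Zar's finite-n correction
#' `p = exp(sqrt(1 + 4n + 4(n^2 - nZ)) - (1 + 2n))`, clamped to (0, 1],
#' which behaves better at small n than the asymptotic `exp(-Z)` (also
#' reported).
#'
#' @param angles Numeric vector of angles in radians, `n >= 3`.
#' @return A list of class `rayleigh_test`: `n`, `R_bar`, `Z`, `p_value`
#'   (Zar correction), `p_asymptotic`, `mean_direction` (radians).
#' @export
rayleigh_test <- function(angles) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 3L) stop("need at least 3 finite angles")
  C <- mean(cos(angles)); S <- mean(sin(angles))
  R <- sqrt(C^2 + S^2)
  Z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - n * Z)) - (1 + 2 * n))
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(n = n, R_bar = R, Z = Z, p_value = p,
                 p_asymptotic = min(max(exp(-Z), .Machine$double.xmin), 1),
                 mean_direction = atan2(S, C)),
            class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf(
    "Rayleigh test: n = %d, Rbar = %.3f, Z = %.3f, p = %.4g (mean dir %.1f deg)\n",
    x$n, x$R_bar, x$Z, x$p_value, x$mean_direction * 180 / pi))
  invisible(x)
}

#' Correlation between shape volatility and migration speed
#'
#' Correlates per-cell volatility (`sigma_ar`) with migration speed across a
#' cohort, the analysis that links morphological fluctuation to motility.
#' Pearson correlation is the default; Spearman is available for
#' nonparametric comparison.
#'
#' @param cohort Data frame with columns `sigma_ar` and `speed_um_per_h`
#'   (one row per cell).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list: `r`, `p_value`, `n`, `method`.
#' @export
volatility_speed_correlation <- function(cohort,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(all(c("sigma_ar", "speed_um_per_h") %in% names(cohort)))
  d <- cohort[complete.cases(cohort[c("sigma_ar", "speed_um_per_h")]), ]
  if (nrow(d) < 3L) stop("need at least 3 cells")
  if (var(d$sigma_ar) == 0 || var(d$speed_um_per_h) == 0)
    stop("correlation undefined: a column is constant")
  ct <- cor.test(d$sigma_ar, d$speed_um_per_h, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(d),
       method = method)
}
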