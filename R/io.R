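#' Construct a movie stack
#'
#' A `movie_stack` holds a time-lapse microscopy movie as a 3-D numeric array
#' indexed `[frame, row, col]`, together with the acquisition metadata needed
#' to report physical quantities: the pixel size in micrometres and the frame
#' interval in seconds. Shape movies are typically acquired at 2 frames per
#' hour over 18 h; TIRF focal-adhesion movies at 30-s intervals over 61
#' frames.
#'
#' @param frames 3-D numeric array `[t, row, col]` with `t >= 1`, or a list of
#'   equally sized matrices (one per frame).
#' @param pixel_size_um Pixel size, micrometres per pixel (> 0).
#' @param frame_interval_s Time between frames, seconds (> 0).
#' @param is_mask Logical; `TRUE` for binary cell/adhesion masks. Nonzero
#'   values are coerced to 1.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size_um, frame_interval_s,
                        is_mask = FALSE) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(frames) == 0L) stop("movie must contain at least one frame")
    if (length(dims) != 1L || length(dims[[1]]) != 2L)
      stop("all frames must be matrices sharing one shape")
    arr <- array(0, dim = c(length(frames), dims[[1]]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array [t, row, col]")
  if (dim(frames)[1] < 1L) stop("movie must contain at least one frame")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      !is.finite(frame_interval_s) || frame_interval_s <= 0)
    stop("`frame_interval_s` must be a single positive number")
  if (isTRUE(is_mask)) {
    frames <- (frames != 0) * 1
  }
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s, is_mask = isTRUE(is_mask)),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "movie_stack: %d frame(s) of %d x %d px (%s)\n  %.4g um/px, %.4g s/frame\n",
    d[1], d[2], d[3], if (x$is_mask) "binary mask" else "intensity",
    x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie A [movie_stack].
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[1]

#' Extract one frame of a movie as a matrix
#' @param movie A [movie_stack].
#' @param i Frame index (1-based).
#' @return Numeric matrix `[row, col]`.
#' @export
get_frame <- function(movie, i) {
  d <- dim(movie$frames)
  if (i < 1L || i > d[1]) stop("frame index out of range")
  matrix(movie$frames[i, , ], d[2], d[3])
}

#' Read a multi-page TIFF movie
#'
#' Reads a multi-page TIFF into a [movie_stack]. All pages must share one
#' shape. Values are read as stored (no 0-1 rescaling), so integer movies
#' written by [write_movie()] round-trip bit-exactly. With `as_mask = TRUE`
#' every nonzero pixel becomes 1.
#'
#' @param path Path to a multi-page TIFF file.
#' @inheritParams movie_stack
#' @param as_mask Coerce to a binary mask by a nonzero test.
#' @return A [movie_stack].
#' @export
read_movie <- function(path, pixel_size_um, frame_interval_s,
                       as_mask = FALSE) {
  if (!file.exists(path)) stop("cannot read movie: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # drop extra channels
    p
  })
  if (length(unique(lapply(pages, dim))) != 1L)
    stop("inconsistent frame shapes in ", path)
  movie_stack(pages, pixel_size_um, frame_interval_s, is_mask = as_mask)
}

#' Write a movie to a multi-page TIFF
#'
#' Movies are stored as unsigned integer TIFF (8-bit for masks, 16-bit
#' otherwise), the native container for camera counts. Integer-valued frames
#' in range round-trip bit-exactly through [read_movie()]; non-integer values
#' are rounded to the nearest count with a warning.
#'
#' @param movie A [movie_stack].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  bits <- if (movie$is_mask) 8L else 16L
  top <- 2^bits - 1
  vals <- movie$frames
  if (any(vals < 0) || any(vals > top))
    stop("movie values outside the storable range [0, ", top, "]")
  if (any(vals != round(vals))) {
    warning("non-integer movie values rounded to the nearest count")
    vals <- round(vals)
  }
  pages <- lapply(seq_len(dim(vals)[1]), function(i)
    matrix(vals[i, , ] / top, dim(vals)[2], dim(vals)[3]))
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = bits,
                        compression = "deflate")
  if (!ok) stop("failed to write TIFF: ", path)
  invisible(path)
}

#' Construct an AFM force curve
#'
#' A calibrated approach force curve: force (nN) versus piezo z position
#' (micrometres, increasing toward the sample) together with the probe
#' parameters used by the Sneddon conical-indenter model. Defaults follow a
#' soft silicon-nitride probe (nominal spring constant 0.06 N/m, half-angle
#' 18 degrees) on cells, analysed at a 1.5 nN trigger force with Poisson
#' ratio 0.5.
#'
#' @param z_um Piezo z positions, micrometres; sorted ascending internally.
#' @param force_nN Force samples, nanonewtons, same length as `z_um`.
#' @param spring_constant Cantilever spring constant, N/m (> 0).
#' @param half_angle_deg Tip half-opening angle, degrees, in (0, 90).
#' @param poisson_ratio Sample Poisson ratio, in \[0, 0.5\].
#' @param trigger_nN Trigger force, nN; the default fit domain ends here.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z_um, force_nN, spring_constant = 0.06,
                        half_angle_deg = 18, poisson_ratio = 0.5,
                        trigger_nN = 1.5) {
  if (length(z_um) != length(force_nN))
    stop("`z_um` and `force_nN` must have equal length")
  ok <- is.finite(z_um) & is.finite(force_nN)
  z_um <- z_um[ok]; force_nN <- force_nN[ok]
  if (length(z_um) < 10L) stop("a force curve needs at least 10 samples")
  if (!is.finite(spring_constant) || spring_constant <= 0)
    stop("`spring_constant` must be positive")
  if (!is.finite(half_angle_deg) || half_angle_deg <= 0 || half_angle_deg >= 90)
    stop("`half_angle_deg` must lie in (0, 90)")
  if (!is.finite(poisson_ratio) || poisson_ratio < 0 || poisson_ratio > 0.5)
    stop("`poisson_ratio` must lie in [0, 0.5]")
  o <- order(z_um)
  structure(
    list(z_um = z_um[o], force_nN = force_nN[o],
         spring_constant = spring_constant, half_angle_deg = half_angle_deg,
         poisson_ratio = poisson_ratio, trigger_nN = trigger_nN),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "force_curve: %d samples, z %.3g..%.3g um, F up to %.3g nN\n  k = %.3g N/m, half-angle %.3g deg, nu = %.2f, trigger %.3g nN\n",
    length(x$z_um), min(x$z_um), max(x$z_um), max(x$force_nN),
    x$spring_constant, x$half_angle_deg, x$poisson_ratio, x$trigger_nN))
  invisible(x)
}

#' Read an AFM force curve from a two-column text file
#'
#' Expects two numeric columns: z position (micrometres) and raw deflection
#' signal. The force is `spring_constant * deflection_sensitivity * signal`,
#' the standard optical-lever calibration; pass `deflection_sensitivity = 1`
#' when the second column is already force in nN. Comma-, tab- and
#' whitespace-separated files with or without a header row are accepted.
#'
#' @param path Path to the file.
#' @param deflection_sensitivity Calibration factor converting the raw
#'   deflection signal to tip deflection such that the product with
#'   `spring_constant` yields nN.
#' @inheritParams force_curve
#' @param ... Passed to [force_curve()] (probe parameters).
#' @return A [force_curve].
#' @export
read_force_curve <- function(path, spring_constant = 0.06,
                             deflection_sensitivity = 1, ...) {
  if (!file.exists(path)) stop("cannot read force curve: no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  hdr <- is.na(suppressWarnings(as.numeric(strsplit(
    first, if (sep == ",") "," else "[[:space:]]+")[[1]][1])))
  d <- read.table(path, sep = sep, header = hdr,
                  stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("force-curve file must have two columns")
  z <- suppressWarnings(as.numeric(d[[1]]))
  s <- suppressWarnings(as.numeric(d[[2]]))
  if (anyNA(z) || anyNA(s)) stop("non-numeric rows in force-curve file")
  if (length(z) < 10L) stop("a force curve needs at least 10 samples")
  force_curve(z, spring_constant * deflection_sensitivity * s,
              spring_constant = spring_constant, ...)
}
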