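#' Otsu threshold of a numeric sample
#'
#' Returns the threshold maximizing the between-class variance over all
#' candidate cut points (the exact empirical histogram, not a binned
#' approximation). Foreground is defined as values strictly greater than the
#' returned threshold; ties in the criterion resolve to the smallest
#' threshold. Returns `NA` for a constant sample, where no threshold is
#' defined.
#'
#' @param v Numeric vector (non-finite values dropped).
#' @return The threshold value, or `NA_real_`.
#' @export
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  u <- sort(unique(v))
  if (length(u) < 2L) return(NA_real_)
  vs <- sort(v)
  n <- length(vs)
  cs <- cumsum(vs)
  # last index of each unique value; thresholds at all but the largest value
  idx <- cumsum(tabulate(match(vs, u), nbins = length(u)))
  idx <- idx[-length(u)]
  w1 <- as.numeric(idx); w2 <- as.numeric(n - idx)
  m1 <- cs[idx] / w1; m2 <- (cs[n] - cs[idx]) / w2
  bcv <- w1 * w2 * (m1 - m2)^2
  u[which.max(bcv)]
}

#' Apply the TIRF preprocessing median filter to one frame
#'
#' Square-window 2-D running median with replicate padding. The published
#' pipeline uses a 10-pixel window; even windows are applied as stated, with
#' the window spanning `floor((w-1)/2)` pixels before and the remainder after
#' the centre pixel (a half-pixel shift toward larger indices). Pass an odd
#' window (e.g. 11) for a symmetric filter.
#'
#' @param frame Numeric matrix.
#' @param window Window side length, px.
#' @return Filtered matrix of the same size.
#' @export
median_filter <- function(frame, window = 10) {
  stopifnot(is.matrix(frame), window >= 1)
  median_filter_cpp(frame, as.integer(window), as.integer(window))
}

#' Segment focal adhesions in a TIRF movie
#'
#' Reimplements the standard adhesion segmentation pipeline: each frame is
#' median filtered (square window), thresholded by Otsu's criterion, cleaned
#' by binary opening with a square kernel, hole-filled, and labelled
#' (4-connected components); segments below `min_area` are discarded.
#' Integrated intensities are measured on the unfiltered frames.
#'
#' By default one global Otsu threshold is computed from the filtered time
#' series and applied to every frame, so a truly constant adhesion keeps an
#' exactly constant segmented area; with `global_threshold = FALSE` the
#' threshold is recomputed per frame, which tracks slow illumination drift
#' but lets the threshold — and hence every segment boundary — shift as
#' other adhesions brighten or fade.
#'
#' @param movie An intensity [movie_stack].
#' @param median_window Median-filter window, px (default 10).
#' @param opening_kernel Opening kernel side, px (default 3).
#' @param min_area Minimum segment area, px^2 (default 4).
#' @param global_threshold If `TRUE` (default) compute one Otsu threshold
#'   from all filtered frames; if `FALSE`, per frame.
#' @return An object of class `fa_segmentation`: `labels` (integer array
#'   `[t, row, col]`), `stats` (data frame `frame, label, area_px2,
#'   intensity, centroid_row, centroid_col` with 0-based px centroids) and
#'   the parameters used.
#' @export
segment_adhesions <- function(movie, median_window = 10, opening_kernel = 3,
                              min_area = 4, global_threshold = TRUE) {
  stopifnot(inherits(movie, "movie_stack"))
  nt <- n_frames(movie)
  d <- dim(movie$frames)
  filt <- vector("list", nt)
  for (i in seq_len(nt))
    filt[[i]] <- median_filter(get_frame(movie, i), median_window)
  gthr <- if (global_threshold) otsu_threshold(unlist(filt)) else NA_real_
  kern <- matrix(1, opening_kernel, opening_kernel)
  labels <- array(0L, dim = d)
  stats <- vector("list", nt)
  for (i in seq_len(nt)) {
    thr <- if (global_threshold) gthr else otsu_threshold(filt[[i]])
    if (is.na(thr)) {
      warning("frame ", i, " is constant: threshold undefined, 0 segments")
      stats[[i]] <- empty_fa_stats()
      next
    }
    bin <- (filt[[i]] > thr) * 1
    bin <- EBImage::fillHull(EBImage::opening(bin, kern))
    lab <- EBImage::bwlabel(bin)
    lab <- as.matrix(EBImage::imageData(lab))
    stats[[i]] <- relabel_and_measure(lab, get_frame(movie, i), min_area, i)
    labels[i, , ] <- attr(stats[[i]], "labels")
    attr(stats[[i]], "labels") <- NULL
  }
  structure(list(labels = labels, stats = do.call(rbind, stats),
                 params = list(median_window = median_window,
                               opening_kernel = opening_kernel,
                               min_area = min_area,
                               global_threshold = global_threshold),
                 pixel_size_um = movie$pixel_size_um,
                 frame_interval_s = movie$frame_interval_s),
            class = "fa_segmentation")
}

empty_fa_stats <- function() {
  data.frame(frame = integer(0), label = integer(0), area_px2 = numeric(0),
             intensity = numeric(0), centroid_row = numeric(0),
             centroid_col = numeric(0))
}

relabel_and_measure <- function(lab, raw, min_area, frame_i) {
  nlab <- max(lab)
  if (nlab == 0L) {
    out <- empty_fa_stats()
    attr(out, "labels") <- lab
    return(out)
  }
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(areas >= min_area)
  new <- integer(nlab)
  new[keep] <- seq_along(keep)
  relab <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0
  relab[pos] <- new[lab[pos]]
  if (length(keep) == 0L) {
    out <- empty_fa_stats()
    attr(out, "labels") <- relab
    return(out)
  }
  idx <- which(relab > 0, arr.ind = TRUE)
  lv <- relab[relab > 0]
  out <- data.frame(
    frame = frame_i, label = seq_along(keep), area_px2 = areas[keep],
    intensity = as.numeric(tapply(raw[relab > 0], lv, sum)),
    centroid_row = as.numeric(tapply(idx[, 1] - 1, lv, mean)),
    centroid_col = as.numeric(tapply(idx[, 2] - 1, lv, mean)))
  attr(out, "labels") <- relab
  out
}

#' @export
print.fa_segmentation <- function(x, ...) {
  cat(sprintf(
    "fa_segmentation: %d frame(s), %d segment observation(s), median window %d px, opening %d px, min area %d px^2\n",
    dim(x$labels)[1], nrow(x$stats), x$params$median_window,
    x$params$opening_kernel, x$params$min_area))
  invisible(x)
}

#' Count adhesions in one frame
#'
#' @param seg An [fa_segmentation].
#' @param frame Frame index (1-based).
#' @return Number of segments of at least `min_area` in that frame.
#' @export
count_adhesions <- function(seg, frame) {
  stopifnot(inherits(seg, "fa_segmentation"))
  if (frame < 1L || frame > dim(seg$labels)[1]) stop("frame index out of range")
  sum(seg$stats$frame == frame)
}

#' Link adhesion segments into tracks across frames
#'
#' Segments in consecutive frames are linked when their pixel overlap
#' reaches `iou_threshold`; among competing candidates the largest overlap
#' wins, ties broken by larger segment area and then lower label. No gap
#' closing and no split/merge handling: an unmatched segment ends its
#' track, a segment with no predecessor starts a new one — the simplest
#' rule consistent with dense 30-s TIRF sampling.
#'
#' The default `criterion = "overlap"` measures overlap relative to the
#' smaller of the two segments, the convention of focal-adhesion tracking
#' tools: an adhesion's first detected patch is much smaller than its grown
#' successor, so intersection-over-union (`criterion = "iou"`) severs the
#' birth and death frames of growing adhesions into spurious one-frame
#' tracks while the smaller-segment overlap links them.
#'
#' @param seg An [fa_segmentation].
#' @param iou_threshold Minimum overlap to accept a link (default 0.3).
#' @param criterion `"overlap"` (intersection over the smaller segment,
#'   default) or `"iou"` (intersection over union).
#' @return A list of `fa_track` objects, each with `track_id`, `frames`
#'   (consecutive), `area_px2`, `intensity`, `first_frame`, `last_frame`.
#' @export
link_tracks <- function(seg, iou_threshold = 0.3,
                        criterion = c("overlap", "iou")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(seg, "fa_segmentation"))
  nt <- dim(seg$labels)[1]
  st <- seg$stats
  # track id carried per (frame, label)
  track_of <- vector("list", nt)
  next_id <- 0L
  tracks <- list()
  add_obs <- function(id, frame, label) {
    row <- st[st$frame == frame & st$label == label, ]
    tr <- tracks[[id]]
    tr$frames <- c(tr$frames, frame)
    tr$area_px2 <- c(tr$area_px2, row$area_px2)
    tr$intensity <- c(tr$intensity, row$intensity)
    tracks[[id]] <<- tr
  }
  start_track <- function(frame, label) {
    next_id <<- next_id + 1L
    tracks[[next_id]] <<- list(track_id = next_id, frames = integer(0),
                               area_px2 = numeric(0), intensity = numeric(0))
    add_obs(next_id, frame, label)
    next_id
  }
  labs1 <- st$label[st$frame == 1L]
  track_of[[1L]] <- setNames(vapply(labs1, function(l) start_track(1L, l),
                                    integer(1)), labs1)
  for (f in seq_len(nt - 1L)) {
    A <- matrix(seg$labels[f, , ], dim(seg$labels)[2], dim(seg$labels)[3])
    B <- matrix(seg$labels[f + 1L, , ], dim(seg$labels)[2], dim(seg$labels)[3])
    labsB <- st$label[st$frame == f + 1L]
    assigned <- setNames(rep(NA_integer_, length(labsB)), labsB)
    both <- A > 0 & B > 0
    if (any(both)) {
      ov <- table(A = A[both], B = B[both])
      areaA <- setNames(st$area_px2[st$frame == f], st$label[st$frame == f])
      areaB <- setNames(st$area_px2[st$frame == f + 1L], labsB)
      cand <- which(ov > 0, arr.ind = TRUE)
      if (nrow(cand)) {
        la <- as.integer(rownames(ov))[cand[, 1]]
        lb <- as.integer(colnames(ov))[cand[, 2]]
        inter <- ov[cand]
        denom <- if (criterion == "iou") {
          areaA[as.character(la)] + areaB[as.character(lb)] - inter
        } else {
          pmin(areaA[as.character(la)], areaB[as.character(lb)])
        }
        iou <- as.numeric(inter / denom)
        keep <- iou >= iou_threshold
        la <- la[keep]; lb <- lb[keep]
        inter <- inter[keep]; iou <- iou[keep]
        segarea <- pmax(areaA[as.character(la)], areaB[as.character(lb)])
        o <- order(-iou, -inter, -segarea, la, lb)
        usedA <- integer(0); usedB <- integer(0)
        for (k in o) {
          if (la[k] %in% usedA || lb[k] %in% usedB) next
          usedA <- c(usedA, la[k]); usedB <- c(usedB, lb[k])
          id <- track_of[[f]][[as.character(la[k])]]
          add_obs(id, f + 1L, lb[k])
          assigned[as.character(lb[k])] <- id
        }
      }
    }
    for (l in labsB[is.na(assigned[as.character(labsB)])])
      assigned[as.character(l)] <- start_track(f + 1L, l)
    track_of[[f + 1L]] <- assigned
  }
  lapply(tracks, function(tr) {
    tr$first_frame <- tr$frames[1]
    tr$last_frame <- tr$frames[length(tr$frames)]
    class(tr) <- "fa_track"
    tr
  })
}

#' Classify a focal-adhesion track as stable or dynamic
#'
#' A stable adhesion keeps a constant area and integrated fluorescence
#' intensity over the whole movie: the track must span every frame and at no
#' point may area or intensity deviate more than `tolerance` (default 10%,
#' inclusive) from its initial value. Tracks starting with zero area or
#' intensity cannot be normalized and are classified not-stable with a
#' warning.
#'
#' @param track An `fa_track` from [link_tracks()].
#' @param tolerance Maximum relative change from the initial value.
#' @param movie_length Total number of frames in the movie.
#' @return Logical.
#' @export
classify_stable <- function(track, tolerance = 0.10, movie_length) {
  stopifnot(inherits(track, "fa_track"))
  if (track$area_px2[1] <= 0 || track$intensity[1] <= 0) {
    warning("track ", track$track_id,
            ": zero initial area or intensity; classified not stable")
    return(FALSE)
  }
  if (track$first_frame != 1L || track$last_frame != movie_length)
    return(FALSE)
  tol <- tolerance + 1e-12 # inclusive boundary
  all(abs(track$area_px2 - track$area_px2[1]) / track$area_px2[1] <= tol) &&
    all(abs(track$intensity - track$intensity[1]) / track$intensity[1] <= tol)
}

#' Fraction of stable focal adhesions
#'
#' Number of stable tracks divided by the total number of tracks ever
#' observed in the movie (the denominator choice is recorded in the result).
#'
#' @param tracks List of `fa_track` from [link_tracks()].
#' @param movie_length Total number of frames.
#' @param tolerance Stability tolerance (see [classify_stable()]).
#' @return A list: `fraction`, `n_stable`, `n_tracks`, `tolerance`,
#'   `denominator = "all tracks"`.
#' @export
stable_fraction <- function(tracks, movie_length, tolerance = 0.10) {
  if (length(tracks) == 0L) stop("no tracks: stable fraction undefined")
  stable <- vapply(tracks, classify_stable, logical(1),
                   tolerance = tolerance, movie_length = movie_length)
  list(fraction = mean(stable), n_stable = sum(stable),
       n_tracks = length(tracks), tolerance = tolerance,
       denominator = "all tracks")
}

#' Tabulate linked tracks
#'
#' @param tracks List of `fa_track`.
#' @param movie_length Total number of frames (for the stability flag).
#' @param tolerance Stability tolerance.
#' @return Data frame `track_id, frame, area_px2, intensity, stable`.
#' @export
tracks_table <- function(tracks, movie_length, tolerance = 0.10) {
  do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = tr$track_id, frame = tr$frames,
               area_px2 = tr$area_px2, intensity = tr$intensity,
               stable = classify_stable(tr, tolerance, movie_length))
  }))
}

#' Autocorrelation of adhesion masks against the first frame
#'
#' For each frame the 2-D (Pearson) correlation coefficient between that
#' frame and the first frame of the series is computed over all pixels; the
#' decay of this curve with lag time summarizes how quickly the adhesion
#' pattern remodels. The lag-0 coefficient is exactly 1. A later frame with
#' zero variance has no defined coefficient and is recorded as missing.
#'
#' @param movie A [movie_stack] (binary adhesion masks, per the published
#'   analysis) or a 3-D array; intensities are accepted for the masked
#'   variant.
#' @param frame_interval_s Frame interval, s (taken from the movie when
#'   available).
#' @return A list of class `autocorr_curve`: `lag_s`, `r`.
#' @export
mask_autocorrelation <- function(movie, frame_interval_s = NULL) {
  if (inherits(movie, "movie_stack")) {
    frames <- movie$frames
    frame_interval_s <- frame_interval_s %||% movie$frame_interval_s
  } else {
    frames <- movie
    if (is.null(frame_interval_s)) stop("`frame_interval_s` required")
  }
  nt <- dim(frames)[1]
  if (nt < 2L) stop("need at least 2 frames")
  ref <- as.numeric(frames[1, , ])
  if (var(ref) == 0) stop("first frame has zero variance")
  r <- numeric(nt)
  r[1] <- 1
  for (i in 2:nt) {
    v <- as.numeric(frames[i, , ])
    if (var(v) == 0) {
      warning("frame ", i, " has zero variance: coefficient recorded as missing")
      r[i] <- NA_real_
    } else {
      r[i] <- cor(ref, v)
    }
  }
  structure(list(lag_s = (seq_len(nt) - 1) * frame_interval_s, r = r),
            class = "autocorr_curve")
}

#' @export
print.autocorr_curve <- function(x, ...) {
  cat(sprintf("autocorr_curve: %d lags to %.0f s, final r = %.3f\n",
              length(x$lag_s), max(x$lag_s), x$r[length(x$r)]))
  invisible(x)
}

#' @export
plot.autocorr_curve <- function(x, ...) {
  graphics::plot(x$lag_s, x$r, xlab = "lag (s)",
                 ylab = "correlation coefficient", ylim = c(min(0, x$r), 1),
                 pch = 16, ...)
  fit <- attr(x, "fit")
  if (!is.null(fit)) {
    tt <- seq(0, max(x$lag_s), length.out = 200)
    graphics::lines(tt, fit$A1 * exp(-tt / fit$tau1) +
                      fit$A2 * exp(-tt / fit$tau2), lty = 2)
  }
  invisible(x)
}

#' Fit a double-exponential decay to an autocorrelation curve
#'
#' Fits `r(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2)` (no offset: the
#' correlation decays to 0 at long lag) by bounded nonlinear least squares
#' with multi-start initialization over a grid of time-scale pairs;
#' amplitudes are constrained nonnegative and the components are returned
#' ordered `tau1 <= tau2`. Non-decaying input never crashes: the fit is
#' returned with a warning and the `no_decay` flag when both time scales
#' exceed 10 times the observation window.
#'
#' @param curve An `autocorr_curve`, or a list/data frame with `lag_s`, `r`.
#' @return A list of class `autocorr_fit`: `A1, tau1, A2, tau2`,
#'   `residual_rms`, `no_decay`.
#' @export
fit_double_exponential <- function(curve) {
  t <- curve$lag_s; r <- curve$r
  ok <- is.finite(t) & is.finite(r)
  t <- t[ok]; r <- r[ok]
  if (length(t) < 6L) stop("need at least 6 lag points")
  Tmax <- max(t)
  r0 <- r[which.min(t)]
  grid <- Tmax * c(0.02, 0.1, 0.3, 1, 3)
  best <- NULL
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    if (j <= i) next
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2),
        start = list(A1 = max(r0 / 2, 0.1), tau1 = grid[i],
                     A2 = max(r0 / 2, 0.1), tau2 = grid[j]),
        lower = c(0, Tmax * 1e-4, 0, Tmax * 1e-4),
        upper = c(2, Tmax * 1e3, 2, Tmax * 1e3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    # non-decaying or degenerate data: return a flagged constant-level fit
    # rather than crashing (time constants pushed beyond the window)
    warning("no decay detected: returning a degenerate constant-level fit")
    lvl <- max(mean(r), 1e-6)
    return(structure(list(A1 = lvl / 2, tau1 = 1e3 * Tmax, A2 = lvl / 2,
                          tau2 = 1e3 * Tmax,
                          residual_rms = sqrt(mean((r - lvl)^2)),
                          no_decay = TRUE),
                     class = "autocorr_fit"))
  }
  p <- as.list(coef(best$fit))
  if (p$tau1 > p$tau2) p <- list(A1 = p$A2, tau1 = p$tau2,
                                 A2 = p$A1, tau2 = p$tau1)
  no_decay <- min(p$tau1, p$tau2) > 10 * Tmax ||
    (p$A1 + p$A2) < 1e-3
  if (no_decay)
    warning("no decay detected: time constants exceed 10x the observation window")
  structure(list(A1 = p$A1, tau1 = p$tau1, A2 = p$A2, tau2 = p$tau2,
                 residual_rms = sqrt(best$rss / length(t)),
                 no_decay = no_decay),
            class = "autocorr_fit")
}

#' @export
print.autocorr_fit <- function(x, ...) {
  cat(sprintf(
    "double-exponential fit: %.3f exp(-t/%.3g s) + %.3f exp(-t/%.3g s), rms %.3g%s\n",
    x$A1, x$tau1, x$A2, x$tau2, x$residual_rms,
    if (x$no_decay) " [no decay]" else ""))
  invisible(x)
}

#' Apparent assembly and disassembly rates from a total-intensity series
#'
#' Total adhesion fluorescence per frame is median-smoothed, the peak
#' located, and the apparent rates taken from the slopes of the
#' semi-logarithmic intensity plot: `k_a` is the slope of `ln I` versus time
#' on the rising window and `k_d` the negative slope on the falling window.
#' The running median flattens the peak into a plateau and blurs the kink
#' where assembly turns into disassembly, so the fit windows exclude the
#' plateau: assembly runs from the first frame to just before the first
#' attainment of the smoothed maximum, disassembly from just after its last
#' attainment to the end (a series that is all plateau, i.e. constant,
#' keeps both full windows and yields rates of 0). A phase with fewer than
#' 3 samples is absent and its rate is reported as missing (`NA`), not 0.
#'
#' @param intensity Positive intensity series (one value per frame).
#' @param frame_interval_s Frame interval, s.
#' @param smooth_k Running-median window (odd; default 5). The ends are kept
#'   unsmoothed so monotone phases retain their exact slopes.
#' @return A list of class `intensity_kinetics`: `k_a`, `k_d` (1/min),
#'   `assembly_window`, `disassembly_window` (frame ranges), `r2_assembly`,
#'   `r2_disassembly`.
#' @export
assembly_disassembly_rates <- function(intensity, frame_interval_s,
                                       smooth_k = 5) {
  n <- length(intensity)
  if (n < 6L) stop("need at least 6 frames")
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("intensity must be positive and finite throughout")
  sm <- stats::runmed(intensity, k = min(smooth_k, n - (1 - n %% 2)),
                      endrule = "keep")
  t_min <- (seq_len(n) - 1) * frame_interval_s / 60
  mx <- max(sm)
  p_first <- which(sm == mx)[1]
  p_last <- tail(which(sm == mx), 1)
  slope_fit <- function(idx) {
    if (length(idx) < 3L) return(list(k = NA_real_, r2 = NA_real_))
    m <- lm(log(sm[idx]) ~ t_min[idx])
    r2 <- suppressWarnings(summary(m)$r.squared)
    list(k = unname(coef(m)[2]), r2 = r2)
  }
  up_idx <- seq_len(p_first - 1L)
  down_idx <- if (p_last < n) seq(p_last + 1L, n) else integer(0)
  if (p_last == n) up_idx <- seq_len(n)   # no falling phase: rise is clean
  if (p_first == 1L) down_idx <- seq_len(n) # no rising phase: fall is clean
  up <- slope_fit(up_idx)
  down <- slope_fit(down_idx)
  structure(list(
    k_a = up$k, k_d = if (is.na(down$k)) NA_real_ else -down$k,
    assembly_window = if (is.na(up$k)) NULL else range(up_idx),
    disassembly_window = if (is.na(down$k)) NULL else range(down_idx),
    r2_assembly = up$r2, r2_disassembly = down$r2),
    class = "intensity_kinetics")
}

#' @export
print.intensity_kinetics <- function(x, ...) {
  cat(sprintf("FA kinetics: k_a = %s /min, k_d = %s /min\n",
              format(x$k_a, digits = 3), format(x$k_d, digits = 3)))
  invisible(x)
}
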