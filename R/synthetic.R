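#' Ground-truth record of a synthetic dataset
#'
#' Every generator returns (and can serialize) a `synthetic_truth` holding
#' the generator name, the seed and the realized true parameters, so
#' recovery tests compare pipeline output against recorded truth rather
#' than against re-derived values. Regeneration from the same
#' `(generator, seed, params)` is bit-identical.
#'
#' @param generator Generator name.
#' @param seed Integer seed used.
#' @param params Named list of requested parameters.
#' @param realized Named list of realized quantities (e.g. the actual AR
#'   series).
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(generator, seed, params, realized = list()) {
  structure(list(generator = generator, seed = as.integer(seed),
                 params = params, realized = realized),
            class = "synthetic_truth")
}

#' Write / read a ground-truth record as JSON
#'
#' Generators conventionally place `truth.json` next to the data files they
#' emit; recovery tests read truth only from that record.
#'
#' @param truth A [synthetic_truth].
#' @param path Output path (conventionally `truth.json`).
#' @return `path` invisibly (`write_truth`); a `synthetic_truth`
#'   (`read_truth`).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_truth(x$generator, x$seed, as.list(x$params),
                  as.list(x$realized))
}

#' Simulate a single-cell mask movie with fluctuating aspect ratio
#'
#' Emulates the random-migration shape assay: a rasterized ellipse whose
#' aspect ratio follows the multiplicative random walk
#' `AR_n = AR_(n-1) (1 + eps_n)`, `eps_n ~ Normal(0, ar_noise_sd)` truncated
#' above -0.9, optionally modulated by a sinusoid, while the centroid
#' translocates at constant speed along a (by default random) heading.
#' Because the noise is multiplicative, the relative increments `dAR` are
#' the i.i.d. innovations and the true volatility equals the SD of the
#' realized `dAR` series, recorded in the truth. The realized AR is clamped
#' to `[1, ar_max]` so the cell stays rasterizable; the canvas is enlarged
#' automatically to contain the cell at all times. Defaults follow the
#' 2-frames-per-hour, 18-h acquisition.
#'
#' @param n_frames Number of frames (default 37).
#' @param frame_interval_s Frame interval, s (default 1800).
#' @param base_ar Initial aspect ratio.
#' @param ar_noise_sd SD of the multiplicative AR innovations.
#' @param ar_period_s Optional period of a sinusoidal AR modulation, s.
#' @param ar_amplitude Amplitude of the sinusoidal modulation (relative).
#' @param speed_um_per_h Centroid speed, um/h.
#' @param heading_rad Migration heading; `NULL` draws one at random.
#' @param pixel_size_um Pixel size, um/px.
#' @param cell_area_um2 Cell area, um^2 (held constant).
#' @param ar_max Upper clamp on the realized AR.
#' @param seed Integer seed.
#' @return A list: `movie` ([movie_stack], mask), `truth`
#'   ([synthetic_truth] with realized `ar`, `x_um`, `y_um`).
#' @export
make_shape_movie <- function(n_frames = 37, frame_interval_s = 1800,
                             base_ar = 2, ar_noise_sd = 0.1,
                             ar_period_s = NULL, ar_amplitude = 0,
                             speed_um_per_h = 10, heading_rad = NULL,
                             pixel_size_um = 0.65, cell_area_um2 = 1000,
                             ar_max = 8, seed = 1L) {
  stopifnot(n_frames >= 4, frame_interval_s > 0, base_ar >= 1,
            ar_noise_sd >= 0, speed_um_per_h >= 0, cell_area_um2 > 0)
  with_seed(seed, {
    heading <- heading_rad %||% runif(1, 0, 2 * pi)
    ar <- numeric(n_frames)
    ar[1] <- min(max(base_ar, 1), ar_max)
    for (i in 2:n_frames) {
      eps <- rnorm(1, 0, ar_noise_sd)
      while (eps <= -0.9) eps <- rnorm(1, 0, ar_noise_sd)
      ar[i] <- min(max(ar[i - 1] * (1 + eps), 1), ar_max)
    }
    t_s <- (seq_len(n_frames) - 1) * frame_interval_s
    if (!is.null(ar_period_s) && ar_amplitude > 0) {
      ar <- pmin(pmax(ar * (1 + ar_amplitude * sin(2 * pi * t_s / ar_period_s)),
                      1), ar_max)
    }
    step_um <- speed_um_per_h * frame_interval_s / 3600
    x_um <- (t_s / frame_interval_s) * step_um * cos(heading)
    y_um <- (t_s / frame_interval_s) * step_um * sin(heading)
    area_px <- cell_area_um2 / pixel_size_um^2
    a_px <- sqrt(area_px * ar / pi) # semi-major, px (along columns)
    b_px <- sqrt(area_px / (ar * pi))
    x_px <- x_um / pixel_size_um
    y_px <- y_um / pixel_size_um
    margin <- max(a_px) + 3
    c0 <- x_px - min(x_px) + margin
    r0 <- y_px - min(y_px) + margin
    nc <- ceiling(max(c0) + margin)
    nr <- ceiling(max(r0) + margin)
    frames <- array(0, dim = c(n_frames, nr, nc))
    rows <- seq_len(nr) - 1
    cols <- seq_len(nc) - 1
    for (i in seq_len(n_frames)) {
      dr2 <- ((rows - r0[i]) / b_px[i])^2
      dc2 <- ((cols - c0[i]) / a_px[i])^2
      frames[i, , ] <- (outer(dr2, dc2, "+") <= 1) * 1
    }
    movie <- movie_stack(frames, pixel_size_um, frame_interval_s,
                         is_mask = TRUE)
    truth <- synthetic_truth(
      "shape_movie", seed,
      params = list(n_frames = n_frames, frame_interval_s = frame_interval_s,
                    base_ar = base_ar, ar_noise_sd = ar_noise_sd,
                    ar_period_s = ar_period_s, ar_amplitude = ar_amplitude,
                    speed_um_per_h = speed_um_per_h,
                    pixel_size_um = pixel_size_um,
                    cell_area_um2 = cell_area_um2, ar_max = ar_max),
      realized = list(ar = ar, heading_rad = heading,
                      x_um = x_um - min(x_um) + margin * pixel_size_um,
                      y_um = y_um - min(y_um) + margin * pixel_size_um,
                      sigma_ar_true = sd(ar[-1] / ar[-length(ar)] - 1)))
    list(movie = movie, truth = truth)
  })
}

#' Simulate a TIRF focal-adhesion movie with known stable fraction
#'
#' Emulates the 61-frame, 30-s-interval TIRF assay: bright disk-shaped
#' adhesions on a noisy background, placed on a jittered grid so spots never
#' overlap. Stable spots keep constant intensity for the whole movie;
#' dynamic spots appear at staggered onsets, grow exponentially at rate
#' `k_a` to their peak and then decay at `k_d`, so the population shows
#' distinct assembly and disassembly phases. Pixel values are integer
#' camera counts; the noise SD is `amplitude / intensity_snr`.
#'
#' @param n_stable,n_dynamic Spot counts per class.
#' @param spot_radius Spot radius, px.
#' @param intensity_snr Peak-amplitude-to-noise ratio (`Inf` for clean).
#' @param k_a,k_d Assembly/disassembly rates of dynamic spots, 1/min.
#' @param n_frames Number of frames (default 61).
#' @param frame_interval_s Frame interval, s (default 30).
#' @param amplitude Peak spot amplitude, counts.
#' @param background Background level, counts.
#' @param pixel_size_um Pixel size, um/px.
#' @param seed Integer seed.
#' @return A list: `movie` (intensity [movie_stack]), `truth` (classes,
#'   positions, onsets, kinetics).
#' @export
make_fa_movie <- function(n_stable = 40, n_dynamic = 60, spot_radius = 6,
                          intensity_snr = 10, k_a = 0.3, k_d = 0.15,
                          n_frames = 61, frame_interval_s = 30,
                          amplitude = 1000, background = 100,
                          pixel_size_um = 0.16, seed = 1L) {
  n_spots <- n_stable + n_dynamic
  stopifnot(n_stable >= 0, n_dynamic >= 0, n_spots >= 1,
            intensity_snr > 1, spot_radius >= 2)
  with_seed(seed, {
    g <- ceiling(sqrt(n_spots))
    cell <- 2 * spot_radius + 10
    side <- g * cell + 2 * spot_radius + 10
    if (side > 4096) stop("too many spots for the canvas")
    # jittered grid placement: non-overlapping by construction
    slots <- expand.grid(gr = seq_len(g), gc = seq_len(g))
    slots <- slots[sample(nrow(slots), n_spots), ]
    r0 <- spot_radius + 5 + (slots$gr - 0.5) * cell +
      runif(n_spots, -3, 3)
    c0 <- spot_radius + 5 + (slots$gc - 0.5) * cell +
      runif(n_spots, -3, 3)
    cls <- sample(rep(c("stable", "dynamic"), c(n_stable, n_dynamic)))
    t_min <- (seq_len(n_frames) - 1) * frame_interval_s / 60
    dur <- max(t_min)
    onset <- runif(n_spots, 0, dur / 3)
    rise <- runif(n_spots, dur / 4, dur / 2.5)
    noise_sd <- if (is.finite(intensity_snr)) amplitude / intensity_snr else 0
    rows <- seq_len(side) - 1
    frames <- array(0, dim = c(n_frames, side, side))
    disc <- list()
    for (s in seq_len(n_spots)) {
      dr2 <- (rows - r0[s])^2
      dc2 <- (rows - c0[s])^2
      disc[[s]] <- which(outer(dr2, dc2, "+") <= spot_radius^2)
    }
    for (f in seq_len(n_frames)) {
      img <- matrix(background, side, side)
      for (s in seq_len(n_spots)) {
        amp <- if (cls[s] == "stable") {
          amplitude
        } else {
          tp <- onset[s] + rise[s]
          if (t_min[f] < onset[s]) 0
          else if (t_min[f] <= tp)
            amplitude * exp(k_a * (t_min[f] - tp))
          else amplitude * exp(-k_d * (t_min[f] - tp))
        }
        img[disc[[s]]] <- img[disc[[s]]] + amp
      }
      if (noise_sd > 0)
        img <- img + matrix(rnorm(side^2, 0, noise_sd), side, side)
      frames[f, , ] <- pmax(round(img), 0)
    }
    movie <- movie_stack(frames, pixel_size_um, frame_interval_s)
    truth <- synthetic_truth(
      "fa_movie", seed,
      params = list(n_stable = n_stable, n_dynamic = n_dynamic,
                    spot_radius = spot_radius, intensity_snr = intensity_snr,
                    k_a = k_a, k_d = k_d, n_frames = n_frames,
                    frame_interval_s = frame_interval_s,
                    amplitude = amplitude, background = background),
      realized = list(stable_fraction = n_stable / n_spots,
                      class = cls, row = r0, col = c0,
                      onset_min = onset, peak_min = onset + rise))
    list(movie = movie, truth = truth)
  })
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration (>= 0).
#' @return Angles in radians.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return((runif(n, -pi, pi) + mu + pi) %% (2 * pi) - pi)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rho <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + rho * z) / (rho + z)
    cval <- kappa * (rho - f)
    ok <- (cval * (2 - cval) - u2 > 0) | (log(cval / u2) + 1 - cval >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, th)
  }
  ((out[seq_len(n)] + mu + pi) %% (2 * pi)) - pi
}

#' Simulate chemotaxis tracks with von Mises directional bias
#'
#' Emulates the chemotaxis-chamber endpoint assay (45 cells per group in the
#' reference conditions): each cell performs a biased random walk whose step
#' headings are i.i.d. von Mises about `mean_direction_rad` with
#' concentration `kappa`; `kappa = 0` gives isotropic migration and the
#' `kappa -> Inf` limit straight paths with persistence 1.
#'
#' @param n_cells Number of cells (default 45).
#' @param n_steps Steps per track (default 36; 18 h at 2 frames/h).
#' @param step_length_um Step length, um.
#' @param kappa von Mises concentration (>= 0).
#' @param mean_direction_rad Gradient direction, radians.
#' @param seed Integer seed.
#' @return A list: `tracks` (data frame `cell_id, step, x_um, y_um`),
#'   `endpoint_angles` (radians), `truth`.
#' @export
make_chemotaxis_tracks <- function(n_cells = 45, n_steps = 36,
                                   step_length_um = 10, kappa = 2,
                                   mean_direction_rad = pi, seed = 1L) {
  stopifnot(n_cells >= 1, n_steps >= 1, step_length_um > 0, kappa >= 0)
  with_seed(seed, {
    th <- matrix(rvonmises(n_cells * n_steps, mean_direction_rad, kappa),
                 n_cells, n_steps)
    x <- t(apply(cos(th) * step_length_um, 1, cumsum))
    y <- t(apply(sin(th) * step_length_um, 1, cumsum))
    tracks <- data.frame(
      cell_id = rep(seq_len(n_cells), each = n_steps + 1),
      step = rep(0:n_steps, n_cells),
      x_um = as.numeric(t(cbind(0, x))),
      y_um = as.numeric(t(cbind(0, y))))
    truth <- synthetic_truth(
      "chemotaxis_tracks", seed,
      params = list(n_cells = n_cells, n_steps = n_steps,
                    step_length_um = step_length_um, kappa = kappa,
                    mean_direction_rad = mean_direction_rad))
    list(tracks = tracks, endpoint_angles = atan2(y[, n_steps], x[, n_steps]),
         truth = truth)
  })
}

#' Endpoint angles of a chemotaxis track table
#'
#' @param tracks Data frame `cell_id, step, x_um, y_um` (start at the
#'   origin).
#' @return Angle (radians) of each cell's final position.
#' @export
endpoint_angles <- function(tracks) {
  ends <- do.call(rbind, lapply(split(tracks, tracks$cell_id), function(d) {
    d[which.max(d$step), c("x_um", "y_um")]
  }))
  atan2(ends$y_um, ends$x_um)
}

#' Simulate a Sneddon-form AFM approach curve
#'
#' Zero-force baseline up to the contact point `z0`, then the Sneddon
#' conical-contact force with the cantilever-bending relation inverted
#' exactly (the generated `F(z)` satisfies
#' `F = coef * ((z - z0) - F/k)^2`), plus optional additive Gaussian noise.
#' Defaults mirror the reference acquisition: 2.5-um ramp, 0.06 N/m
#' cantilever, 18-degree half-angle, Poisson ratio 0.5.
#'
#' @param E_pa Young's modulus, Pa (> 0).
#' @param poisson_ratio,half_angle_deg,spring_constant Probe parameters.
#' @param z0_um Contact point, um.
#' @param ramp_um Ramp size, um (default 2.5).
#' @param n_samples Samples along the ramp.
#' @param noise_sd_nN Additive force noise SD, nN.
#' @param trigger_nN Trigger force stored with the curve.
#' @param seed Integer seed.
#' @return A list: `curve` ([force_curve]), `truth`.
#' @export
make_force_curve <- function(E_pa, poisson_ratio = 0.5, half_angle_deg = 18,
                             spring_constant = 0.06, z0_um = 0.75,
                             ramp_um = 2.5, n_samples = 512,
                             noise_sd_nN = 0, trigger_nN = 1.5, seed = 1L) {
  if (!is.finite(E_pa) || E_pa <= 0) stop("`E_pa` must be positive")
  with_seed(seed, {
    z <- seq(0, ramp_um, length.out = n_samples)
    cc <- sneddon_coef(E_pa, poisson_ratio, half_angle_deg)
    b <- 1e-3 / spring_constant # um of cantilever bending per nN
    d <- pmax(z - z0_um, 0)
    # F solves F = cc * (d - b F)^2; smaller quadratic root keeps delta > 0
    F <- (2 * cc * b * d + 1 - sqrt(4 * cc * b * d + 1)) / (2 * cc * b^2)
    if (noise_sd_nN > 0) F <- F + rnorm(n_samples, 0, noise_sd_nN)
    curve <- force_curve(z, F, spring_constant = spring_constant,
                         half_angle_deg = half_angle_deg,
                         poisson_ratio = poisson_ratio,
                         trigger_nN = trigger_nN)
    truth <- synthetic_truth(
      "force_curve", seed,
      params = list(E_pa = E_pa, poisson_ratio = poisson_ratio,
                    half_angle_deg = half_angle_deg,
                    spring_constant = spring_constant, z0_um = z0_um,
                    ramp_um = ramp_um, n_samples = n_samples,
                    noise_sd_nN = noise_sd_nN))
    list(curve = curve, truth = truth)
  })
}

#' Simulate a cell mask and cortical signal image
#'
#' A disk-shaped cell with signal painted on the boundary band over a known
#' arc fraction (for the edge-positive fraction) and/or on an interior ring
#' at a known depth (for the edge-distance profile), plus optional Gaussian
#' noise.
#'
#' @param cell_radius_um Cell radius, um.
#' @param pixel_size_um Pixel size, um/px.
#' @param band_arc_fraction Fraction of the boundary band carrying signal,
#'   in \[0, 1\].
#' @param band_width_um Band depth, um.
#' @param ring_depth_um Depth of an interior signal ring, um (`NULL` for
#'   none).
#' @param ring_width_um Ring thickness, um.
#' @param signal_level Painted signal level (a.u.).
#' @param background Background signal level.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @return A list: `mask`, `signal` (matrices), `truth`.
#' @export
make_cortex_image <- function(cell_radius_um = 20, pixel_size_um = 0.5,
                              band_arc_fraction = 0.5, band_width_um = 1,
                              ring_depth_um = NULL, ring_width_um = 1,
                              signal_level = 100, background = 0,
                              noise_sd = 0, seed = 1L) {
  stopifnot(band_arc_fraction >= 0, band_arc_fraction <= 1,
            cell_radius_um > 0)
  with_seed(seed, {
    R_px <- cell_radius_um / pixel_size_um
    side <- ceiling(2 * R_px + 9)
    ctr <- (side + 1) / 2
    rows <- seq_len(side) - ctr
    d2 <- outer(rows^2, rows^2, "+")
    mask <- (d2 <= R_px^2) * 1
    dist_um <- edge_distance_px(mask) * pixel_size_um
    theta <- (atan2(outer(rows, rep(1, side)), outer(rep(1, side), rows)) +
                2 * pi) %% (2 * pi)
    signal <- matrix(background, side, side)
    if (band_arc_fraction > 0) {
      band <- mask == 1 & dist_um <= band_width_um &
        theta < 2 * pi * band_arc_fraction
      signal[band] <- signal_level
    }
    if (!is.null(ring_depth_um)) {
      ring <- mask == 1 & abs(dist_um - ring_depth_um) <= ring_width_um / 2
      signal[ring] <- signal_level
    }
    if (noise_sd > 0)
      signal <- signal + matrix(rnorm(side^2, 0, noise_sd), side, side)
    truth <- synthetic_truth(
      "cortex_image", seed,
      params = list(cell_radius_um = cell_radius_um,
                    pixel_size_um = pixel_size_um,
                    band_arc_fraction = band_arc_fraction,
                    band_width_um = band_width_um,
                    ring_depth_um = ring_depth_um,
                    ring_width_um = ring_width_um,
                    signal_level = signal_level, noise_sd = noise_sd))
    list(mask = mask, signal = signal, truth = truth)
  })
}
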