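# Shared fixture: seeded TIRF movies used by several blocks (generation and
# segmentation dominate the suite's runtime, so build them once).
fa_noisy <- make_fa_movie(n_stable = 40, n_dynamic = 60, intensity_snr = 10,
                          seed = 5)
fa_seg <- segment_adhesions(fa_noisy$movie)
fa_tracks <- link_tracks(fa_seg)

test_that("otsu_threshold equals the enumeration oracle", {
  set.seed(8)
  for (i in 1:20) {
    v <- switch(1 + i %% 4,
                rnorm(200),
                sample(0:255, 150, replace = TRUE),
                c(rnorm(80, 0), rnorm(40, 6)),
                round(runif(60, 0, 10)) / 2)
    expect_identical(otsu_threshold(v), oracle_otsu(v))
  }
  expect_true(is.na(otsu_threshold(rep(3, 50))))
})

test_that("median filter matches the naive reference, including even windows", {
  set.seed(12)
  for (w in c(3, 4, 10, 11)) {
    m <- matrix(rnorm(16 * 16), 16, 16)
    expect_equal(median_filter(m, w), oracle_median_filter(m, w))
  }
})

test_that("segmentation equals the brute-force set-operation reference", {
  set.seed(31)
  for (i in 1:12) {
    n <- sample(8:16, 1)
    frame <- matrix(round(runif(n * n, 0, 4)), n, n)
    # plant a bright blob so most frames have structure
    r <- sample(2:(n - 3), 1); c <- sample(2:(n - 3), 1)
    frame[r:(r + 2), c:(c + 2)] <- frame[r:(r + 2), c:(c + 2)] + 10
    mv <- movie_stack(array(frame, c(1, n, n)), 1, 1)
    seg <- segment_adhesions(mv, median_window = 1, opening_kernel = 3,
                             min_area = 1)
    want <- oracle_segment_frame(frame, opening_kernel = 3, min_area = 1)
    expect_same_labelling(matrix(seg$labels[1, , ], n, n), want)
  }
})

test_that("segmentation is equivariant to image translation", {
  set.seed(7)
  field <- matrix(round(rnorm(60 * 60, 10, 2)), 60, 60)
  field[15:21, 17:23] <- 100
  field[35:40, 35:41] <- 80
  # two 48 x 48 crops of the same field, offset by (5, 3)
  f1 <- field[6:53, 4:51]
  f2 <- field[1:48, 1:48]
  s1 <- segment_adhesions(movie_stack(array(f1, c(1, 48, 48)), 1, 1),
                          median_window = 3, min_area = 4)
  s2 <- segment_adhesions(movie_stack(array(f2, c(1, 48, 48)), 1, 1),
                          median_window = 3, min_area = 4)
  key <- function(st) order(st$centroid_row * 1e4 + st$centroid_col)
  st1 <- s1$stats[key(s1$stats), ]
  st2 <- s2$stats[key(s2$stats), ]
  expect_equal(nrow(st1), 2)
  expect_equal(nrow(st2), 2)
  expect_equal(st2$centroid_row, st1$centroid_row + 5)
  expect_equal(st2$centroid_col, st1$centroid_col + 3)
  expect_equal(st1$area_px2, st2$area_px2)
})

test_that("segmentation handles blank frames, disks and annuli", {
  blank <- movie_stack(array(0, c(1, 32, 32)), 1, 1)
  expect_warning(s0 <- segment_adhesions(blank, median_window = 3), "constant")
  expect_equal(count_adhesions(s0, 1), 0)

  # two bright disks at 10x background with seeded noise: 2 segments near truth
  set.seed(3)
  img <- matrix(rnorm(64 * 64, 10, 1), 64, 64)
  d1 <- raster_ellipse(8, 8, n = 64, ctr = 17)          # centre (17, 17)
  d2 <- matrix(0, 64, 64); d2[37:59, 37:59] <- raster_ellipse(8, 8, n = 23)
  img <- img + 100 * d1 + 100 * d2
  seg <- segment_adhesions(movie_stack(array(img, c(1, 64, 64)), 1, 1),
                           median_window = 3, min_area = 4)
  expect_equal(count_adhesions(seg, 1), 2)
  st <- seg$stats[order(seg$stats$centroid_row), ]
  expect_lt(max(abs(st$centroid_row - c(16, 47))), 2) # 0-based truth
  expect_lt(max(abs(st$centroid_col - c(16, 47))), 2)

  # annulus: hole filling recovers the filled disk area
  ann <- (raster_ellipse(10, 10, n = 32) - raster_ellipse(5, 5, n = 32)) * 100
  sega <- segment_adhesions(movie_stack(array(ann + 1, c(1, 32, 32)), 1, 1),
                            median_window = 1, min_area = 4)
  expect_equal(count_adhesions(sega, 1), 1)
  expect_equal(sega$stats$area_px2, sum(raster_ellipse(10, 10, n = 32)),
               tolerance = 0.05)
})

test_that("per-frame counts are invariant to intensity rescaling", {
  sub <- movie_stack(fa_noisy$movie$frames[1:2, , , drop = FALSE] * 2,
                     0.16, 30)
  seg2 <- segment_adhesions(sub)
  sub1 <- movie_stack(fa_noisy$movie$frames[1:2, , , drop = FALSE], 0.16, 30)
  seg1 <- segment_adhesions(sub1)
  expect_equal(count_adhesions(seg2, 1), count_adhesions(seg1, 1))
  expect_equal(count_adhesions(seg2, 2), count_adhesions(seg1, 2))
  expect_error(count_adhesions(seg1, 99), "out of range")
})

test_that("overlap linking keeps identities without gap closing", {
  # one static spot: a single track spanning the movie
  disk <- raster_ellipse(5, 5, n = 32, ctr = 16) * 500 + 10
  mv <- movie_stack(array(rep(disk, each = 8), c(8, 32, 32)), 1, 30)
  tr <- link_tracks(segment_adhesions(mv, median_window = 1))
  expect_length(tr, 1)
  expect_equal(tr[[1]]$first_frame, 1L)
  expect_equal(tr[[1]]$last_frame, 8L)
  expect_equal(tr[[1]]$frames, 1:8)

  # spot present frames 1-4 then gone: track ends at 4
  frames <- array(10, c(8, 32, 32))
  for (i in 1:4) frames[i, , ] <- disk
  frames[5:8, 2, 2] <- 600 # keep later frames non-constant
  tr2 <- link_tracks(segment_adhesions(movie_stack(frames, 1, 30),
                                       median_window = 1, min_area = 1))
  spans <- vapply(tr2, function(t) t$last_frame, integer(1))
  expect_true(any(spans == 4L))
  big <- tr2[[which.max(vapply(tr2, function(t) max(t$area_px2), numeric(1)))]]
  expect_equal(big$frames, 1:4)

  # two fixed spots swapping intensities: two tracks, no identity switch
  dA <- matrix(0, 40, 40); dA[8:14, 8:14] <- 1
  dB <- matrix(0, 40, 40); dB[26:32, 26:32] <- 1
  fr <- array(10, c(6, 40, 40))
  for (i in 1:6) {
    hiA <- if (i %% 2) 800 else 500 # both always well above threshold
    fr[i, , ] <- 10 + dA * hiA + dB * (1300 - hiA)
  }
  tr3 <- link_tracks(segment_adhesions(movie_stack(fr, 1, 30),
                                       median_window = 1))
  expect_length(tr3, 2)
  for (t in tr3) {
    expect_equal(t$frames, 1:6)
    expect_equal(var(t$area_px2), 0) # same pixels throughout: no switch
  }
})

test_that("the 10%-change stability rule is inclusive and full-span", {
  mk_track <- function(area, intens, first = 1L) {
    structure(list(track_id = 1L, frames = seq(first, first + length(area) - 1L),
                   area_px2 = area, intensity = intens,
                   first_frame = first,
                   last_frame = first + length(area) - 1L),
              class = "fa_track")
  }
  n <- 10L
  const <- mk_track(rep(50, n), rep(1000, n))
  expect_true(classify_stable(const, movie_length = n))

  # +15% area excursion at any frame breaks stability
  a <- rep(50, n); a[6] <- 50 * 1.15
  expect_false(classify_stable(mk_track(a, rep(1000, n)), movie_length = n))

  # fluctuations of +/-9% in both area and intensity stay stable
  set.seed(2)
  a9 <- 50 * (1 + runif(n - 1, -0.09, 0.09))
  i9 <- 1000 * (1 + runif(n - 1, -0.09, 0.09))
  expect_true(classify_stable(mk_track(c(50, a9), c(1000, i9)),
                              movie_length = n))

  # exactly 10% is inclusive
  expect_true(classify_stable(mk_track(c(50, rep(55, n - 1)),
                                       rep(1000, n)), movie_length = n))

  # not spanning the movie is never stable
  expect_false(classify_stable(mk_track(rep(50, n - 2), rep(1000, n - 2),
                                        first = 2L), movie_length = n))

  # zero initial area flagged, not stable
  expect_warning(
    st <- classify_stable(mk_track(c(0, rep(5, n - 1)), rep(10, n)),
                          movie_length = n), "zero initial")
  expect_false(st)

  # counting: 3 stable of 10
  tracks <- c(lapply(1:3, function(i) mk_track(rep(40, n), rep(900, n))),
              lapply(1:7, function(i) mk_track(rep(40, 3), rep(900, 3))))
  sf <- stable_fraction(tracks, movie_length = n)
  expect_equal(sf$fraction, 0.3)
  expect_equal(sf$n_tracks, 10)
  expect_error(stable_fraction(list(), 10), "no tracks")

  # stricter tolerance can only shrink the stable set
  fr_tol <- vapply(c(0.20, 0.10, 0.05, 0.01), function(tol)
    stable_fraction(fa_tracks, n_frames(fa_noisy$movie), tol)$fraction,
    numeric(1))
  expect_true(all(diff(fr_tol) <= 0))
})

test_that("stable fraction recovers the generated 40/100 mixture", {
  sf <- stable_fraction(fa_tracks, n_frames(fa_noisy$movie))
  expect_equal(sf$n_tracks, 100)
  expect_lt(abs(sf$fraction - 0.40), 0.05)
})

test_that("mask autocorrelation obeys its contract", {
  set.seed(15)
  base <- matrix(rbinom(128 * 128, 1, 0.3), 128, 128)
  # static movie: all coefficients 1
  stat <- movie_stack(array(rep(base, each = 3), c(3, 128, 128)), 1, 30,
                      is_mask = TRUE)
  ac <- mask_autocorrelation(stat)
  expect_identical(ac$r[1], 1)
  expect_equal(ac$r, rep(1, 3))
  expect_equal(ac$lag_s, c(0, 30, 60))

  # complement of frame 0 anticorrelates exactly
  fr <- array(0, c(2, 128, 128))
  fr[1, , ] <- base; fr[2, , ] <- 1 - base
  expect_equal(mask_autocorrelation(movie_stack(fr, 1, 30, is_mask = TRUE))$r,
               c(1, -1))

  # independent random masks decorrelate
  fr2 <- array(rbinom(5 * 128 * 128, 1, 0.3), c(5, 128, 128))
  acr <- mask_autocorrelation(movie_stack(fr2, 1, 30, is_mask = TRUE))
  expect_true(all(abs(acr$r[-1]) < 0.05))
  expect_true(all(acr$r >= -1 & acr$r <= 1))

  # zero-variance frames: first is an error, later ones are missing
  fr3 <- array(0, c(2, 8, 8)); fr3[1, 1, 1] <- 1
  expect_warning(acz <- mask_autocorrelation(movie_stack(fr3, 1, 30)),
                 "missing")
  expect_true(is.na(acz$r[2]))
  fr4 <- array(0, c(2, 8, 8)); fr4[2, 1, 1] <- 1
  expect_error(mask_autocorrelation(movie_stack(fr4, 1, 30)), "zero variance")
})

test_that("double-exponential fits invert the forward model", {
  lag <- (0:60) * 30
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    r <- 0.6 * exp(-lag / 60) + 0.4 * exp(-lag / 600) + rnorm(61, 0, 0.01)
    f <- fit_double_exponential(list(lag_s = lag, r = r))
    expect_lte(f$tau1, f$tau2)
    expect_gte(f$A1, 0)
    max(abs(c(f$A1 - 0.6, f$tau1 - 60, f$A2 - 0.4, f$tau2 - 600) /
              c(0.6, 60, 0.4, 600)))
  })
  expect_lt(median(errs), 0.15)
  expect_lt(mean(errs > 0.15), 0.25) # isolated seeds may exceed, most not

  # single-exponential data: nested-model limit, residual stays tiny
  r1 <- exp(-lag / 120)
  f1 <- fit_double_exponential(list(lag_s = lag, r = r1))
  expect_lt(f1$residual_rms, 1e-4)
  degenerate <- f1$A2 < 0.05 || abs(f1$tau1 - f1$tau2) / f1$tau2 < 0.2
  expect_true(degenerate || abs(f1$A1 * f1$tau1 + f1$A2 * f1$tau2 -
                                  120) / 120 < 0.05)

  # constant series: flagged as non-decaying
  expect_warning(f2 <- fit_double_exponential(list(lag_s = lag,
                                                   r = rep(1, 61))),
                 "no decay")
  expect_true(f2$no_decay)
  expect_gt(min(f2$tau1, f2$tau2), 10 * max(lag))
  expect_error(fit_double_exponential(list(lag_s = 1:4, r = rep(1, 4))),
               "6 lag")
})

test_that("semi-log slopes recover assembly and disassembly rates", {
  t_min <- (0:60) * 0.5
  I <- ifelse(t_min <= 10, exp(0.1 * t_min),
              exp(1) * exp(-0.05 * (t_min - 10))) * 100
  k <- assembly_disassembly_rates(I, frame_interval_s = 30)
  expect_equal(k$k_a, 0.10, tolerance = 0.05)
  expect_equal(k$k_d, 0.05, tolerance = 0.05)

  kc <- assembly_disassembly_rates(rep(500, 20), 30)
  expect_lt(abs(kc$k_a), 1e-3)
  expect_lt(abs(kc$k_d), 1e-3)

  kd <- assembly_disassembly_rates(100 * exp(-0.05 * t_min), 30)
  expect_true(is.na(kd$k_a))
  expect_equal(kd$k_d, 0.05, tolerance = 0.05)
  ka <- assembly_disassembly_rates(100 * exp(0.1 * t_min), 30)
  expect_true(is.na(ka$k_d))
  expect_equal(ka$k_a, 0.10, tolerance = 0.05)

  expect_error(assembly_disassembly_rates(c(1, 2, 3), 30), "6 frames")
  expect_error(assembly_disassembly_rates(c(rep(1, 10), 0), 30), "positive")

  # noisy replicates: median recovery within 10%
  errs <- sapply(1:50, function(s) {
    set.seed(s)
    In <- I * exp(rnorm(61, 0, 0.02))
    kk <- assembly_disassembly_rates(In, 30)
    c(abs(kk$k_a - 0.1) / 0.1, abs(kk$k_d - 0.05) / 0.05)
  })
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.10)
})
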