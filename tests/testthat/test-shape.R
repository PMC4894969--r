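test_that("moment ellipse fit recovers analytic axes and aspect ratios", {
  # disk: AR 1 within 2%
  disk <- raster_ellipse(30, 30)
  fd <- fit_ellipse(disk)
  expect_lt(abs(fd$aspect_ratio - 1), 0.02)
  expect_equal(fd$major_axis, 60, tolerance = 0.05)

  # AR 2, 4, 8 within 3% of the generating axes
  for (ar in c(2, 4, 8)) {
    f <- fit_ellipse(raster_ellipse(15 * ar, 15))
    expect_lt(abs(f$aspect_ratio - ar) / ar, 0.03)
  }

  # the 40 x 10 ellipse of the classic example, and its 37-degree rotation
  f0 <- fit_ellipse(raster_ellipse(40, 10))
  expect_lt(abs(f0$aspect_ratio - 4) / 4, 0.03)
  fr <- fit_ellipse(raster_ellipse(40, 10, theta = 37 * pi / 180))
  expect_lt(abs(fr$aspect_ratio - f0$aspect_ratio) / f0$aspect_ratio, 0.03)
})

test_that("ellipse fit is translation invariant and takes the largest blob", {
  m <- matrix(0, 90, 90)
  e <- raster_ellipse(20, 8, n = 61)
  m[10:70, 10:70] <- e
  m2 <- matrix(0, 90, 90)
  m2[25:85, 20:80] <- e
  expect_equal(fit_ellipse(m)$aspect_ratio, fit_ellipse(m2)$aspect_ratio)
  # debris smaller than the cell is ignored
  m[85:88, 85:88] <- 1
  expect_equal(fit_ellipse(m)$aspect_ratio, fit_ellipse(m2)$aspect_ratio)
})

test_that("degenerate masks are rejected, polygons are accepted", {
  expect_error(fit_ellipse(matrix(0, 10, 10)), "empty mask")
  line <- matrix(0, 10, 10); line[5, 2:9] <- 1
  expect_error(fit_ellipse(line), "degenerate")
  tiny <- matrix(0, 10, 10); tiny[5, 5] <- 1
  expect_error(fit_ellipse(tiny), "too small")
  # a 20 x 10 rectangle as a polygon outline: AR = sqrt of variance ratio = 2
  poly <- cbind(c(5.2, 25.2, 25.2, 5.2), c(10.2, 10.2, 20.2, 20.2))
  fp <- fit_ellipse(poly)
  expect_equal(fp$aspect_ratio, 2, tolerance = 0.05)
})

test_that("track_shape reports centroids and AR in physical units", {
  # static disk
  disk <- raster_ellipse(10, 10, n = 41)
  mv <- movie_stack(array(rep(disk, each = 4), c(4, 41, 41)),
                    pixel_size_um = 0.5, frame_interval_s = 1800,
                    is_mask = TRUE)
  tr <- track_shape(mv)
  expect_equal(tr$times_h, c(0, 0.5, 1, 1.5))
  expect_lt(max(abs(tr$aspect_ratio - 1)), 0.02)
  expect_equal(var(tr$x_um), 0)

  # disk translating 1 px/frame moves pixel_size_um per frame
  frames <- array(0, c(5, 41, 61))
  for (i in 1:5) frames[i, , i:(i + 40)] <- disk
  mv2 <- movie_stack(frames, 0.5, 1800, is_mask = TRUE)
  tr2 <- track_shape(mv2)
  expect_equal(diff(tr2$x_um), rep(0.5, 4), tolerance = 1e-6)
  expect_equal(diff(tr2$y_um), rep(0, 4), tolerance = 1e-6)

  # empty frame fails loudly
  frames[3, , ] <- 0
  expect_error(track_shape(movie_stack(frames, 0.5, 1800, is_mask = TRUE)),
               "frame 3")
})

test_that("shape volatility matches the hand-evaluated formula", {
  v <- shape_volatility(c(1, 2, 1, 2), sampling_interval_h = 1)
  expect_equal(v$delta_ar, c(1, -0.5, 1))
  expect_equal(v$sigma_ar, sd(c(1, -0.5, 1)))
  expect_equal(v$sigma_ar, 0.8660254, tolerance = 1e-6)
  expect_equal(v$n_intervals, 3L)

  expect_equal(shape_volatility(c(2, 2, 2, 2), 1)$sigma_ar, 0)
})

test_that("shape volatility is scale-free and resamples to the interval", {
  set.seed(4)
  ar <- cumprod(c(2, 1 + rnorm(30, 0, 0.08)))
  expect_equal(shape_volatility(ar, 1)$sigma_ar,
               shape_volatility(3.7 * ar, 1)$sigma_ar)

  # half-hour track sampled hourly takes every second frame
  tr <- shape_track("c", times_h = (0:30) * 0.5, aspect_ratio = ar,
                    x_um = numeric(31), y_um = numeric(31))
  v1 <- shape_volatility(tr, sampling_interval_h = 1)
  sub <- ar[seq(1, 31, by = 2)]
  expect_equal(v1$sigma_ar, sd(sub[-1] / sub[-16] - 1))
  expect_error(shape_volatility(tr, sampling_interval_h = 0.75), "multiple")
  expect_error(shape_volatility(c(1, 2), 1), "3 samples")
  expect_error(shape_volatility(c(1, -1, 2, 1), 1), "positive")
})

test_that("volatility estimates recover the generating noise scale", {
  # AR_n = AR_{n-1}(1 + eps), eps ~ N(0, sigma): sigma_ar estimates sigma
  sigma <- 0.1; n <- 1000
  set.seed(97)
  eps <- rnorm(n, 0, sigma)
  eps[eps <= -0.9] <- -0.5
  ar <- cumprod(c(2, 1 + eps))
  est <- shape_volatility(ar, 1)$sigma_ar
  se <- sigma / sqrt(2 * n)
  expect_lt(abs(est - sigma), 3 * se)
})

test_that("migration speed is path length over elapsed time", {
  tr <- shape_track("a", c(0, 1), c(1, 1), x_um = c(0, 10), y_um = c(0, 0))
  expect_equal(migration_speed(tr), 10)
  tr0 <- shape_track("b", c(0, 0.5, 1), c(1, 1, 1), x_um = rep(2, 3),
                     y_um = rep(5, 3))
  expect_equal(migration_speed(tr0), 0)
  # right-angle legs of 3 and 4 um in 1 h: 7 um/h
  trL <- shape_track("c", c(0, 0.5, 1), c(1, 1, 1), x_um = c(0, 3, 3),
                     y_um = c(0, 0, 4))
  expect_equal(migration_speed(trL), 7)
  expect_error(migration_speed(shape_track("d", 0, 1, 0, 0)), "2 centroid")
})

test_that("directional persistence is displacement over distance", {
  trL <- shape_track("c", c(0, 0.5, 1), c(1, 1, 1), x_um = c(0, 3, 3),
                     y_um = c(0, 0, 4))
  expect_equal(directional_persistence(trL), 5 / 7)
  straight <- shape_track("s", 0:3, rep(1, 4), x_um = 0:3, y_um = rep(0, 4))
  expect_equal(directional_persistence(straight), 1)
  loop <- shape_track("l", 0:4, rep(1, 5), x_um = c(0, 1, 1, 0, 0),
                      y_um = c(0, 0, 1, 1, 0))
  expect_equal(directional_persistence(loop), 0)
  still <- shape_track("z", 0:2, rep(1, 3), x_um = rep(0, 3), y_um = rep(0, 3))
  expect_warning(p <- directional_persistence(still), "undefined")
  expect_true(is.na(p))
  # speed bounds displacement rate
  expect_gte(migration_speed(trL),
             5 / diff(range(trL$times_h)) - 1e-12)
})

test_that("Rayleigh test matches definitions and detects von Mises bias", {
  sym <- rayleigh_test(c(0, pi / 2, pi, 3 * pi / 2))
  expect_lt(sym$R_bar, 1e-12)
  expect_equal(sym$p_value, 1)

  same <- rayleigh_test(rep(1.2, 10))
  expect_equal(same$R_bar, 1)
  expect_equal(same$Z, 10)
  expect_lt(same$p_value, 1e-3)

  set.seed(5)
  biased <- rayleigh_test(rvonmises(45, mu = pi / 3, kappa = 2))
  expect_lt(biased$p_value, 0.001)
  expect_error(rayleigh_test(c(0, 1)), "at least 3")

  # p decreases monotonically in R_bar at fixed n: shrink a fixed angle
  # spread toward alignment and watch R_bar rise and p fall
  phi <- seq(-pi, pi, length.out = 45)
  res <- t(vapply(seq(1, 0.1, by = -0.1), function(beta) {
    rt <- rayleigh_test(beta * phi)
    c(rt$R_bar, rt$p_value)
  }, numeric(2)))
  expect_true(all(diff(res[, 1]) > 0))
  expect_true(all(diff(res[, 2]) <= 0))
})

test_that("volatility-speed correlation matches collinear references", {
  d <- data.frame(sigma_ar = 1:6, speed_um_per_h = 2 * (1:6) + 1)
  expect_equal(volatility_speed_correlation(d)$r, 1)
  d$speed_um_per_h <- -d$speed_um_per_h
  expect_equal(volatility_speed_correlation(d)$r, -1)
  d$speed_um_per_h <- rep(3, 6)
  expect_error(volatility_speed_correlation(d), "constant")
  expect_error(volatility_speed_correlation(d[1:2, ]), "3 cells")
  # spearman available
  d2 <- data.frame(sigma_ar = 1:10, speed_um_per_h = (1:10)^3)
  expect_equal(volatility_speed_correlation(d2, "spearman")$r, 1)
})

test_that("synthetic cohorts recover the analytic volatility-speed r", {
  set.seed(21)
  n <- 50
  a <- 60; noise_sd <- 0.3
  sigma <- runif(n, 0.05, 0.25)
  speed <- a * sigma + rnorm(n, 0, noise_sd)
  r_analytic <- a * sd(sigma) / sqrt(a^2 * var(sigma) + noise_sd^2)
  est <- volatility_speed_correlation(
    data.frame(sigma_ar = sigma, speed_um_per_h = speed))
  expect_lt(abs(est$r - r_analytic), 0.1)
  expect_lt(est$p_value, 1e-6)
})
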