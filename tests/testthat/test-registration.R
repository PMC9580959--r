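grid_pairs <- function(t, n = 7, lo = 5, hi = 59) {
  g <- seq(lo, hi, length.out = n)
  pts <- expand.grid(x = g, y = g)
  m <- apply_field_transform(t, pts)
  data.frame(x = pts$x, y = pts$y, xp = m$x, yp = m$y)
}

test_that("the transform model carries exactly 10 coefficients per axis", {
  t <- identity_transform()
  expect_length(t$ax, 10)
  expect_length(t$ay, 10)
  expect_error(field_transform(1:9, 1:10), "10")
})

test_that("fitting identity pairs recovers the identity pattern", {
  pairs <- grid_pairs(identity_transform())
  t <- fit_field_transform(pairs)
  expect_equal(t$ax, c(rep(0, 7), 1, 0, 0), tolerance = 1e-9)
  expect_equal(t$ay, c(rep(0, 8), 1, 0), tolerance = 1e-9)
})

test_that("a known random cubic warp is recovered from noiseless pairs", {
  truth <- random_cubic_transform(31)
  pairs <- grid_pairs(truth)
  t <- fit_field_transform(pairs)
  expect_equal(t$ax, truth$ax, tolerance = 1e-6)
  expect_equal(t$ay, truth$ay, tolerance = 1e-6)
  qc <- attr(t, "qc")
  expect_lt(qc$median_nm, 1e-6)
})

test_that("closed-form least squares equals Levenberg-Marquardt refinement", {
  set.seed(12)
  truth <- random_cubic_transform(13)
  pairs <- grid_pairs(truth)
  pairs$xp <- pairs$xp + rnorm(nrow(pairs), 0, 0.05)
  pairs$yp <- pairs$yp + rnorm(nrow(pairs), 0, 0.05)
  t_qr <- fit_field_transform(pairs)
  B <- spectralSMLM:::poly3_basis(pairs$x, pairs$y)
  lm_fit <- minpack.lm::nls.lm(par = rep(0, 10),
                               fn = function(a) pairs$xp - as.vector(B %*% a))
  expect_equal(t_qr$ax, unname(lm_fit$par), tolerance = 1e-6)
})

test_that("applying transforms matches direct polynomial evaluation", {
  expect_equal(apply_field_transform(identity_transform(),
                                     data.frame(x = 3.25, y = -7.5)),
               data.frame(x = 3.25, y = -7.5))
  # identity plus zero-order terms: a pure translation by (5, -3)
  shift <- identity_transform()
  shift$ax[10] <- 5
  shift$ay[10] <- -3
  got <- apply_field_transform(shift, data.frame(x = 10, y = 20))
  expect_equal(got, data.frame(x = 15, y = 17))

  t <- random_cubic_transform(77)
  x <- 12.5; y <- 40.25
  manual_x <- sum(t$ax * c(x^3, y^3, x^2 * y, x * y^2, x^2, y^2, x * y,
                           x, y, 1))
  manual_y <- sum(t$ay * c(x^3, y^3, x^2 * y, x * y^2, x^2, y^2, x * y,
                           x, y, 1))
  got <- apply_field_transform(t, data.frame(x = x, y = y))
  expect_equal(got$x, manual_x, tolerance = 1e-12)
  expect_equal(got$y, manual_y, tolerance = 1e-12)
})

test_that("degenerate fiducial geometry is rejected with a clear error", {
  pts <- data.frame(x = 1:12, y = 2 * (1:12))    # collinear
  m <- apply_field_transform(identity_transform(), pts)
  pairs <- data.frame(x = pts$x, y = pts$y, xp = m$x, yp = m$y)
  expect_error(fit_field_transform(pairs), "degenerate|rank")
  expect_error(fit_field_transform(pairs[1:5, ]), "at least 10")
})

test_that("registration residuals report constructed offsets exactly", {
  t <- identity_transform()
  pairs <- grid_pairs(t)
  expect_error(registration_residuals(t, pairs[0, ]), "no pairs")
  qc0 <- registration_residuals(t, pairs, pixel_size_nm = 178)
  expect_lt(qc0$median_nm, 1e-9)
  pairs$yp <- pairs$yp + 10 / 178     # exactly 10 nm along y
  qc <- registration_residuals(t, pairs, pixel_size_nm = 178)
  expect_equal(qc$median_nm, 10, tolerance = 1e-9)
  expect_equal(qc$max_nm, 10, tolerance = 1e-9)
})

test_that("jittered 7x7 grids register to about the injected jitter", {
  meds <- sapply(1:5, function(s)
    run_registration_benchmark(seed = s)$median_nm)
  # residuals reflect the two-channel 7 nm/axis jitter (Rayleigh-like
  # median ~10 nm after absorbing 20 of 98 degrees of freedom); individual
  # seeds scatter around that
  expect_lte(median(meds), 12)
  expect_true(all(meds >= 4 & meds <= 14))
})

test_that("zero-order updates translate the transform exactly", {
  t <- random_cubic_transform(3)
  fs <- list(x = 20, y = 30)
  fp <- apply_field_transform(t, data.frame(x = fs$x, y = fs$y))
  # fiducial already consistent: nothing changes
  t2 <- update_transform_offset(t, fs, list(x = fp$x, y = fp$y))
  expect_equal(t2$ax, t$ax, tolerance = 1e-12)
  expect_equal(t2$ay, t$ay, tolerance = 1e-12)
  # a pure session shift of (+2, -1) px moves only the zero-order terms
  t3 <- update_transform_offset(t, fs, list(x = fp$x + 2, y = fp$y - 1))
  expect_equal(t3$ax[10] - t$ax[10], 2, tolerance = 1e-12)
  expect_equal(t3$ay[10] - t$ay[10], -1, tolerance = 1e-12)
  expect_equal(t3$ax[1:9], t$ax[1:9])
  expect_equal(t3$ay[1:9], t$ay[1:9])
  # random shift: the updated transform lands the fiducial at the expected
  # displacement along the dispersion axis
  set.seed(44)
  shift <- rnorm(2)
  t4 <- update_transform_offset(t, fs,
                                list(x = fp$x + shift[1],
                                     y = fp$y + shift[2]),
                                expected_distance_px = 2.5)
  fp4 <- apply_field_transform(t4, data.frame(x = fs$x, y = fs$y))
  expect_equal((fp$y + shift[2]) - fp4$y, 2.5, tolerance = 1e-9)
  expect_equal(fp4$x, fp$x + shift[1], tolerance = 1e-9)
})

test_that("transforms round-trip through their text serialization", {
  t <- random_cubic_transform(9)
  path <- tempfile()
  write_field_transform(t, path)
  back <- read_field_transform(path)
  expect_equal(back$ax, t$ax, tolerance = 1e-15)
  expect_equal(back$ay, t$ay, tolerance = 1e-15)
  file.remove(path)
})

test_that("calibration grids pair by nearest neighbour after coarse shift", {
  set.seed(6)
  g <- seq(5, 59, length.out = 7)
  pts <- expand.grid(x = g, y = g)
  t <- default_field_transform()
  m <- apply_field_transform(t, pts)
  perm <- sample(nrow(pts))
  pairs <- pair_calibration_points(pts, m[perm, ])
  expect_equal(nrow(pairs), 49)
  t_fit <- fit_field_transform(pairs)
  expect_equal(t_fit$ax, t$ax, tolerance = 1e-6)
})

test_that("drift traces recover injected drift and average fiducials", {
  set.seed(17)
  n <- 1000
  drift_x <- 0.01 * (0:(n - 1))
  loc_sd <- 0.05
  fid <- data.frame(frame = 0:(n - 1),
                    x = 10 + drift_x + rnorm(n, 0, loc_sd),
                    y = 20 + rnorm(n, 0, loc_sd),
                    track_id = 1)
  trace <- estimate_drift(localization_table(fid), smoothing_window = 50)
  expect_equal(nrow(trace), n)
  expect_equal(trace$dx[1], 0)
  expect_equal(trace$dx[n], 10, tolerance = 0.5)
  expect_lt(max(abs(trace$dy)), 3 * loc_sd)

  # two fiducials sharing the drift: averaged trace has lower variance
  fid2 <- rbind(fid,
                data.frame(frame = 0:(n - 1),
                           x = 40 + drift_x + rnorm(n, 0, loc_sd),
                           y = 45 + rnorm(n, 0, loc_sd), track_id = 2))
  trace2 <- estimate_drift(localization_table(fid2), smoothing_window = 50)
  resid1 <- trace$dx - drift_x
  resid2 <- trace2$dx - drift_x
  expect_lt(var(resid2), var(resid1))
})

test_that("static fiducials give a null drift trace", {
  set.seed(18)
  n <- 200
  loc_sd <- 0.05
  fid <- data.frame(frame = 0:(n - 1), x = 30 + rnorm(n, 0, loc_sd),
                    y = 12 + rnorm(n, 0, loc_sd), track_id = 1)
  trace <- estimate_drift(localization_table(fid), smoothing_window = 50)
  expect_lt(max(abs(c(trace$dx, trace$dy))), 3 * loc_sd)
  expect_error(estimate_drift(localization_table()), "no fiducial")
})

test_that("drift correction shifts coordinates and nothing else", {
  tab <- localization_table(data.frame(frame = c(0, 1, 2), x = c(1, 2, 3),
                                       y = c(4, 5, 6), photons = 100))
  zero <- data.frame(frame = 0:2, dx = 0, dy = 0)
  expect_equal(apply_drift_correction(tab, zero)$x, tab$x)
  const <- data.frame(frame = 0:2, dx = 1, dy = 1)
  corr <- apply_drift_correction(tab, const)
  expect_equal(corr$x, tab$x - 1)
  expect_equal(corr$y, tab$y - 1)
  expect_equal(corr$photons, tab$photons)
  short <- data.frame(frame = 0:1, dx = 0, dy = 0)
  expect_error(apply_drift_correction(tab, short), "cover")
})

test_that("drift-corrected pair distances of a fixed fiducial stay put", {
  set.seed(23)
  n <- 400
  t <- default_field_transform()
  loc_sd <- 0.05
  drift_lower <- 0.008 * (0:(n - 1))
  drift_upper <- -0.005 * (0:(n - 1))
  pos <- data.frame(x = 30, y = 30)
  mapped <- apply_field_transform(t, pos)
  lower <- data.frame(frame = 0:(n - 1),
                      x = pos$x + drift_lower + rnorm(n, 0, loc_sd),
                      y = pos$y + rnorm(n, 0, loc_sd), track_id = 1)
  upper <- data.frame(frame = 0:(n - 1),
                      x = mapped$x + rnorm(n, 0, loc_sd),
                      y = mapped$y + drift_upper + rnorm(n, 0, loc_sd),
                      track_id = 1)
  lower_c <- apply_drift_correction(
    localization_table(lower), estimate_drift(localization_table(lower)))
  upper_c <- apply_drift_correction(
    localization_table(upper), estimate_drift(localization_table(upper)))
  d <- apply_field_transform(t, lower_c)
  pair_dist <- upper_c$y - d$y
  # corrected pair distance is time-invariant within localization noise
  late <- mean(pair_dist[(n - 50):n])
  early <- mean(pair_dist[1:50])
  expect_lt(abs(late - early), 2 * loc_sd)
})
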