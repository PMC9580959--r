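test_that("the crossing scenario sweeps the prescribed separations", {
  scen <- make_crossing_scenario(step_nm_per_frame = 10, n_frames = 320)
  mover <- scen$emitters[[2]]$traj
  static <- scen$emitters[[1]]$traj
  travel_nm <- (max(mover$x_px) - min(mover$x_px)) * 160
  expect_equal(travel_nm, 3190)           # 319 steps of 10 nm
  sep_nm <- (mover$x_px - static$x_px) * 160
  expect_equal(range(sep_nm), c(-1600, 1590))
  expect_equal(sum(abs(sep_nm) <= 500), 101)
  # z = 0 keeps both emitters at focus, where the width curves cross
  w <- astig_sigma_at_z(default_astig_calibration(), 0)
  expect_equal(w$sigma_x, w$sigma_y, tolerance = 1e-9)
})

test_that("multi-species scenarios keep their bookkeeping straight", {
  scen <- make_multispecies_scenario(n_emitters = 50, n_frames = 3, seed = 2)
  expect_length(scen$emitters, 50)
  lam <- vapply(scen$emitters, function(e) e$wavelength_nm, numeric(1))
  expect_true(all(lam %in% c(525, 565, 605, 655, 705)))
  sim <- render_dual_stacks(scen, optics_model(field_px = 160),
                            camera_noise_model(), seed = 2)
  truth <- as.data.frame(sim$truth)
  expect_equal(length(unique(truth$id)), 50)
  expect_equal(nrow(truth), 150)

  # at the reference wavelength the spectral displacement vanishes
  ref <- make_multispecies_scenario(wavelengths = 683, n_emitters = 5,
                                    n_frames = 1, seed = 3, field_px = 64)
  sim_ref <- render_dual_stacks(ref, optics_model(), camera_noise_model(),
                                seed = 3)
  tr <- as.data.frame(sim_ref$truth)
  mapped <- apply_field_transform(optics_model()$transform,
                                  data.frame(x = tr$x, y = tr$y))
  expect_lt(max(abs(tr$y_spectral - mapped$y)), 1e-9)
})

test_that("spectral crowding grows monotonically with density", {
  cal <- spectral_calibration()
  zone <- zone_from_wavelengths(cal, 500, 730, dx_px = 2)
  crowding <- sapply(c(20, 60, 140), function(n) {
    set.seed(9)
    x <- runif(n, 0, 256)
    y <- runif(n, 0, 256)
    lam <- sample(c(525, 565, 605, 655, 705), n, replace = TRUE)
    ys <- y + (lam - cal$lambda0_nm) / cal$alpha_nm_per_px
    shared <- vapply(seq_len(n), function(i) {
      d <- ys - y[i]
      sum(abs(x - x[i]) <= zone$dx_px & d >= zone$dmin_px &
            d <= zone$dmax_px) >= 2
    }, logical(1))
    mean(shared)
  })
  expect_true(all(diff(crowding) > 0))
})

test_that("background-only stacks match the noise model statistics", {
  scen <- simulation_scenario(list(), 10, 64, 1)
  noise <- camera_noise_model(baseline_counts = 100, readout_std_counts = 2,
                              background_photons = 10)
  sim <- render_dual_stacks(scen, optics_model(), noise, seed = 10)
  px <- as.vector(sim$spatial$frames)
  expect_equal(mean(px), 110, tolerance = 110 * 0.01)
  pred_sd <- sqrt(10 + 2^2 + 1 / 12)   # shot + readout + rounding
  expect_equal(sd(px), pred_sd, tolerance = pred_sd * 0.05)
})

test_that("noiseless rendering conserves the photon flux", {
  optics <- optics_model(field_px = 64)
  noise <- camera_noise_model(baseline_counts = 50, readout_std_counts = 0,
                              background_photons = 0, shot_noise = FALSE,
                              gain_counts_per_photon = 2)
  scen <- make_multispecies_scenario(wavelengths = 683, n_emitters = 1,
                                     n_frames = 1, field_px = 64, seed = 4,
                                     photons = 800)
  sim <- render_dual_stacks(scen, optics, noise, seed = 4)
  total <- sum(sim$spatial$frames[, , 1] - 50)
  expect_equal(total, 800 * 2, tolerance = 800 * 2 * 0.005)
})

test_that("the dispersion gap between 655 and 705 nm is ~6.2 px", {
  scen <- simulation_scenario(list(
    list(wavelength_nm = 655, photons = 500,
         traj = data.frame(frame = 0, x_px = 32, y_px = 32, z_nm = 0)),
    list(wavelength_nm = 705, photons = 500,
         traj = data.frame(frame = 0, x_px = 32, y_px = 32, z_nm = 0))),
    1, 64, 1)
  sim <- render_dual_stacks(scen, optics_model(), camera_noise_model(),
                            seed = 1)
  tr <- as.data.frame(sim$truth)
  gap <- abs(diff(tr$y_spectral))
  expect_equal(gap, 50 / 8.1, tolerance = 1e-9)
})

test_that("rendering is bit-exact reproducible per seed", {
  scen <- make_multispecies_scenario(n_emitters = 4, n_frames = 3,
                                     field_px = 64, seed = 6)
  a <- render_dual_stacks(scen, optics_model(field_px = 64),
                          camera_noise_model(), seed = 6)
  b <- render_dual_stacks(scen, optics_model(field_px = 64),
                          camera_noise_model(), seed = 6)
  expect_identical(a$spatial$frames, b$spatial$frames)
  expect_identical(a$spectral$frames, b$spectral$frames)
  c <- render_dual_stacks(scen, optics_model(field_px = 64),
                          camera_noise_model(), seed = 7)
  expect_false(identical(a$spatial$frames, c$spatial$frames))
})

test_that("localization errors score constructed offsets exactly", {
  truth <- data.frame(frame = rep(0:4, each = 3),
                      id = rep(1:3, 5),
                      x = runif(15, 5, 50), y = runif(15, 5, 50),
                      wavelength = 655)
  est <- localization_table(data.frame(frame = truth$frame, x = truth$x,
                                       y = truth$y))
  perfect <- localization_error(est, truth, 500, 160)
  expect_equal(perfect$mean_error_nm, 0)
  expect_equal(perfect$false_positives, 0)
  expect_equal(perfect$false_negatives, 0)

  est30 <- localization_table(data.frame(frame = truth$frame,
                                         x = truth$x + 30 / 160,
                                         y = truth$y))
  off <- localization_error(est30, truth, 500, 160)
  expect_equal(off$mean_error_nm, 30, tolerance = 1e-9)
})

test_that("species-aware scoring pins estimates to their claimed species", {
  truth <- data.frame(frame = 0, id = 1:2, x = c(10, 12), y = 10,
                      wavelength = c(655, 705))
  # spatially near emitter 1 but claiming emitter 2's wavelength
  est <- localization_table(data.frame(frame = 0, x = c(10.05, 12.05),
                                       y = 10, wavelength = c(705, 655)))
  free <- localization_error(est, truth, 900, 160, species_aware = FALSE)
  aware <- localization_error(est, truth, 900, 160, species_aware = TRUE)
  expect_lt(free$mean_error_nm, 20)
  expect_gt(aware$mean_error_nm, 250)    # ~2 px * 160 nm cross distance
})

test_that("Brownian scenarios produce the prescribed step statistics", {
  scen0 <- make_brownian_scenario(0, n_tracks = 3, n_frames = 10, seed = 8)
  tr <- scen0$emitters[[1]]$traj
  expect_equal(var(tr$x_px), 0)

  D <- 0.1; dt <- 0.05
  scen <- make_brownian_scenario(D, n_tracks = 150, n_frames = 10,
                                 dt_s = dt, seed = 9, field_px = 2048)
  steps2 <- unlist(lapply(scen$emitters, function(e)
    diff(e$traj$x_px)^2 + diff(e$traj$y_px)^2)) * 0.16^2
  expected <- 4 * D * dt
  se <- sd(steps2) / sqrt(length(steps2))
  expect_lt(abs(mean(steps2) - expected), 3 * se)
})
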