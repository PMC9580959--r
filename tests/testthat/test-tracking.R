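test_that("a quietly moving molecule yields one full-length track", {
  set.seed(61)
  tab <- localization_table(data.frame(frame = 0:9,
                                       x = 10 + cumsum(rnorm(10, 0, 0.3)),
                                       y = 10 + cumsum(rnorm(10, 0, 0.3))))
  tracks <- link_tracks(tab, max_disp_px = 5, max_gap = 2)
  expect_length(tracks, 1)
  expect_equal(nrow(tracks[[1]]$records), 10)
})

test_that("frame-to-frame linking is optimal for small frames", {
  set.seed(62)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    a <- data.frame(x = runif(n, 0, 20), y = runif(n, 0, 20))
    b <- data.frame(x = a$x + rnorm(n, 0, 1), y = a$y + rnorm(n, 0, 1))
    tab <- localization_table(data.frame(frame = rep(0:1, each = n),
                                         x = c(a$x, b$x), y = c(a$y, b$y)))
    tracks <- link_tracks(tab, max_disp_px = 50, max_gap = 0)
    linked <- Filter(function(tr) nrow(tr$records) == 2, tracks)
    got <- sum(vapply(linked, function(tr) {
      sum(diff(tr$records$x)^2 + diff(tr$records$y)^2)
    }, numeric(1)))
    cost <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
    bf <- spectralSMLM:::brute_force_assignment(cost)
    expect_equal(got, bf$cost, tolerance = 1e-9)
    expect_lte(got, greedy_cost(cost) + 1e-9)
  }
})

test_that("the annealing solver agrees with the exact one on small frames", {
  set.seed(63)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    tab <- localization_table(data.frame(
      frame = rep(0:3, each = n),
      x = runif(4 * n, 0, 15) , y = runif(4 * n, 0, 15)))
    ex <- link_tracks(tab, max_disp_px = 50, max_gap = 0, method = "exact")
    an <- link_tracks(tab, max_disp_px = 50, max_gap = 0, method = "anneal",
                      seed = rep)
    cost_of <- function(tracks) sum(vapply(tracks, function(tr) {
      if (nrow(tr$records) < 2) return(0)
      sum(diff(tr$records$x)^2 + diff(tr$records$y)^2)
    }, numeric(1)))
    expect_equal(cost_of(an), cost_of(ex), tolerance = 1e-6)
  }
})

test_that("linking bridges gaps and conserves every record", {
  tab <- localization_table(data.frame(frame = c(0, 1, 3, 4),
                                       x = c(5, 5.2, 5.5, 5.6),
                                       y = c(5, 5.1, 5.2, 5.4)))
  tracks <- link_tracks(tab, max_disp_px = 2, max_gap = 2)
  expect_length(tracks, 1)          # the 1-frame gap is bridged
  tracks2 <- link_tracks(tab, max_disp_px = 2, max_gap = 0)
  expect_length(tracks2, 2)         # without gap closing it splits
  n_rec <- sum(vapply(tracks2, function(tr) nrow(tr$records), integer(1)))
  expect_equal(n_rec, nrow(tab))
})

test_that("linking is invariant to within-frame record order", {
  set.seed(64)
  df <- data.frame(frame = rep(0:9, each = 4),
                   x = rep(c(2, 12, 22, 32), 10) + rnorm(40, 0, 0.2),
                   y = rep(c(2, 12, 22, 32), 10) + rnorm(40, 0, 0.2))
  shuffled <- df[order(df$frame, runif(nrow(df))), ]
  sig <- function(tracks) {
    sets <- lapply(tracks, function(tr)
      sort(paste(tr$records$frame, round(tr$records$x, 9))))
    sort(vapply(sets, paste, "", collapse = "|"))
  }
  t1 <- link_tracks(localization_table(df), max_disp_px = 5)
  t2 <- link_tracks(localization_table(shuffled), max_disp_px = 5)
  expect_identical(sig(t1), sig(t2))
})

test_that("MSD curves obey the closed forms for simple motions", {
  static <- data.frame(frame = 0:19, x = 5, y = 5)
  res <- compute_msd(static, 160, 0.05)
  expect_true(all(res$msd$msd_um2 == 0))

  # ballistic motion: MSD(tau) = v^2 tau^2
  v_um_s <- 0.8
  dt <- 0.05
  step_px <- v_um_s * dt / 0.16
  ball <- data.frame(frame = 0:29, x = 1 + step_px * (0:29), y = 7)
  res <- compute_msd(ball, 160, dt)
  expect_equal(res$msd$msd_um2, (v_um_s * res$msd$lag_s)^2,
               tolerance = 1e-12)

  short <- data.frame(frame = 0:2, x = 1:3, y = 1:3)
  expect_identical(compute_msd(short)$flagged, "too_short")
})

test_that("Brownian ensembles satisfy the Einstein relation", {
  D <- 0.1; dt <- 0.05
  scen <- make_brownian_scenario(D, n_tracks = 300, n_frames = 12,
                                 dt_s = dt, seed = 71, field_px = 2048)
  tab <- as.data.frame(scenario_to_table(scen))
  msd1 <- vapply(split(tab, tab$track_id), function(tr)
    compute_msd(tr, 160, dt)$msd$msd_um2[1], numeric(1))
  expected <- 4 * D * dt                 # 0.02 um^2 at the first lag
  se <- sd(msd1) / sqrt(length(msd1))
  expect_lt(abs(mean(msd1) - expected), 3 * se + 1e-6)
})

test_that("diffusion fits recover exact and simulated coefficients", {
  # exact line: MSD = 4 D tau
  D <- 0.12
  msd <- data.frame(lag_s = (1:6) * 0.05, msd_um2 = 4 * D * (1:6) * 0.05,
                    n_pairs = 10)
  res <- structure(list(msd = msd, D = NA_real_, dimensionality = 2L,
                        flagged = NULL), class = "DiffusionResult")
  expect_equal(fit_diffusion(res)$D, D, tolerance = 1e-12)

  # negative slopes clamp to zero and are flagged
  res$msd$msd_um2 <- rev(res$msd$msd_um2)
  neg <- fit_diffusion(res)
  expect_equal(neg$D, 0)
  expect_identical(neg$flagged, "negative_slope")

  # long-track parameter recovery within 5%
  for (D_true in c(0.06, 0.12)) {
    scen <- make_brownian_scenario(D_true, n_tracks = 40, n_frames = 1000,
                                   dt_s = 0.05, seed = 72,
                                   field_px = 4096)
    tab <- as.data.frame(scenario_to_table(scen))
    Ds <- vapply(split(tab, tab$track_id), function(tr)
      fit_diffusion(compute_msd(tr, 160, 0.05))$D, numeric(1))
    expect_lt(abs(median(Ds) - D_true) / D_true, 0.05)
  }
})

test_that("static tracks with localization noise stay at the noise floor", {
  set.seed(73)
  sloc_um <- 0.015
  dt <- 0.05
  Ds <- replicate(100, {
    tr <- data.frame(frame = 0:29,
                     x = 10 + rnorm(30, 0, sloc_um / 0.16),
                     y = 10 + rnorm(30, 0, sloc_um / 0.16))
    fit_diffusion(compute_msd(tr, 160, dt))$D
  })
  floor_scale <- sloc_um^2 / dt     # naive attribution of noise to motion
  expect_lt(median(Ds), floor_scale)
})

test_that("species diffusion summaries separate and order populations", {
  scen <- make_brownian_scenario(c(0.12, 0.06), n_tracks = 100,
                                 n_frames = 60, dt_s = 0.05, seed = 74,
                                 field_px = 2048,
                                 wavelengths = c(655, 705))
  tab <- as.data.frame(scenario_to_table(scen))
  tracks <- lapply(split(tab, tab$track_id), function(d)
    structure(list(track_id = d$track_id[1], records = d,
                   species = d$species[1]), class = "Track"))
  summ <- species_split_diffusion(unname(tracks), 160, 0.05)
  expect_setequal(summ$species, c("655", "705"))
  expect_gt(summ$median_D[summ$species == "655"],
            summ$median_D[summ$species == "705"])
  expect_equal(summ$median_D[summ$species == "655"], 0.12, tolerance = 0.2)

  # single-species reduction equals the plain median
  one <- species_split_diffusion(unname(tracks[tab$species[
    match(names(tracks), tab$track_id)] == "655"]), 160, 0.05)
  expect_equal(nrow(one), 1L)

  # empty labels are excluded with a warning
  tracks[[1]]$species <- ""
  expect_warning(species_split_diffusion(unname(tracks), 160, 0.05),
                 "empty species")
})

test_that("identical populations are statistically indistinguishable", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    scen <- make_brownian_scenario(c(0.1, 0.1), n_tracks = 60,
                                   n_frames = 80, dt_s = 0.05, seed = 100 + s,
                                   field_px = 2048,
                                   wavelengths = c(655, 705))
    tab <- as.data.frame(scenario_to_table(scen))
    Ds <- lapply(split(tab, tab$species), function(d)
      vapply(split(d, d$track_id), function(tr)
        fit_diffusion(compute_msd(tr, 160, 0.05))$D, numeric(1)))
    p <- stats::wilcox.test(Ds[[1]], Ds[[2]])$p.value
    if (p > 0.05) hits <- hits + 1
  }
  # under the null ~95% of seeds should accept; 17/20 rejects the
  # alternative that the two identical populations look different
  expect_gte(hits, 17)
})
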