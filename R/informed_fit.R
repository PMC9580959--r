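# Analytic Jacobian of the cubic field transform at a point.
transform_jacobian <- function(t, x, y) {
  dxdx <- 3 * t$ax[1] * x^2 + 2 * t$ax[3] * x * y + t$ax[4] * y^2 +
    2 * t$ax[5] * x + t$ax[7] * y + t$ax[8]
  dxdy <- 3 * t$ax[2] * y^2 + t$ax[3] * x^2 + 2 * t$ax[4] * x * y +
    2 * t$ax[6] * y + t$ax[7] * x + t$ax[9]
  dydx <- 3 * t$ay[1] * x^2 + 2 * t$ay[3] * x * y + t$ay[4] * y^2 +
    2 * t$ay[5] * x + t$ay[7] * y + t$ay[8]
  dydy <- 3 * t$ay[2] * y^2 + t$ay[3] * x^2 + 2 * t$ay[4] * x * y +
    2 * t$ay[6] * y + t$ay[7] * x + t$ay[9]
  matrix(c(dxdx, dydx, dxdy, dydy), 2, 2)
}

#' Invert a field transform at given spectral-channel points
#'
#' Gauss-Newton iteration using the analytic Jacobian; used to map spectral
#' localizations back to spatial-channel coordinates (e.g. for multi-fit
#' initialization).
#'
#' @param t a `FieldTransform`.
#' @param points data.frame with spectral `x`, `y`.
#' @param start optional data.frame of starting spatial coordinates.
#' @param tol convergence tolerance (px).
#' @return data.frame of spatial-channel `x`, `y`.
#' @export
invert_field_transform <- function(t, points, start = NULL, tol = 1e-10) {
  n <- nrow(points)
  out <- data.frame(x = numeric(n), y = numeric(n))
  for (i in seq_len(n)) {
    p <- if (!is.null(start)) c(start$x[i], start$y[i])
         else c(points$x[i], points$y[i])
    for (it in 1:50) {
      f <- apply_field_transform(t, data.frame(x = p[1], y = p[2]))
      r <- c(points$x[i] - f$x, points$y[i] - f$y)
      if (max(abs(r)) < tol) break
      J <- transform_jacobian(t, p[1], p[2])
      p <- p + solve(J, r)
    }
    out$x[i] <- p[1]
    out$y[i] <- p[2]
  }
  out
}

#' Decide single- versus two-emitter fitting from the spectral channel
#'
#' Counts the spectral-channel localizations inside the pair search zone
#' around the transformed spatial seed. `n = 0`: single fit without
#' wavelength; `n = 1`: single fit; `n >= 2`: two-emitter fit using the two
#' brightest candidates (the emitter count is capped at 2; a warning is
#' logged beyond that). Candidates closer than `min_spectral_sep_px` along
#' the dispersion axis are merged (spectrally unresolvable) before
#' counting.
#'
#' @param spatial_seed list/row with spatial-channel `x`, `y`.
#' @param spectral_frame data.frame of spectral-channel localizations of
#'   the same frame.
#' @param t a `FieldTransform`.
#' @param zone a `PairSearchZone`.
#' @param dispersion_axis `"y"` or `"x"`.
#' @param min_spectral_sep_px merge radius along the dispersion axis.
#' @return a `MultiFitDecision`: `list(n_emitters, candidates,
#'   init_perp_px)` where `init_perp_px` are the candidates' coordinates
#'   perpendicular to the dispersion axis (spectral px).
#' @export
count_candidates <- function(spatial_seed, spectral_frame, t, zone,
                             dispersion_axis = "y",
                             min_spectral_sep_px = 2) {
  tr <- apply_field_transform(t, data.frame(x = spatial_seed$x,
                                            y = spatial_seed$y))
  if (nrow(spectral_frame) == 0) {
    return(structure(list(n_emitters = 0L, candidates = spectral_frame,
                          init_perp_px = numeric(0)),
                     class = "MultiFitDecision"))
  }
  if (dispersion_axis == "y") {
    disp <- spectral_frame$y - tr$y
    perp <- spectral_frame$x - tr$x
  } else {
    disp <- spectral_frame$x - tr$x
    perp <- spectral_frame$y - tr$y
  }
  inz <- abs(perp) <= zone$dx_px & disp >= zone$dmin_px & disp <= zone$dmax_px
  cand <- spectral_frame[inz, , drop = FALSE]
  cand$.disp <- disp[inz]
  cand$.perp <- perp[inz]
  if (nrow(cand) > 1) {
    # merge spectrally unresolvable candidates, keeping the brighter
    o <- order(-ifelse(is.na(cand$photons), 0, cand$photons))
    cand <- cand[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))[-1]) {
      if (any(keep[seq_len(i - 1)] &
              abs(cand$.disp[seq_len(i - 1)] - cand$.disp[i]) <
                min_spectral_sep_px))
        keep[i] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  n <- nrow(cand)
  if (n > 2) {
    warning("more than two spectral candidates in the pair zone; ",
            "using the two brightest")
    cand <- cand[seq_len(2), , drop = FALSE]
    n <- 2L
  }
  structure(list(n_emitters = as.integer(min(n, 2)),
                 candidates = cand,
                 init_perp_px = if (n) cand$.perp else numeric(0)),
            class = "MultiFitDecision")
}

# Sum of two pixel-integrated elliptical Gaussians + common offset.
# p = (x1, y1, sx1, sy1, N1, x2, y2, sx2, sy2, N2, b)
gauss2d_two_model <- function(p, xs, ys) {
  g1 <- p[5] * outer(int_gauss1d(ys, p[2], p[4]),
                     int_gauss1d(xs, p[1], p[3]))
  g2 <- p[10] * outer(int_gauss1d(ys, p[7], p[9]),
                      int_gauss1d(xs, p[6], p[8]))
  g1 + g2 + p[11]
}

#' Fit two overlapping emitters around one spatial seed
#'
#' Least-squares fit of a sum of two elliptical Gaussians with a common
#' offset over an enlarged window. With a `MultiFitDecision` (spectrally
#' informed), the coordinates perpendicular to the dispersion axis are
#' initialized from the spectral candidates mapped back through the
#' transform, both along-axis coordinates start at the seed, and amplitudes
#' are split in proportion to the candidates' intensities. Without spectral
#' information (`decision = NULL`, the "systematic" mode) the emitter count
#' is unknown and the components start symmetrically one pixel either side
#' of the blob centroid with equal amplitudes and free widths.
#'
#' @param image 2-D matrix of counts.
#' @param seed list/row with 0-based `x`, `y` (spatial px).
#' @param decision a `MultiFitDecision` with `n_emitters == 2`, or `NULL`.
#' @param params a [detection_params()]; the multi-fit window has radius
#'   `roi_radius_px + 2`.
#' @param t,dispersion_axis transform and axis used to map candidate
#'   coordinates back (informed mode only).
#' @param frame frame index stored in the records.
#' @return two-row localization record data.frame (goodness 0 flags a
#'   failed fit).
#' @export
fit_two_emitters <- function(image, seed, decision = NULL,
                             params = detection_params(), t = NULL,
                             dispersion_axis = "y", frame = 0) {
  r <- params$roi_radius_px + 2L
  cx <- round(seed$x)
  cy <- round(seed$y)
  nr <- nrow(image)
  nc <- ncol(image)
  cx <- min(max(cx, r), nc - 1 - r)
  cy <- min(max(cy, r), nr - 1 - r)
  xs <- (cx - r):(cx + r)
  ys <- (cy - r):(cy + r)
  roi <- image[ys + 1, xs + 1]
  p_single <- init_from_moments(roi, xs, ys)
  informed <- !is.null(decision) && decision$n_emitters == 2
  if (informed) {
    cand <- decision$candidates
    # map candidate spectral positions back to spatial coordinates
    back <- invert_field_transform(
      t, data.frame(x = cand$x, y = cand$y),
      start = data.frame(x = rep(seed$x, 2), y = rep(seed$y, 2)))
    if (dispersion_axis == "y") {
      x_init <- back$x
      y_init <- rep(seed$y, 2)
    } else {
      x_init <- rep(seed$x, 2)
      y_init <- back$y
    }
    ph <- ifelse(is.na(cand$photons) | cand$photons <= 0, 1, cand$photons)
    a_frac <- ph / sum(ph)
  } else {
    # blind initialization: the emitter count is unknown, so the two
    # components start symmetrically about the blob centroid with equal
    # amplitudes, the standard naive always-two initialization
    x_init <- p_single[1] + c(-1, 1)
    y_init <- rep(p_single[2], 2)
    a_frac <- c(0.5, 0.5)
  }
  A0 <- max(p_single[5], 1)
  if (informed) {
    # the emitter count and perpendicular coordinates are known from the
    # spectral channel: constrain the fit accordingly. The width along the
    # non-separated axis estimates the PSF width far better than the
    # blob moments along the separation axis.
    # The spectral channel measured each component's perpendicular
    # coordinate to a few tens of nm; the search is bounded to a few
    # standard deviations of that measurement. Widths are bounded to the
    # physically plausible PSF range rather than left free: free widths let
    # one component swallow its neighbour in near-degenerate geometries.
    s0 <- min(p_single[3:4])
    s_lo <- 0.75 * s0
    s_hi <- 1.6 * s0
    perp_bound <- 0.5
    p0 <- c(x_init[1], y_init[1], s0, s0, A0 * a_frac[1],
            x_init[2], y_init[2], s0, s0, A0 * a_frac[2],
            p_single[6])
    if (dispersion_axis == "y") {
      lower <- c(x_init[1] - perp_bound, min(ys) - 1, s_lo, s_lo, 0.1 * A0,
                 x_init[2] - perp_bound, min(ys) - 1, s_lo, s_lo, 0.1 * A0,
                 -Inf)
      upper <- c(x_init[1] + perp_bound, max(ys) + 1, s_hi, s_hi, Inf,
                 x_init[2] + perp_bound, max(ys) + 1, s_hi, s_hi, Inf, Inf)
    } else {
      lower <- c(min(xs) - 1, y_init[1] - perp_bound, s_lo, s_lo, 0.1 * A0,
                 min(xs) - 1, y_init[2] - perp_bound, s_lo, s_lo, 0.1 * A0,
                 -Inf)
      upper <- c(max(xs) + 1, y_init[1] + perp_bound, s_hi, s_hi, Inf,
                 max(xs) + 1, y_init[2] + perp_bound, s_hi, s_hi, Inf, Inf)
    }
  } else {
    s0 <- max(p_single[3:4])
    p0 <- c(x_init[1], y_init[1], s0, s0, A0 * a_frac[1],
            x_init[2], y_init[2], s0, s0, A0 * a_frac[2],
            p_single[6])
    lower <- c(min(xs) - 1, min(ys) - 1, 0.5, 0.5, 0,
               min(xs) - 1, min(ys) - 1, 0.5, 0.5, 0, -Inf)
    upper <- c(max(xs) + 1, max(ys) + 1, 6, 6, Inf,
               max(xs) + 1, max(ys) + 1, 6, 6, Inf, Inf)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0,
                       fn = function(p) as.vector(roi - gauss2d_two_model(p, xs, ys)),
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 150, ftol = 1e-8, ptol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to a single fit, flagged
    f1 <- fit_single(image, seed, params, frame)
    f1$goodness <- 0
    return(rbind(f1, f1))
  }
  p <- fit$par
  ss_res <- sum(fit$fvec^2)
  ss_tot <- sum((roi - mean(roi))^2)
  goodness <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 0
  rbind(
    new_record(frame, p[1], p[2], sigma_x = p[3], sigma_y = p[4],
               photons = p[5] / params$gain,
               background = p[11], goodness = goodness),
    new_record(frame, p[6], p[7], sigma_x = p[8], sigma_y = p[9],
               photons = p[10] / params$gain,
               background = p[11], goodness = goodness))
}

#' Full per-frame dual-channel localization
#'
#' Detects and fits on both channels, then, per spatial seed, chooses
#' single- or two-emitter fitting:
#' * `mode = "informed"` (default): spectral candidates in the pair zone are
#'   partitioned to their nearest spatial seed; a seed with two candidates
#'   is fit with two Gaussians initialized from the candidates' positions
#'   perpendicular to the dispersion axis, otherwise a single Gaussian.
#' * `mode = "single"`: always single-emitter fitting.
#' * `mode = "systematic"`: always two-emitter fitting, without spectral
#'   information.
#' Fitted records are then paired with the spectral localizations for
#' wavelength assignment; spatial coordinates are never altered by the
#' spectral steps.
#'
#' @param spatial_image,spectral_image matrices of one synchronized frame
#'   pair.
#' @param t `FieldTransform`.
#' @param zone `PairSearchZone`.
#' @param calib `SpectralCalibration`.
#' @param params `DetectionParams` (shared by both channels).
#' @param astig optional astigmatism calibration for z.
#' @param frame frame index.
#' @param mode fitting policy, see above.
#' @param min_goodness drop fitted records below this goodness.
#' @return a `LocalizationTable` (spatial-channel px) with wavelengths for
#'   paired records.
#' @export
informed_localize_frame <- function(spatial_image, spectral_image, t, zone,
                                    calib = spectral_calibration(),
                                    params = detection_params(),
                                    astig = NULL, frame = 0,
                                    mode = c("informed", "single",
                                             "systematic"),
                                    min_goodness = 0) {
  mode <- match.arg(mode)
  spec_tab <- localize_frame(spectral_image, params, frame)
  spec_df <- as.data.frame(spec_tab)
  spec_df <- spec_df[!is.na(spec_df$sigma_x) & spec_df$goodness > 0, ,
                     drop = FALSE]
  plane <- wavelet_filter(spatial_image, params$wavelet_scale)
  seeds <- detect_spots(plane, params)
  recs <- list()
  if (nrow(seeds)) {
    n_cand <- integer(nrow(seeds))
    cand_of <- vector("list", nrow(seeds))
    if (mode == "informed" && nrow(spec_df)) {
      # partition spectral candidates to their nearest transformed seed
      tr <- apply_field_transform(t, seeds)
      if (calib$dispersion_axis == "y") {
        disp <- outer(spec_df$y, tr$y, "-")
        perp <- outer(spec_df$x, tr$x, "-")
      } else {
        disp <- outer(spec_df$x, tr$x, "-")
        perp <- outer(spec_df$y, tr$y, "-")
      }
      inz <- abs(perp) <= zone$dx_px & disp >= zone$dmin_px &
        disp <= zone$dmax_px
      for (c_i in seq_len(nrow(spec_df))) {
        js <- which(inz[c_i, ])
        if (!length(js)) next
        j <- js[which.min(abs(perp[c_i, js]))]
        cand_of[[j]] <- c(cand_of[[j]], c_i)
      }
      n_cand <- lengths(cand_of)
    }
    for (i in seq_len(nrow(seeds))) {
      seed <- seeds[i, ]
      if (mode == "systematic") {
        recs[[length(recs) + 1L]] <-
          fit_two_emitters(spatial_image, seed, NULL, params,
                           frame = frame)
      } else if (mode == "informed" && n_cand[i] >= 2) {
        ci <- cand_of[[i]]
        cand <- spec_df[ci, , drop = FALSE]
        if (calib$dispersion_axis == "y") {
          tr_i <- apply_field_transform(t, seed)
          cand$.disp <- cand$y - tr_i$y
          cand$.perp <- cand$x - tr_i$x
        } else {
          tr_i <- apply_field_transform(t, seed)
          cand$.disp <- cand$x - tr_i$x
          cand$.perp <- cand$y - tr_i$y
        }
        # spectrally unresolvable candidates collapse to a single fit
        o <- order(-ifelse(is.na(cand$photons), 0, cand$photons))
        cand <- cand[o, , drop = FALSE]
        sep_ok <- abs(diff(sort(cand$.disp[1:2]))) >= 2 ||
          abs(diff(sort(cand$.perp[1:2]))) >= 2
        if (nrow(cand) >= 2 && sep_ok) {
          dec <- structure(list(n_emitters = 2L,
                                candidates = cand[1:2, ],
                                init_perp_px = cand$.perp[1:2]),
                           class = "MultiFitDecision")
          recs[[length(recs) + 1L]] <-
            fit_two_emitters(spatial_image, seed, dec, params, t,
                             calib$dispersion_axis, frame)
        } else {
          recs[[length(recs) + 1L]] <-
            fit_single(spatial_image, seed, params, frame)
        }
      } else {
        recs[[length(recs) + 1L]] <-
          fit_single(spatial_image, seed, params, frame)
      }
    }
  }
  tab <- localization_table(if (length(recs)) do.call(rbind, recs) else NULL)
  if (nrow(tab)) {
    keep <- !is.na(tab$sigma_x) & tab$goodness >= min_goodness
    tab <- localization_table(as.data.frame(tab)[keep, , drop = FALSE])
  }
  if (!is.null(astig) && nrow(tab)) tab <- assign_z(tab, astig)
  if (nrow(tab) && nrow(spec_df)) {
    spec_frame_tab <- localization_table(spec_df, "spectral")
    tab <- pair_localizations(tab, spec_frame_tab, t, zone, calib)
  }
  tab
}
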