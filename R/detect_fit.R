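#' Detection and fitting parameters
#'
#' @param wavelet_scale a-trous plane used for detection (1, 2 or 3);
#'   plane 2 isolates structures at the PSF scale.
#' @param threshold_k detection threshold as a multiple of the robust noise
#'   scale (1.4826 x MAD) of the filtered plane.
#' @param roi_radius_px half-width of the square fitting window, pixels.
#' @param min_separation_px seeds closer than this are merged to the
#'   brighter one.
#' @param gain camera gain in counts per photon, used to convert integrated
#'   signal to photons.
#' @return a `DetectionParams` list.
#' @export
detection_params <- function(wavelet_scale = 2, threshold_k = 4.5,
                             roi_radius_px = 3, min_separation_px = 4,
                             gain = 1) {
  stopifnot(wavelet_scale >= 1, threshold_k > 0, roi_radius_px >= 2,
            min_separation_px >= 0, gain > 0)
  structure(list(wavelet_scale = as.integer(wavelet_scale),
                 threshold_k = threshold_k,
                 roi_radius_px = as.integer(roi_radius_px),
                 min_separation_px = min_separation_px,
                 gain = gain),
            class = "DetectionParams")
}

# Mirror-boundary index for 1-based positions.
reflect_index <- function(i, n) {
  i[i < 1L] <- 2L - i[i < 1L]
  i[i > n] <- 2L * n - i[i > n]
  i
}

# Separable B3-spline smoothing with holes of size `step` (undecimated).
b3_smooth <- function(image, step) {
  k <- c(1, 4, 6, 4, 1) / 16
  off <- step * (-2:2)
  nr <- nrow(image)
  nc <- ncol(image)
  tmp <- matrix(0, nr, nc)
  for (t in 1:5)
    tmp <- tmp + k[t] * image[reflect_index(seq_len(nr) + off[t], nr), ,
                              drop = FALSE]
  out <- matrix(0, nr, nc)
  for (t in 1:5)
    out <- out + k[t] * tmp[, reflect_index(seq_len(nc) + off[t], nc),
                            drop = FALSE]
  out
}

#' A-trous wavelet plane of an image
#'
#' Undecimated B3-spline wavelet decomposition. Plane `i` is the difference
#' between the smoothed approximations at scales `i-1` and `i`; it is
#' band-pass, so constant offsets (and, away from borders, linear ramps)
#' map to zero. Plane 2 responds maximally to spots of roughly the PSF size
#' and is the default detection plane.
#'
#' @param image 2-D numeric matrix with finite entries.
#' @param scale plane index, 1..3.
#' @return matrix of the same size.
#' @export
wavelet_filter <- function(image, scale = 2) {
  stopifnot(is.matrix(image), scale %in% 1:3)
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  sm <- image
  plane <- NULL
  for (s in seq_len(scale)) {
    sm2 <- b3_smooth(sm, 2^(s - 1))
    plane <- sm - sm2
    sm <- sm2
  }
  plane
}

#' Detect spot seeds on a wavelet plane
#'
#' Seeds are 8-neighbour local maxima exceeding `threshold_k` times the
#' robust noise scale (1.4826 x median absolute deviation) of the plane.
#' Seeds closer than `min_separation_px` are merged, keeping the brighter.
#'
#' @param plane filtered image from [wavelet_filter()].
#' @param params a [detection_params()] object.
#' @return data.frame with 0-based integer columns `x` (column), `y` (row)
#'   and the plane `value`; zero rows if nothing detected.
#' @export
detect_spots <- function(plane, params = detection_params()) {
  noise <- stats::mad(plane)          # 1.4826 * MAD by definition
  thr <- params$threshold_k * noise
  nr <- nrow(plane)
  nc <- ncol(plane)
  if (nr < 3 || nc < 3 || all(plane <= thr))
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  core <- plane[2:(nr - 1), 2:(nc - 1)]
  ismax <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    ismax <- ismax & core >= plane[2:(nr - 1) + dy, 2:(nc - 1) + dx]
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  # core[r, c] is plane[r+1, c+1]; its 0-based image coords are (x=c, y=r)
  seeds <- data.frame(x = as.numeric(idx[, 2]), y = as.numeric(idx[, 1]),
                      value = core[idx])
  seeds <- seeds[order(-seeds$value), , drop = FALSE]
  if (params$min_separation_px > 0 && nrow(seeds) > 1) {
    keep <- logical(nrow(seeds))
    for (i in seq_len(nrow(seeds))) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      d2 <- (seeds$x[keep] - seeds$x[i])^2 + (seeds$y[keep] - seeds$y[i])^2
      keep[i] <- all(d2 >= params$min_separation_px^2)
    }
    seeds <- seeds[keep, , drop = FALSE]
  }
  rownames(seeds) <- NULL
  seeds
}

# Fraction of a unit Gaussian integrated over unit pixels centered at `c`.
int_gauss1d <- function(coords, mu, sigma) {
  pnorm((coords + 0.5 - mu) / sigma) - pnorm((coords - 0.5 - mu) / sigma)
}

# Pixel-integrated elliptical Gaussian on a 0-based grid; matches how a
# camera collects photons, so noiseless fits recover positions exactly.
# p = (x0, y0, sx, sy, N, b): N is the integrated signal above offset b.
gauss2d_model <- function(p, xs, ys) {
  p[5] * outer(int_gauss1d(ys, p[2], p[4]), int_gauss1d(xs, p[1], p[3])) +
    p[6]
}

# Moment-based initialization over a background-subtracted ROI.
# Returns (x, y, sx, sy, N, b) with N the integrated signal estimate.
init_from_moments <- function(roi, xs, ys) {
  b0 <- stats::quantile(roi, 0.25, names = FALSE)
  w <- roi - b0
  w[w < 0] <- 0
  tot <- sum(w)
  if (tot <= 0) {
    mx <- xs[which.max(apply(roi, 2, max))]
    my <- ys[which.max(apply(roi, 1, max))]
    return(c(mx, my, 1.3, 1.3, max(max(roi) - b0, 1) * 2 * pi * 1.3^2, b0))
  }
  cx <- sum(sweep(w, 2, xs, "*")) / tot   # w is [row, col]; x varies with col
  cy <- sum(sweep(w, 1, ys, "*")) / tot
  vx <- sum(sweep(w, 2, (xs - cx)^2, "*")) / tot
  vy <- sum(sweep(w, 1, (ys - cy)^2, "*")) / tot
  sx <- min(max(sqrt(max(vx, 0.25)), 0.8), 3)
  sy <- min(max(sqrt(max(vy, 0.25)), 0.8), 3)
  c(cx, cy, sx, sy, tot, b0)
}

#' Fit a single elliptical Gaussian around a seed
#'
#' Least-squares fit of the pixel-integrated elliptical Gaussian
#' `N g(x0, sx) g(y0, sy) + b` over a `(2r+1)^2` window (g the per-pixel
#' Gaussian integral), initialized from the centroid and second moments of
#' the background-subtracted window (Levenberg-Marquardt, relative
#' tolerance 1e-8, at most 100 iterations). The integrated signal above
#' background is `N / gain` photons; goodness of fit is
#' the coefficient of determination clipped to \[0, 1\]. A window clipped by
#' the image border, or a failed fit, yields a record with `goodness = 0`
#' and `photons = NA` rather than an error.
#'
#' @param image 2-D matrix of counts.
#' @param seed list or data.frame row with 0-based `x`, `y`.
#' @param params a [detection_params()].
#' @param frame 0-based frame index stored in the record.
#' @return one-row localization record data.frame.
#' @export
fit_single <- function(image, seed, params = detection_params(), frame = 0) {
  r <- params$roi_radius_px
  cx <- round(seed$x)
  cy <- round(seed$y)
  nr <- nrow(image)
  nc <- ncol(image)
  if (cx - r < 0 || cy - r < 0 || cx + r > nc - 1 || cy + r > nr - 1)
    return(new_record(frame, seed$x, seed$y, goodness = 0))
  xs <- (cx - r):(cx + r)
  ys <- (cy - r):(cy + r)
  roi <- image[ys + 1, xs + 1]
  p0 <- init_from_moments(roi, xs, ys)
  lower <- c(min(xs) - 1, min(ys) - 1, 0.3, 0.3, 0, -Inf)
  upper <- c(max(xs) + 1, max(ys) + 1, 2 * r + 1, 2 * r + 1, Inf, Inf)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0,
                       fn = function(p) as.vector(roi - gauss2d_model(p, xs, ys)),
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 100, ftol = 1e-8, ptol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new_record(frame, seed$x, seed$y, goodness = 0))
  p <- fit$par
  ss_res <- sum(fit$fvec^2)
  ss_tot <- sum((roi - mean(roi))^2)
  goodness <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 0
  new_record(frame, p[1], p[2], sigma_x = p[3], sigma_y = p[4],
             photons = p[5] / params$gain,
             background = p[6], goodness = goodness)
}

#' Localize all emitters in one frame (single-emitter pipeline)
#'
#' Wavelet filtering, seed detection and per-seed Gaussian fitting.
#'
#' @inheritParams fit_single
#' @param astig optional [astig_calibration()]; when given, z is assigned
#'   from the fitted widths.
#' @return a `LocalizationTable` in the frame's channel pixels.
#' @export
localize_frame <- function(image, params = detection_params(), frame = 0,
                           astig = NULL) {
  plane <- wavelet_filter(image, params$wavelet_scale)
  seeds <- detect_spots(plane, params)
  recs <- lapply(seq_len(nrow(seeds)), function(i)
    fit_single(image, seeds[i, ], params, frame))
  tab <- if (length(recs)) do.call(rbind, recs) else NULL
  tab <- localization_table(tab)
  if (!is.null(astig) && nrow(tab)) tab <- assign_z(tab, astig)
  tab
}

#' Localize every frame of a stack
#'
#' @param stack an `ImageStack`.
#' @param params a [detection_params()].
#' @param astig optional astigmatism calibration for z assignment.
#' @param min_goodness records with goodness below this are dropped
#'   (default 0 keeps everything; 0.6 reproduces the usual quality filter).
#' @return a `LocalizationTable`.
#' @export
localize_stack <- function(stack, params = detection_params(), astig = NULL,
                           min_goodness = 0) {
  tabs <- lapply(seq_len(n_frames(stack)) - 1L, function(f)
    localize_frame(get_frame(stack, f), params, frame = f, astig = astig))
  tab <- localization_table(do.call(rbind, lapply(tabs, as.data.frame)),
                            channel_label = stack$channel_label,
                            metadata = list(pixel_size_nm = stack$pixel_size_nm,
                                            frame_interval_s = stack$frame_interval_s))
  if (min_goodness > 0 && nrow(tab))
    tab <- localization_table(as.data.frame(tab)[!is.na(tab$goodness) &
                                                 tab$goodness >= min_goodness, ],
                              channel_label = stack$channel_label,
                              metadata = attr(tab, "metadata"))
  tab
}
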