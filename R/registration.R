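#' Third-order polynomial field transform between the two channels
#'
#' Maps spatial-channel pixel coordinates (x, y) to spectral-channel pixel
#' coordinates (x', y') with 10 coefficients per output dimension:
#' \deqn{x' = a_1 x^3 + a_2 y^3 + a_3 x^2 y + a_4 x y^2 + a_5 x^2 +
#'       a_6 y^2 + a_7 x y + a_8 x + a_9 y + a_{10}}
#' and identically for y'. The transform is wavelength dependent through the
#' prism; it is centered at the emission wavelength of the fiducial used for
#' calibration (`reference_wavelength_nm`).
#'
#' @param ax,ay numeric(10) coefficient vectors, basis order
#'   `x^3, y^3, x^2 y, x y^2, x^2, y^2, x y, x, y, 1`.
#' @param reference_wavelength_nm wavelength of the calibration fiducial.
#' @return a `FieldTransform` object.
#' @export
field_transform <- function(ax, ay, reference_wavelength_nm = 683) {
  stopifnot(length(ax) == 10, length(ay) == 10,
            all(is.finite(ax)), all(is.finite(ay)))
  structure(list(ax = as.numeric(ax), ay = as.numeric(ay),
                 reference_wavelength_nm = reference_wavelength_nm),
            class = "FieldTransform")
}

#' Identity field transform
#' @inheritParams field_transform
#' @export
identity_transform <- function(reference_wavelength_nm = 683) {
  ax <- c(rep(0, 7), 1, 0, 0)
  ay <- c(rep(0, 8), 1, 0)
  field_transform(ax, ay, reference_wavelength_nm)
}

# Cubic design matrix, one row per point, columns in the coefficient order.
poly3_basis <- function(x, y) {
  cbind(x^3, y^3, x^2 * y, x * y^2, x^2, y^2, x * y, x, y, 1)
}

#' Fit the field transform from paired fiducial localizations
#'
#' Both output polynomials are linear in their coefficients, so the
#' least-squares optimum is computed in closed form by QR; this reaches the
#' same minimum as an iterative Levenberg-Marquardt refinement of the same
#' residuals (verified by test).
#'
#' @param pairs data.frame with columns `x, y` (spatial px) and `xp, yp`
#'   (spectral px); at least 10 pairs spanning the field.
#' @param reference_wavelength_nm wavelength of the fiducial.
#' @param pixel_size_nm spectral-channel pixel size for the residual QC.
#' @return a `FieldTransform` with a `RegistrationQC` in attribute `"qc"`.
#' @export
fit_field_transform <- function(pairs, reference_wavelength_nm = 683,
                                pixel_size_nm = 178) {
  stopifnot(all(c("x", "y", "xp", "yp") %in% names(pairs)))
  if (nrow(pairs) < 10)
    stop("at least 10 point pairs are required to fit 10 coefficients")
  B <- poly3_basis(pairs$x, pairs$y)
  qrB <- qr(B)
  if (qrB$rank < 10)
    stop("degenerate fiducial geometry: design matrix rank ", qrB$rank,
         " < 10 (points collinear or insufficiently spread)")
  ax <- qr.coef(qrB, pairs$xp)
  ay <- qr.coef(qrB, pairs$yp)
  t <- field_transform(ax, ay, reference_wavelength_nm)
  attr(t, "qc") <- registration_residuals(t, pairs, pixel_size_nm)
  t
}

#' Apply a field transform to points
#'
#' @param t a `FieldTransform`.
#' @param points data.frame (or list) with `x`, `y` in spatial px.
#' @return data.frame with transformed `x`, `y` in spectral px.
#' @export
apply_field_transform <- function(t, points) {
  B <- poly3_basis(points$x, points$y)
  data.frame(x = as.vector(B %*% t$ax), y = as.vector(B %*% t$ay))
}

#' Registration quality control
#'
#' Euclidean distances (in spectral-channel nm) between transformed spatial
#' points and their paired spectral localizations.
#'
#' @inheritParams fit_field_transform
#' @param t a `FieldTransform`.
#' @return a `RegistrationQC` list with `residuals_nm`, `median_nm`, `max_nm`.
#' @export
registration_residuals <- function(t, pairs, pixel_size_nm = 178) {
  if (nrow(pairs) == 0) stop("no pairs to evaluate")
  tr <- apply_field_transform(t, pairs)
  res <- sqrt((tr$x - pairs$xp)^2 + (tr$y - pairs$yp)^2) * pixel_size_nm
  structure(list(residuals_nm = res, median_nm = stats::median(res),
                 max_nm = max(res)),
            class = "RegistrationQC")
}

#' Update the transform's zero-order coefficients from one fiducial
#'
#' Session-to-session shifts of the fields of view are absorbed by updating
#' only the translation terms a_x10 and a_y10, so that the transformed
#' fiducial lands exactly `expected_distance_px` away from its spectral
#' localization along the dispersion axis (0 for a fiducial at the
#' reference wavelength), and exactly on it perpendicular to it.
#'
#' @param t a `FieldTransform`.
#' @param fiducial_spatial,fiducial_spectral lists/rows with `x`, `y` (px in
#'   their own channel).
#' @param expected_distance_px expected displacement along the dispersion
#'   axis (spectral px).
#' @param dispersion_axis `"y"` (default) or `"x"`.
#' @return the updated `FieldTransform`.
#' @export
update_transform_offset <- function(t, fiducial_spatial, fiducial_spectral,
                                    expected_distance_px = 0,
                                    dispersion_axis = "y") {
  tr <- apply_field_transform(t, data.frame(x = fiducial_spatial$x,
                                            y = fiducial_spatial$y))
  if (dispersion_axis == "y") {
    t$ax[10] <- t$ax[10] + (fiducial_spectral$x - tr$x)
    t$ay[10] <- t$ay[10] + (fiducial_spectral$y - expected_distance_px - tr$y)
  } else {
    t$ax[10] <- t$ax[10] + (fiducial_spectral$x - expected_distance_px - tr$x)
    t$ay[10] <- t$ay[10] + (fiducial_spectral$y - tr$y)
  }
  t
}

#' Write / read a field transform as plain text
#'
#' 21 values: 10 x-coefficients, 10 y-coefficients, reference wavelength.
#' @param t a `FieldTransform`.
#' @param path file path.
#' @export
write_field_transform <- function(t, path) {
  writeLines(format(c(t$ax, t$ay, t$reference_wavelength_nm), digits = 17),
             path)
  invisible(path)
}

#' @rdname write_field_transform
#' @export
read_field_transform <- function(path) {
  v <- as.numeric(readLines(path))
  if (length(v) != 21) stop("field transform file must contain 21 values")
  field_transform(v[1:10], v[11:20], v[21])
}

#' Pair two calibration point sets by nearest neighbour
#'
#' Coarse translation alignment (median offset of mutual nearest
#' neighbours), then one-to-one nearest-neighbour matching.
#'
#' @param spatial,spectral data.frames with `x`, `y`.
#' @param max_dist_px matching radius after coarse alignment.
#' @return pairs data.frame (`x, y, xp, yp`) for [fit_field_transform()].
#' @export
pair_calibration_points <- function(spatial, spectral, max_dist_px = 10) {
  # coarse shift from centroids
  dx <- stats::median(spectral$x) - stats::median(spatial$x)
  dy <- stats::median(spectral$y) - stats::median(spatial$y)
  cost <- outer(spatial$x + dx, spectral$x, "-")^2 +
          outer(spatial$y + dy, spectral$y, "-")^2
  j <- match_one_to_one(cost, max_cost = max_dist_px^2)
  keep <- !is.na(j)
  data.frame(x = spatial$x[keep], y = spatial$y[keep],
             xp = spectral$x[j[keep]], yp = spectral$y[j[keep]])
}

#' Estimate per-channel lateral drift from fiducial localizations
#'
#' Fiducials are grouped by `track_id` when present, otherwise linked by
#' proximity. Per-frame offsets relative to frame 0 are averaged over
#' fiducials, gaps are linearly interpolated, and the trace is smoothed by
#' a centered rolling mean.
#'
#' @param fiducial_table `LocalizationTable` of fiducial localizations.
#' @param n_frames total number of frames the trace must cover (default:
#'   up to the largest fiducial frame).
#' @param smoothing_window rolling-mean window in frames.
#' @return a `DriftTrace` data.frame with columns `frame, dx, dy` (pixels,
#'   offset relative to frame 0).
#' @export
estimate_drift <- function(fiducial_table, n_frames = NULL,
                           smoothing_window = 50) {
  df <- as.data.frame(fiducial_table)
  if (nrow(df) == 0) stop("no fiducial localizations provided")
  if (all(is.na(df$track_id))) {
    tracks <- link_tracks(fiducial_table, max_disp_px = 5,
                          max_gap = max(df$frame))
    df <- do.call(rbind, lapply(tracks, function(tr) {
      d <- as.data.frame(tr$records)
      d$track_id <- tr$track_id
      d
    }))
  }
  if (is.null(n_frames)) n_frames <- max(df$frame) + 1L
  frames <- 0:(n_frames - 1L)
  per_fid <- list()
  for (id in unique(df$track_id)) {
    sub <- df[df$track_id == id, ]
    sub <- sub[order(sub$frame), ]
    if (nrow(sub) < 0.8 * n_frames) next  # requires >= 80% coverage
    ref <- c(sub$x[1], sub$y[1])
    dx <- stats::approx(sub$frame, sub$x - ref[1], xout = frames,
                        rule = 2)$y
    dy <- stats::approx(sub$frame, sub$y - ref[2], xout = frames,
                        rule = 2)$y
    per_fid[[length(per_fid) + 1L]] <- cbind(dx, dy)
  }
  if (!length(per_fid))
    stop("no fiducial is localized in at least 80% of frames")
  dx <- rowMeans(sapply(per_fid, function(m) m[, 1]))
  dy <- rowMeans(sapply(per_fid, function(m) m[, 2]))
  w <- max(1, min(smoothing_window, n_frames))
  dx <- zoo::rollapply(dx, w, mean, partial = TRUE)
  dy <- zoo::rollapply(dy, w, mean, partial = TRUE)
  # re-anchor at frame 0 after smoothing
  trace <- data.frame(frame = frames, dx = dx - dx[1], dy = dy - dy[1])
  class(trace) <- c("DriftTrace", "data.frame")
  attr(trace, "smoothing_window") <- w
  trace
}

#' Apply a drift correction to a localization table
#'
#' Subtracts the per-frame `(dx, dy)` offsets from each record's
#' coordinates; all other fields are untouched.
#'
#' @param table a `LocalizationTable`.
#' @param drift a `DriftTrace` covering every frame of the table.
#' @return the corrected table.
#' @export
apply_drift_correction <- function(table, drift) {
  if (nrow(table) == 0) return(table)
  idx <- match(table$frame, drift$frame)
  if (any(is.na(idx)))
    stop("drift trace does not cover frames: ",
         paste(unique(table$frame[is.na(idx)]), collapse = ", "))
  table$x <- table$x - drift$dx[idx]
  table$y <- table$y - drift$dy[idx]
  table
}
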