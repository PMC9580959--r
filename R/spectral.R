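#' Spectral dispersion calibration
#'
#' The prism shifts an emitter's spectral-channel image along the dispersion
#' axis in proportion to its mean emission wavelength:
#' `lambda = lambda0 + alpha d`, with `d` the displacement (spectral px)
#' between the paired spectral localization and the transformed spatial one,
#' and `lambda0` the reference wavelength at which the field transform was
#' calibrated (d = 0 there).
#'
#' @param lambda0_nm reference emission wavelength (nm).
#' @param alpha_nm_per_px dispersion coefficient (nm per spectral pixel);
#'   non-zero, negative on a system dispersing towards smaller y.
#' @param dispersion_axis `"y"` (default) or `"x"`.
#' @param uncertainty_nm_per_px standard error of the fitted slope.
#' @param lambda_range_nm physically plausible emission range; assigned
#'   wavelengths outside it are flagged.
#' @return a `SpectralCalibration` object.
#' @export
spectral_calibration <- function(lambda0_nm = 683, alpha_nm_per_px = -8.1,
                                 dispersion_axis = "y",
                                 uncertainty_nm_per_px = NA_real_,
                                 lambda_range_nm = c(400, 800)) {
  stopifnot(alpha_nm_per_px != 0,
            lambda0_nm >= lambda_range_nm[1] - 100,
            lambda0_nm <= lambda_range_nm[2] + 100)
  dispersion_axis <- match.arg(dispersion_axis, c("y", "x"))
  structure(list(lambda0_nm = lambda0_nm,
                 alpha_nm_per_px = alpha_nm_per_px,
                 dispersion_axis = dispersion_axis,
                 uncertainty_nm_per_px = uncertainty_nm_per_px,
                 lambda_range_nm = lambda_range_nm),
            class = "SpectralCalibration")
}

#' Calibrate the dispersion coefficient from multicolor bead peaks
#'
#' Unweighted least-squares regression of peak wavelength on measured
#' displacement; the slope is the dispersion coefficient alpha (nm/px) and
#' its standard error is reported. Intercept is fitted freely (and will be
#' close to `lambda0_nm` when the zero-displacement peak is the reference).
#'
#' @param peaks data.frame with `displacement_px` and `wavelength_nm`, one
#'   row per resolved emission peak (at least 2 distinct displacements).
#' @param lambda0_nm reference wavelength stored in the calibration.
#' @inheritParams spectral_calibration
#' @return a `SpectralCalibration`.
#' @export
calibrate_dispersion <- function(peaks, lambda0_nm = 683,
                                 dispersion_axis = "y",
                                 lambda_range_nm = c(400, 800)) {
  stopifnot(all(c("displacement_px", "wavelength_nm") %in% names(peaks)))
  if (length(unique(peaks$displacement_px)) < 2)
    stop("at least two distinct displacements are required")
  fit <- stats::lm(wavelength_nm ~ displacement_px, data = peaks)
  alpha <- unname(coef(fit)[2])
  se <- if (nrow(peaks) > 2) summary(fit)$coefficients[2, 2] else NA_real_
  cal <- spectral_calibration(lambda0_nm, alpha, dispersion_axis,
                              uncertainty_nm_per_px = se,
                              lambda_range_nm = lambda_range_nm)
  attr(cal, "intercept_nm") <- unname(coef(fit)[1])
  cal
}

#' Pair search zone
#'
#' Rectangular zone in which the spectral counterpart of a transformed
#' spatial localization is sought: half-width `dx_px` perpendicular to the
#' dispersion axis, displacement window `[dmin_px, dmax_px]` along it. Its
#' height bounds the usable density of simultaneously emitting molecules.
#'
#' @param dx_px half-width perpendicular to the dispersion axis (px).
#' @param dmin_px,dmax_px displacement window along the dispersion axis.
#' @return a `PairSearchZone`.
#' @export
pair_search_zone <- function(dx_px = 2, dmin_px = -15, dmax_px = 35) {
  stopifnot(dx_px > 0, dmin_px < dmax_px)
  structure(list(dx_px = dx_px, dmin_px = dmin_px, dmax_px = dmax_px),
            class = "PairSearchZone")
}

#' Pair search zone covering a wavelength interval
#'
#' Converts a-priori knowledge of the species' emission range into the
#' displacement window via the dispersion calibration.
#'
#' @param calib a `SpectralCalibration`.
#' @param lambda_min_nm,lambda_max_nm expected emission range.
#' @inheritParams pair_search_zone
#' @export
zone_from_wavelengths <- function(calib, lambda_min_nm, lambda_max_nm,
                                  dx_px = 2) {
  d <- sort((c(lambda_min_nm, lambda_max_nm) - calib$lambda0_nm) /
              calib$alpha_nm_per_px)
  pair_search_zone(dx_px, d[1], d[2])
}

#' Pair spatial and spectral localizations frame by frame
#'
#' Spatial records are mapped through the field transform; spectral records
#' falling inside the pair search zone are candidates. Conflicts are
#' resolved per frame by a minimum-cost one-to-one assignment with cost
#' `perp_offset^2 + w_disp * (displacement - expected)^2` (default
#' `w_disp = 0`: no species prior). Unmatched spatial records are kept
#' without a wavelength. Spatial coordinates are never modified.
#'
#' @param spatial_table,spectral_table `LocalizationTable`s of the two
#'   channels, same frame basis.
#' @param t a `FieldTransform`.
#' @param zone a `PairSearchZone`.
#' @param calib optional `SpectralCalibration`; when given, wavelengths are
#'   assigned to paired records.
#' @param w_disp weight of the displacement prior in the pairing cost.
#' @param expected_d_px expected displacement used with `w_disp > 0`.
#' @return the spatial table with `pair_distance` (spectral px) and, when
#'   `calib` is given, `wavelength` filled for paired records.
#' @export
pair_localizations <- function(spatial_table, spectral_table, t, zone,
                               calib = NULL, w_disp = 0, expected_d_px = 0) {
  sp <- as.data.frame(spatial_table)
  se <- as.data.frame(spectral_table)
  sp$pair_distance <- NA_real_
  if (!is.null(calib)) sp$wavelength <- NA_real_
  if (nrow(sp) == 0 || nrow(se) == 0)
    return(localization_table(sp, attr(spatial_table, "channel_label"),
                              attr(spatial_table, "metadata")))
  tr <- apply_field_transform(t, sp)
  for (f in unique(sp$frame)) {
    i_sp <- which(sp$frame == f)
    i_se <- which(se$frame == f)
    if (!length(i_sp) || !length(i_se)) next
    # displacement along the dispersion axis and perpendicular offset
    if (is.null(calib) || calib$dispersion_axis == "y") {
      disp <- outer(-tr$y[i_sp], se$y[i_se], "+")   # y_spec - y'_spat
      perp <- outer(-tr$x[i_sp], se$x[i_se], "+")
    } else {
      disp <- outer(-tr$x[i_sp], se$x[i_se], "+")
      perp <- outer(-tr$y[i_sp], se$y[i_se], "+")
    }
    ok <- abs(perp) <= zone$dx_px & disp >= zone$dmin_px & disp <= zone$dmax_px
    cost <- perp^2 + w_disp * (disp - expected_d_px)^2
    cost[!ok] <- Inf
    max_feasible <- zone$dx_px^2 +
      w_disp * (abs(zone$dmax_px - zone$dmin_px) + abs(expected_d_px))^2 + 1
    j <- match_one_to_one(cost, max_cost = max_feasible)
    matched <- which(!is.na(j))
    if (length(matched)) {
      sp$pair_distance[i_sp[matched]] <- disp[cbind(matched, j[matched])]
      if (!is.null(calib))
        sp$wavelength[i_sp[matched]] <-
          assign_wavelength(sp$pair_distance[i_sp[matched]], calib)$wavelength_nm
    }
  }
  localization_table(sp, attr(spatial_table, "channel_label"),
                     attr(spatial_table, "metadata"))
}

#' Assign a wavelength from a pair displacement
#'
#' `lambda = lambda0 + alpha d`, exactly affine in `d`. Wavelengths outside
#' the calibration's physical range are flagged.
#'
#' @param d_px displacement(s) along the dispersion axis (spectral px).
#' @param calib a `SpectralCalibration`.
#' @return data.frame with `wavelength_nm` and logical `out_of_range`.
#' @export
assign_wavelength <- function(d_px, calib) {
  lambda <- calib$lambda0_nm + calib$alpha_nm_per_px * d_px
  data.frame(wavelength_nm = lambda,
             out_of_range = lambda < calib$lambda_range_nm[1] |
                            lambda > calib$lambda_range_nm[2])
}

#' Classify records into species by wavelength windows
#'
#' @param table a `LocalizationTable` with wavelengths.
#' @param windows data.frame with `label`, `lambda_min`, `lambda_max`
#'   (non-overlapping).
#' @return the table with the `species` column filled; records outside all
#'   windows (or without wavelength) are labeled `"unassigned"`.
#' @export
classify_species <- function(table, windows) {
  stopifnot(all(c("label", "lambda_min", "lambda_max") %in% names(windows)))
  w <- windows[order(windows$lambda_min), ]
  if (nrow(w) > 1 && any(w$lambda_max[-nrow(w)] > w$lambda_min[-1]))
    stop("species windows overlap")
  species <- rep("unassigned", nrow(table))
  for (i in seq_len(nrow(w))) {
    inw <- !is.na(table$wavelength) &
      table$wavelength >= w$lambda_min[i] & table$wavelength <= w$lambda_max[i]
    species[inw] <- as.character(w$label[i])
  }
  table$species <- species
  table
}

#' Write / read a spectral calibration as plain text
#' @param calib a `SpectralCalibration`.
#' @param path file path.
#' @export
write_spectral_calibration <- function(calib, path) {
  writeLines(c(
    sprintf("lambda0_nm: %.17g", calib$lambda0_nm),
    sprintf("alpha_nm_per_px: %.17g", calib$alpha_nm_per_px),
    sprintf("uncertainty_nm_per_px: %.17g", calib$uncertainty_nm_per_px),
    sprintf("dispersion_axis: %s", calib$dispersion_axis),
    sprintf("lambda_range_nm: %.17g %.17g", calib$lambda_range_nm[1],
            calib$lambda_range_nm[2])), path)
  invisible(path)
}

#' @rdname write_spectral_calibration
#' @export
read_spectral_calibration <- function(path) {
  kv <- strsplit(readLines(path), ": ", fixed = TRUE)
  vals <- setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  rng <- as.numeric(strsplit(vals$lambda_range_nm, " ")[[1]])
  unc <- suppressWarnings(as.numeric(vals$uncertainty_nm_per_px))
  spectral_calibration(as.numeric(vals$lambda0_nm),
                       as.numeric(vals$alpha_nm_per_px),
                       vals$dispersion_axis,
                       unc, rng)
}
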