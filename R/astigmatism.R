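#' Astigmatism calibration: PSF width versus axial position
#'
#' A cylindrical lens in the spatial path makes the PSF elliptical away from
#' focus, with sigma_x(z) and sigma_y(z) crossing once at focus. The
#' calibration stores 4th-order polynomial fits of the two width curves
#' (pixels) against z (nm), valid over `z_range_nm`.
#'
#' @param z_nm,sigma_x_px,sigma_y_px calibration samples (e.g. from a bead
#'   z-stack).
#' @param z_range_nm valid axial interval, default c(-500, 500).
#' @param degree polynomial degree of the width curves.
#' @return an `AstigmatismCalibration` object.
#' @export
astig_calibration <- function(z_nm, sigma_x_px, sigma_y_px,
                              z_range_nm = c(-500, 500), degree = 4) {
  stopifnot(length(z_nm) > degree, length(sigma_x_px) == length(z_nm),
            length(sigma_y_px) == length(z_nm))
  cx <- stats::lm(sigma_x_px ~ poly(z_nm, degree, raw = TRUE))$coefficients
  cy <- stats::lm(sigma_y_px ~ poly(z_nm, degree, raw = TRUE))$coefficients
  cal <- structure(list(coef_x = unname(cx), coef_y = unname(cy),
                        z_range_nm = z_range_nm),
                   class = "AstigmatismCalibration")
  validate_astig(cal)
  cal
}

validate_astig <- function(cal) {
  zg <- seq(cal$z_range_nm[1], cal$z_range_nm[2], length.out = 201)
  sx <- polyval_asc(cal$coef_x, zg)
  sy <- polyval_asc(cal$coef_y, zg)
  if (any(sx <= 0) || any(sy <= 0))
    stop("invalid astigmatism calibration: width curves not strictly positive")
  crossings <- sum(diff(sign(sx - sy)) != 0)
  if (crossings != 1)
    stop("invalid astigmatism calibration: sigma_x and sigma_y must cross ",
         "exactly once in z_range (found ", crossings, ")")
  invisible(cal)
}

# Evaluate a polynomial with ascending coefficients c0 + c1 z + c2 z^2 ...
polyval_asc <- function(coefs, z) {
  out <- 0
  for (k in rev(seq_along(coefs))) out <- out * z + coefs[k]
  out
}

#' PSF widths predicted by an astigmatism calibration
#' @param cal an `AstigmatismCalibration`.
#' @param z_nm axial positions (nm).
#' @return list with vectors `sigma_x`, `sigma_y` (pixels).
#' @export
astig_sigma_at_z <- function(cal, z_nm) {
  list(sigma_x = polyval_asc(cal$coef_x, z_nm),
       sigma_y = polyval_asc(cal$coef_y, z_nm))
}

#' Read / write an astigmatism calibration as CSV
#'
#' The file stores the raw samples (`z_nm, sigma_x_px, sigma_y_px`);
#' polynomials are refitted at load time.
#' @param path CSV path.
#' @inheritParams astig_calibration
#' @export
read_astig_calibration <- function(path, z_range_nm = c(-500, 500)) {
  df <- utils::read.csv(path)
  astig_calibration(df$z_nm, df$sigma_x_px, df$sigma_y_px, z_range_nm)
}

#' Default astigmatism calibration used by the simulator
#'
#' Width curves follow the standard defocus model
#' `sigma(z) = sigma0 sqrt(1 + ((z -/+ gamma)/d)^2)` with focal offset
#' `gamma = 250 nm` and depth scale `d = 400 nm`, sampled every 25 nm and
#' represented by the package's polynomial calibration.
#'
#' @param sigma0_px in-focus width of each astigmatic branch (pixels).
#' @param gamma_nm,depth_nm defocus model parameters.
#' @param z_range_nm valid interval.
#' @export
default_astig_calibration <- function(sigma0_px = 1.3, gamma_nm = 250,
                                      depth_nm = 400,
                                      z_range_nm = c(-500, 500)) {
  z <- seq(z_range_nm[1] - 100, z_range_nm[2] + 100, by = 25)
  sx <- sigma0_px * sqrt(1 + ((z + gamma_nm) / depth_nm)^2)
  sy <- sigma0_px * sqrt(1 + ((z - gamma_nm) / depth_nm)^2)
  astig_calibration(z, sx, sy, z_range_nm)
}

#' Assign axial positions from fitted PSF widths
#'
#' For each record, z minimizes
#' `(sqrt(sigma_x) - sqrt(sigma_x(z)))^2 + (sqrt(sigma_y) - sqrt(sigma_y(z)))^2`
#' on a 1 nm grid over the calibration range. Minima on the range boundary,
#' or widths too far from the calibration curves (residual above
#' `max_residual`), leave z unset.
#'
#' @param table a `LocalizationTable` (or any data.frame with `sigma_x`,
#'   `sigma_y`).
#' @param cal an `AstigmatismCalibration`.
#' @param max_residual rejection threshold on the minimized distance
#'   (sqrt-pixel units squared).
#' @return the table with a filled `z` column (nm) where assignable.
#' @export
assign_z <- function(table, cal, max_residual = 0.1) {
  validate_astig(cal)
  zg <- seq(cal$z_range_nm[1], cal$z_range_nm[2], by = 1)
  sq_sx <- sqrt(polyval_asc(cal$coef_x, zg))
  sq_sy <- sqrt(polyval_asc(cal$coef_y, zg))
  z <- rep(NA_real_, nrow(table))
  for (i in seq_len(nrow(table))) {
    sx <- table$sigma_x[i]
    sy <- table$sigma_y[i]
    if (is.na(sx) || is.na(sy) || sx <= 0 || sy <= 0) next
    d <- (sqrt(sx) - sq_sx)^2 + (sqrt(sy) - sq_sy)^2
    k <- which.min(d)
    if (k == 1L || k == length(zg) || d[k] > max_residual) next
    z[i] <- zg[k]
  }
  table$z <- z
  table
}
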