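#' @importFrom stats approx coef lm lm.fit mad median pnorm predict quantile
#'   rnorm rpois runif sd setNames var IQR wilcox.test
#' @importFrom utils read.csv write.csv head tail
NULL

# Canonical column set of a localization table. Coordinates are in pixels of
# the owning channel, 0-based, integer coordinates at pixel centers. Frames
# are 0-based.
LOC_COLUMNS <- c("frame", "x", "y", "sigma_x", "sigma_y", "photons",
                 "background", "goodness", "z", "wavelength",
                 "pair_distance", "track_id", "species")

LOC_NUMERIC <- setdiff(LOC_COLUMNS, "species")

#' Construct an image stack
#'
#' @param frames numeric array `[row, col, frame]` of camera counts, or a
#'   single matrix (one frame). 16-bit unsigned semantics: all counts must be
#'   non-negative.
#' @param pixel_size_nm physical size of one pixel in sample space (nm).
#'   Defaults: 160 nm/px on the spatial channel (16 um camera pixels at x100
#'   magnification), 178 nm/px on the spectral channel (x90).
#' @param channel_label `"spatial"` or `"spectral"`.
#' @param frame_interval_s acquisition period in seconds.
#' @return an `ImageStack` object.
#' @export
image_stack <- function(frames, pixel_size_nm = 160, channel_label = "spatial",
                        frame_interval_s = 0.05) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L)
  storage.mode(frames) <- "double"
  if (any(!is.finite(frames))) stop("image stack contains non-finite counts")
  if (any(frames < 0)) stop("image stack contains negative counts")
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be positive")
  if (frame_interval_s <= 0) stop("frame_interval_s must be positive")
  channel_label <- match.arg(channel_label, c("spatial", "spectral"))
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 channel_label = channel_label,
                 frame_interval_s = frame_interval_s),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("ImageStack [%s]: %d frames of %d x %d px, %.0f nm/px, %.3g s/frame\n",
              x$channel_label, d[3], d[1], d[2], x$pixel_size_nm,
              x$frame_interval_s))
  invisible(x)
}

#' Number of frames in an image stack
#' @param stack an `ImageStack`.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Extract one frame (matrix) from an image stack
#' @param stack an `ImageStack`.
#' @param frame 0-based frame index.
#' @export
get_frame <- function(stack, frame) {
  stopifnot(frame >= 0, frame < n_frames(stack))
  stack$frames[, , frame + 1L]
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path path to a grayscale 8/16-bit multi-page TIFF.
#' @inheritParams image_stack
#' @return an `ImageStack`; counts are raw camera units.
#' @export
read_image_stack <- function(path, pixel_size_nm = 160,
                             channel_label = "spatial",
                             frame_interval_s = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("format error: TIFF pages have non-uniform frame dimensions")
  frames <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first sample of multi-sample
    frames[, , i] <- p
  }
  image_stack(frames, pixel_size_nm, channel_label, frame_interval_s)
}

#' Write an image stack as a 16-bit multi-page TIFF
#'
#' Counts are clamped to \[0, 65535\] and rounded; re-reading with
#' [read_image_stack()] restores the pixel values exactly.
#' @param stack an `ImageStack`.
#' @param path output path.
#' @export
write_image_stack <- function(stack, path) {
  nf <- n_frames(stack)
  pages <- vector("list", nf)
  for (i in seq_len(nf)) {
    m <- round(stack$frames[, , i])
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    pages[[i]] <- m / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Construct a localization table
#'
#' A localization table is a `data.frame` with one row per fitted emitter and
#' the fixed column set `frame, x, y, sigma_x, sigma_y, photons, background,
#' goodness, z, wavelength, pair_distance, track_id, species`. Optional
#' fields are `NA` when unset (never 0). Rows are kept sorted by frame,
#' preserving detection order within a frame.
#'
#' @param df data.frame holding at least `frame`, `x`, `y`; missing optional
#'   columns are added as `NA`.
#' @param channel_label channel the coordinates live in.
#' @param metadata named list of provenance (source file, parameters, seed).
#' @return a `LocalizationTable` (a classed `data.frame`).
#' @export
localization_table <- function(df = NULL, channel_label = "spatial",
                               metadata = list()) {
  if (is.null(df)) df <- data.frame()
  df <- as.data.frame(df)
  if (nrow(df) > 0) {
    miss <- setdiff(c("frame", "x", "y"), names(df))
    if (length(miss)) stop("format error: missing mandatory columns: ",
                           paste(miss, collapse = ", "))
  }
  for (cc in LOC_COLUMNS) {
    if (!cc %in% names(df))
      df[[cc]] <- if (cc == "species") rep(NA_character_, nrow(df))
                  else rep(NA_real_, nrow(df))
  }
  extra <- setdiff(names(df), LOC_COLUMNS)
  df <- df[, LOC_COLUMNS, drop = FALSE]
  if (nrow(df) > 0) {
    if (any(df$frame < 0, na.rm = TRUE)) stop("frame indices must be >= 0")
    df <- df[order(df$frame), , drop = FALSE]  # stable: keeps detection order
    rownames(df) <- NULL
  }
  structure(df, class = c("LocalizationTable", "data.frame"),
            channel_label = channel_label,
            metadata = metadata,
            extra_columns = extra)
}

#' @export
print.LocalizationTable <- function(x, ...) {
  cat(sprintf("LocalizationTable [%s]: %d records over %d frames\n",
              attr(x, "channel_label"), nrow(x),
              length(unique(x$frame))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Write a localization table to CSV
#'
#' Comma separator, period decimal point (locale-independent), one header
#' row with the fixed column names, one row per record; unset optional
#' values serialize as empty cells.
#'
#' @param table a `LocalizationTable`.
#' @param path output path.
#' @param sidecar if `TRUE`, write `<path>.params.txt` logging the table
#'   metadata.
#' @export
write_localizations <- function(table, path, sidecar = FALSE) {
  df <- as.data.frame(table)[, LOC_COLUMNS, drop = FALSE]
  old <- Sys.getlocale("LC_NUMERIC")
  if (!identical(old, "C")) {
    Sys.setlocale("LC_NUMERIC", "C")
    on.exit(Sys.setlocale("LC_NUMERIC", old), add = TRUE)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  if (sidecar) {
    md <- attr(table, "metadata")
    lines <- c(sprintf("channel_label: %s", attr(table, "channel_label")),
               vapply(names(md), function(k)
                 sprintf("%s: %s", k, paste(format(md[[k]]), collapse = " ")),
                 character(1)))
    writeLines(lines, paste0(path, ".params.txt"))
  }
  invisible(path)
}

#' Read a localization table from CSV
#'
#' Accepts files written by [write_localizations()] or any CSV carrying at
#' least the mandatory `frame,x,y` columns. Unknown columns are preserved in
#' the table's `extra_columns` attribute (with a warning). Values round-trip
#' to better than 1e-6 pixel.
#'
#' @param path CSV path.
#' @param channel_label channel label to attach.
#' @return a `LocalizationTable`.
#' @export
read_localizations <- function(path, channel_label = "spatial") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("frame", "x", "y"), names(df))
  if (length(miss))
    stop("format error: missing mandatory columns: ",
         paste(miss, collapse = ", "))
  unknown <- setdiff(names(df), LOC_COLUMNS)
  extra <- NULL
  if (length(unknown)) {
    warning("ignoring unknown columns: ", paste(unknown, collapse = ", "))
    extra <- df[, unknown, drop = FALSE]
    df <- df[, setdiff(names(df), unknown), drop = FALSE]
  }
  if ("species" %in% names(df)) {
    df$species <- as.character(df$species)
    df$species[!nzchar(df$species) | is.na(df$species)] <- NA_character_
  }
  tab <- localization_table(df, channel_label = channel_label,
                            metadata = list(source = path))
  if (!is.null(extra)) attr(tab, "extra_data") <- extra
  tab
}

# Internal helper: make a full record row (all canonical columns).
new_record <- function(frame, x, y, sigma_x = NA_real_, sigma_y = NA_real_,
                       photons = NA_real_, background = NA_real_,
                       goodness = NA_real_, z = NA_real_,
                       wavelength = NA_real_, pair_distance = NA_real_,
                       track_id = NA_real_, species = NA_character_) {
  data.frame(frame = frame, x = x, y = y, sigma_x = sigma_x,
             sigma_y = sigma_y, photons = photons, background = background,
             goodness = goodness, z = z, wavelength = wavelength,
             pair_distance = pair_distance, track_id = track_id,
             species = species, stringsAsFactors = FALSE)
}
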