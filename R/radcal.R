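#' Per-band sensor calibration metadata
#'
#' Holds the symbols of the vicarious (sensor-information-based) radiometric
#' correction: calibration coefficients `a1`-`a3`, sensor gain `g`, exposure
#' time `te` (s), the normalized black-current level, and the radial
#' vignetting model (centre pixel plus six polynomial coefficients). All
#' values come from the sensor vendor's per-band metadata; none are assumed.
#'
#' @param a1,a2,a3 Calibration coefficients (unitless).
#' @param g Sensor gain (> 0).
#' @param te Exposure time in seconds (> 0).
#' @param black_level Normalized black-current value in `[0, 1)`, on the
#'   same scale as the normalized digital numbers.
#' @param vignette_center Pixel coordinates `c(cx, cy)` of the vignetting
#'   centre (column, row).
#' @param vignette_coeffs Radial polynomial coefficients `k1..k6`.
#' @param band_id Band centre wavelength, one of 475, 560, 668, 717, 842.
#' @return An object of class `calibration_meta`.
#' @export
calibration_meta <- function(a1, a2 = 0, a3 = 0, g = 1, te,
                             black_level = 0,
                             vignette_center = c(0, 0),
                             vignette_coeffs = rep(0, 6),
                             band_id = 842) {
  if (!is.finite(te) || te <= 0) stop("te must be > 0", call. = FALSE)
  if (!is.finite(g) || g <= 0) stop("g must be > 0", call. = FALSE)
  if (!is.finite(black_level) || black_level < 0 || black_level >= 1) {
    stop("black_level must lie in [0, 1)", call. = FALSE)
  }
  if (!as.character(band_id) %in% MF_BANDS) {
    stop("band_id must be one of ", paste(MF_BANDS, collapse = ", "),
         call. = FALSE)
  }
  if (length(vignette_coeffs) != 6) {
    stop("vignette_coeffs must have six elements k1..k6", call. = FALSE)
  }
  structure(
    list(a1 = a1, a2 = a2, a3 = a3, g = g, te = te,
         black_level = black_level,
         vignette_center = as.numeric(vignette_center),
         vignette_coeffs = as.numeric(vignette_coeffs),
         band_id = as.numeric(band_id)),
    class = "calibration_meta"
  )
}

#' Read/write calibration metadata as a JSON sidecar
#' @param meta A [calibration_meta()].
#' @param path JSON path.
#' @return The path (write) or a `calibration_meta` (read).
#' @export
write_calibration_meta <- function(meta, path) {
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_meta
#' @export
read_calibration_meta <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_meta(a1 = x$a1, a2 = x$a2, a3 = x$a3, g = x$g, te = x$te,
                   black_level = x$black_level,
                   vignette_center = x$vignette_center,
                   vignette_coeffs = x$vignette_coeffs,
                   band_id = x$band_id)
}

#' Raw single-band frame of normalized digital numbers
#'
#' @param dn Matrix of normalized raw pixel values in `[0, 1]` (raw integer
#'   counts divided by the sensor's maximum count).
#' @param meta A [calibration_meta()].
#' @inheritParams mf_grid
#' @return Object of class `raw_frame`.
#' @export
raw_frame <- function(dn, meta, origin = c(0, 0), pixel_size = 1,
                      crs = NA_character_) {
  dn <- as.matrix(dn)
  if (any(!is.finite(dn))) stop("raw DN values must all be finite",
                                call. = FALSE)
  if (any(dn < 0 | dn > 1)) {
    stop("normalized DN values must lie in [0, 1]", call. = FALSE)
  }
  if (!inherits(meta, "calibration_meta")) {
    stop("meta must be a calibration_meta", call. = FALSE)
  }
  structure(
    list(dn = dn, meta = meta, origin = as.numeric(origin),
         pixel_size = as.numeric(pixel_size), crs = crs),
    class = "raw_frame"
  )
}

#' Vignetting correction factor at a pixel
#'
#' Radial six-coefficient inverse-polynomial model:
#' `V(x, y) = 1 / (1 + sum_i k_i r^i)` with `r` the Euclidean pixel distance
#' from the vignetting centre. The factor multiplies the radiance estimate,
#' brightening frame corners relative to the optical centre.
#'
#' @param meta A [calibration_meta()].
#' @param x Column index (pixels).
#' @param y Row index (pixels). `x` and `y` are recycled against each other.
#' @return Strictly positive correction factor(s).
#' @export
vignette_factor <- function(meta, x, y) {
  r <- sqrt((x - meta$vignette_center[1])^2 +
              (y - meta$vignette_center[2])^2)
  k <- meta$vignette_coeffs
  denom <- 1 + k[1] * r + k[2] * r^2 + k[3] * r^3 +
    k[4] * r^4 + k[5] * r^5 + k[6] * r^6
  bad <- which(denom <= 0)
  if (length(bad)) {
    stop(sprintf(
      "vignetting polynomial non-positive at pixel (x=%g, y=%g) with k=[%s]",
      x[((bad[1] - 1) %% length(x)) + 1],
      y[((bad[1] - 1) %% length(y)) + 1],
      paste(format(k), collapse = ", ")), call. = FALSE)
  }
  1 / denom
}

#' Convert a raw frame to spectral radiance
#'
#' Applies the vicarious radiometric correction
#' `L = V(x, y) * (a1 / g) * (dn - black) / (te + a2*y - a3*te*y)`
#' per pixel, with `y` the 0-based row index from the top of the frame and
#' `x` the 0-based column index. Negative radiance can occur (dark pixels
#' below the black level) and is preserved; the count is attached as
#' attribute `n_negative` for the processing log.
#'
#' @param frame A [raw_frame()].
#' @return An [mf_grid()] of spectral radiance (W m-2 sr-1 nm-1) with
#'   attribute `n_negative`.
#' @export
dn_to_radiance <- function(frame) {
  meta <- frame$meta
  d <- dim(frame$dn)
  yrow <- seq_len(d[1]) - 1
  denom <- meta$te + meta$a2 * yrow - meta$a3 * meta$te * yrow
  bad <- which(denom <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive radiance denominator at row y=%d", bad[1] - 1),
         call. = FALSE)
  }
  xcol <- seq_len(d[2]) - 1
  V <- outer(yrow, xcol, function(yy, xx) vignette_factor(meta, xx, yy))
  L <- V * (meta$a1 / meta$g) * (frame$dn - meta$black_level) / denom
  out <- mf_grid(L, frame$origin, frame$pixel_size, frame$crs)
  attr(out, "n_negative") <- sum(L < 0, na.rm = TRUE)
  attr(out, "band_id") <- meta$band_id
  out
}

#' Reflectance-panel observation
#'
#' @param mean_radiance Mean panel radiance (W m-2 sr-1 nm-1, > 0).
#' @param panel_reflectance Known panel reflectance in (0, 1); the field
#'   deployment used a near-Lambertian panel of about 20% reflectance.
#' @return Object of class `panel_observation`.
#' @export
panel_observation <- function(mean_radiance, panel_reflectance = 0.20) {
  if (!is.finite(mean_radiance) || mean_radiance <= 0) {
    stop("panel mean_radiance must be > 0", call. = FALSE)
  }
  if (!is.finite(panel_reflectance) || panel_reflectance <= 0 ||
      panel_reflectance >= 1) {
    stop("panel_reflectance must lie in (0, 1)", call. = FALSE)
  }
  structure(list(mean_radiance = mean_radiance,
                 panel_reflectance = panel_reflectance),
            class = "panel_observation")
}

#' Mean radiance over a panel region of a radiance grid
#'
#' @param rad Radiance [mf_grid()].
#' @param region Integer vector `c(row1, row2, col1, col2)` (inclusive,
#'   1-based) delimiting the panel pixels.
#' @param panel_reflectance Known reflectance of the panel.
#' @return A [panel_observation()].
#' @export
extract_panel_radiance <- function(rad, region, panel_reflectance = 0.20) {
  d <- dim(rad$values)
  r <- as.integer(region)
  if (length(r) != 4 || r[1] > r[2] || r[3] > r[4] ||
      r[1] < 1 || r[3] < 1 || r[2] > d[1] || r[4] > d[2]) {
    stop("panel region must be c(row1, row2, col1, col2) inside the frame",
         call. = FALSE)
  }
  v <- rad$values[r[1]:r[2], r[3]:r[4]]
  if (all(is.na(v))) stop("panel region is entirely NoData", call. = FALSE)
  panel_observation(mean(v, na.rm = TRUE), panel_reflectance)
}

#' Normalize radiance to surface reflectance against a panel
#'
#' `reflectance = radiance / panel_radiance * panel_reflectance`. Values
#' outside the plausibility window `[-0.05, 1.2]` are counted (attribute
#' `n_out_of_range`) and by default preserved, since negative reflectance is
#' a recognised quality signal of the correction.
#'
#' @param rad Radiance [mf_grid()].
#' @param panel A [panel_observation()].
#' @param clip If `TRUE`, clip results into `[0, 1]` after counting.
#' @return Reflectance [mf_grid()] with attributes `n_out_of_range` and
#'   `n_negative`.
#' @export
radiance_to_reflectance <- function(rad, panel, clip = FALSE) {
  if (!inherits(panel, "panel_observation")) {
    stop("panel must be a panel_observation", call. = FALSE)
  }
  refl <- rad$values / panel$mean_radiance * panel$panel_reflectance
  oor <- sum(refl < -0.05 | refl > 1.2, na.rm = TRUE)
  neg <- sum(refl < 0, na.rm = TRUE)
  if (clip) refl <- pmin(pmax(refl, 0), 1)
  out <- mf_grid(refl, rad$origin, rad$pixel_size, rad$crs)
  attr(out, "n_out_of_range") <- oor
  attr(out, "n_negative") <- neg
  out
}
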