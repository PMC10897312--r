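#' Physical constants for carbon upscaling
#'
#' @param daylight_hours Average daylight duration over the year (h);
#'   the Red Sea study setting uses 11.6 h.
#' @param molar_mass_c Molar mass of carbon (g mol-1). One mole of CO2
#'   assimilated carries one mole of carbon.
#' @param days_per_year Days per year used in the annual integral.
#' @param pixel_area Pixel footprint in m2, or `NULL` to take
#'   `pixel_size^2` from the raster georeference. The native-resolution
#'   override of 51.41 cm2 is `pixel_area = 51.41e-4`.
#' @return Object of class `carbon_constants`.
#' @export
carbon_constants <- function(daylight_hours = 11.6,
                             molar_mass_c = 12.011,
                             days_per_year = 365,
                             pixel_area = NULL) {
  vals <- c(daylight_hours, molar_mass_c, days_per_year,
            if (!is.null(pixel_area)) pixel_area)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all carbon constants must be positive", call. = FALSE)
  }
  structure(list(daylight_hours = daylight_hours,
                 molar_mass_c = molar_mass_c,
                 days_per_year = days_per_year,
                 pixel_area = pixel_area),
            class = "carbon_constants")
}

resolve_pixel_area <- function(constants, grid = NULL) {
  if (!is.null(constants$pixel_area)) return(constants$pixel_area)
  if (is.null(grid)) {
    stop("pixel_area not set and no georeferenced grid supplied",
         call. = FALSE)
  }
  grid$pixel_size^2
}

#' Convert net photosynthesis from umol CO2 m-2 s-1 to g C m-2 h-1
#'
#' `a * 1e-6 mol * molar_mass_c * 3600 s/h`; one mole of CO2 fixes one mole
#' of carbon.
#'
#' @param a Net photosynthesis (umol CO2 m-2 s-1).
#' @param molar_mass_c Molar mass of carbon (g mol-1).
#' @return g C m-2 h-1.
#' @export
umol_to_gC_per_h <- function(a, molar_mass_c = 12.011) {
  if (any(!is.finite(a))) stop("input flux must be finite", call. = FALSE)
  a * 1e-6 * molar_mass_c * 3600
}

#' @rdname umol_to_gC_per_h
#' @param g Flux in g C m-2 h-1.
#' @export
gC_per_h_to_umol <- function(g, molar_mass_c = 12.011) {
  if (any(!is.finite(g))) stop("input flux must be finite", call. = FALSE)
  g / (1e-6 * molar_mass_c * 3600)
}

#' Summarize leaf-level net photosynthesis records
#'
#' Arithmetic mean per group (or pooled), the coefficient of variation
#' (sample SD over mean, percent), and the mean converted to g C m-2 h-1.
#'
#' @param records Tibble of leaf-flux records (`area_label`, `local_time`,
#'   `a_umol_m2_s`), e.g. from [read_leaf_flux()] or
#'   [generate_leaf_flux()].
#' @param by Grouping: `"pooled"` (default) or `"area"`.
#' @param molar_mass_c Molar mass of carbon (g mol-1).
#' @return Tibble with `group`, `n`, `mean_a` (umol CO2 m-2 s-1),
#'   `mean_a_gC_h` (g C m-2 h-1) and `cv_pct` (%; `NA` when n < 2).
#' @export
flux_summary <- function(records, by = c("pooled", "area"),
                         molar_mass_c = 12.011) {
  by <- match.arg(by)
  records <- tibble::as_tibble(records)
  if (!nrow(records)) stop("no flux records to summarize", call. = FALSE)
  grp <- if (by == "area") records$area_label else "pooled"
  out <- records |>
    dplyr::mutate(.group = grp) |>
    dplyr::group_by(.data$.group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_a = mean(.data$a_umol_m2_s),
      sd_a = stats::sd(.data$a_umol_m2_s),
      .groups = "drop"
    ) |>
    dplyr::rename(group = ".group")
  if (any(out$n >= 2 & out$mean_a <= 0)) {
    stop("coefficient of variation undefined: group mean <= 0",
         call. = FALSE)
  }
  out |>
    dplyr::mutate(
      mean_a_gC_h = umol_to_gC_per_h(.data$mean_a, molar_mass_c),
      cv_pct = dplyr::if_else(.data$n >= 2,
                              .data$sd_a / .data$mean_a * 100, NA_real_)
    ) |>
    dplyr::select("group", "n", "mean_a", "mean_a_gC_h", "cv_pct")
}

#' Daily net canopy photosynthesis per unit ground area
#'
#' `P_N = A * d * LAI` scaled to moles:
#' `a (umol m-2 s-1) * d * 3600 (s of daylight) * LAI * 1e-6`, in
#' mol CO2 m-2 day-1. The leaf-level rate is assumed to apply over every
#' layer of leaf area for the daylight period.
#'
#' @param a Mean net photosynthesis (umol CO2 m-2 s-1).
#' @param d Daylight hours per day.
#' @param lai Leaf area index (m2 m-2), scalar or matrix/grid values.
#' @return mol CO2 m-2 day-1, same shape as `lai`.
#' @export
daily_canopy_photosynthesis <- function(a, d, lai) {
  if (d <= 0) stop("daylight hours must be > 0", call. = FALSE)
  if (any(lai < 0, na.rm = TRUE)) stop("LAI must be >= 0", call. = FALSE)
  a * (d * 3600) * lai * 1e-6
}

#' Annual per-pixel carbon assimilation map
#'
#' Integrates daily canopy photosynthesis over the year and converts to
#' mass of carbon per pixel:
#' `kg C pixel-1 yr-1 = P_N (mol m-2 day-1) * days_per_year *
#' molar_mass_c * pixel_area * 1e-3`.
#'
#' @param a Mean net photosynthesis (umol CO2 m-2 s-1).
#' @param lai_grid LAI [mf_grid()].
#' @param constants A [carbon_constants()]; `d` and the unit constants come
#'   from here. Pixel area defaults to the grid's `pixel_size^2`.
#' @return Carbon [mf_grid()] (kg C pixel-1 yr-1).
#' @export
annual_pixel_carbon <- function(a, lai_grid, constants = carbon_constants()) {
  pa <- resolve_pixel_area(constants, lai_grid)
  pn <- daily_canopy_photosynthesis(a, constants$daylight_hours,
                                    lai_grid$values)
  kg <- pn * constants$days_per_year * constants$molar_mass_c * pa * 1e-3
  out <- mf_grid(kg, lai_grid$origin, lai_grid$pixel_size, lai_grid$crs)
  attr(out, "pixel_area_m2") <- pa
  out
}

#' Mangrove canopy mask from reflectance thresholds
#'
#' A pixel counts as mangrove canopy when all three strict inequalities
#' hold: `NDVI > ndvi_min`, NIR reflectance `> nir_min`, and red
#' reflectance `< red_max`. NoData in any operand fails the mask.
#'
#' @param stack A [band_stack()].
#' @param ndvi_min,nir_min,red_max Threshold values (defaults 0.1, 0.1,
#'   0.2 — the empirically derived canopy thresholds).
#' @return Logical [mf_grid()] (`TRUE` = mangrove).
#' @export
mangrove_mask <- function(stack, ndvi_min = 0.1, nir_min = 0.1,
                          red_max = 0.2) {
  ndvi <- compute_index(stack, "NDVI")$values
  nir <- stack$bands[["842"]]
  red <- stack$bands[["668"]]
  m <- ndvi > ndvi_min & nir > nir_min & red < red_max
  m[is.na(m)] <- FALSE
  mf_grid(m, stack$origin, stack$pixel_size, stack$crs)
}

#' Aggregate a carbon map to area totals and rates
#'
#' Sums the masked per-pixel annual carbon, converts kg to metric tonnes,
#' and reports mangrove area and the areal assimilation rate.
#'
#' @param carbon Carbon [mf_grid()] (kg C pixel-1 yr-1).
#' @param mask Logical [mf_grid()] from [mangrove_mask()], georeferenced
#'   like `carbon`.
#' @param constants A [carbon_constants()].
#' @param label Optional area label carried into the output.
#' @return One-row tibble: `area_label`, `mangrove_pixels`, `area_km2`,
#'   `total_tonC_yr`, `rate_tonC_km2_yr` (`NA` when the mask is empty).
#' @export
area_carbon_summary <- function(carbon, mask,
                                constants = carbon_constants(),
                                label = NA_character_) {
  if (!same_georef(carbon, mask)) stop_georef_mismatch("carbon map and mask")
  pa <- resolve_pixel_area(constants, carbon)
  sel <- mask$values & !is.na(carbon$values)
  npix <- sum(sel)
  total_ton <- sum(carbon$values[sel]) / 1000
  area_km2 <- npix * pa / 1e6
  tibble::tibble(
    area_label = label,
    mangrove_pixels = npix,
    area_km2 = area_km2,
    total_tonC_yr = total_ton,
    rate_tonC_km2_yr = if (area_km2 > 0) total_ton / area_km2 else NA_real_
  )
}

#' Average areal assimilation rate across study areas
#'
#' Unweighted arithmetic mean of per-area rates (ton C km-2 yr-1).
#'
#' @param rates Numeric vector of per-area rates.
#' @return Scalar mean rate.
#' @export
average_rate <- function(rates) {
  if (!length(rates)) stop("no rates supplied", call. = FALSE)
  mean(rates)
}
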