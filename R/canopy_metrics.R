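#' Index formulas over the five reflectance bands
#'
#' The seven band-combination indices computed from the stack. Each entry is
#' a function of the named band matrices.
#' @keywords internal
INDEX_FORMULAS <- list(
  blueNDVI   = function(b) (b[["842"]] - b[["475"]]) / (b[["842"]] + b[["475"]]),
  greenNDVI  = function(b) (b[["842"]] - b[["560"]]) / (b[["842"]] + b[["560"]]),
  NDRE       = function(b) (b[["842"]] - b[["717"]]) / (b[["842"]] + b[["717"]]),
  NDVI       = function(b) (b[["842"]] - b[["668"]]) / (b[["842"]] + b[["668"]]),
  NIR.RE.Red = function(b) (b[["842"]] + b[["717"]] - b[["668"]]) /
                           (b[["842"]] + b[["717"]] + b[["668"]]),
  RE.Green   = function(b) (b[["717"]] - b[["560"]]) / (b[["717"]] + b[["560"]]),
  RENDVI     = function(b) (b[["717"]] - b[["668"]]) / (b[["717"]] + b[["668"]])
)

#' Names of the vegetation indices
#' @return Character vector of the seven index names.
#' @export
index_names <- function() names(INDEX_FORMULAS)

#' Names of the 13 LAI predictors, in canonical order
#'
#' Five reflectance bands, seven vegetation indices, and the canopy height
#' model.
#' @return Character vector of length 13.
#' @export
predictor_names <- function() {
  c(paste0("b", MF_BANDS), index_names(), "CHM")
}

#' Canopy height model from surface and terrain models
#'
#' `CHM = DSM - DTM`, with negative differences (terrain noise, water
#' surfaces) clamped to zero and NoData propagated.
#'
#' @param dsm,dtm Elevation [mf_grid()]s sharing shape and georeference
#'   (metres above datum).
#' @return Canopy-height [mf_grid()] in metres.
#' @export
compute_chm <- function(dsm, dtm) {
  if (!same_georef(dsm, dtm)) stop_georef_mismatch("DSM and DTM")
  chm <- pmax(dsm$values - dtm$values, 0)
  mf_grid(chm, dsm$origin, dsm$pixel_size, dsm$crs)
}

#' Compute one vegetation index over a reflectance stack
#'
#' Applies the exact published formula per pixel. A zero denominator or
#' NoData in any input band yields NoData.
#'
#' @param stack A [band_stack()].
#' @param name Index name, one of [index_names()].
#' @return An [mf_grid()] of unitless index values.
#' @export
compute_index <- function(stack, name) {
  if (!name %in% names(INDEX_FORMULAS)) {
    stop("unknown index '", name, "'; valid names: ",
         paste(index_names(), collapse = ", "), call. = FALSE)
  }
  v <- INDEX_FORMULAS[[name]](stack$bands)
  v[!is.finite(v)] <- NA_real_
  mf_grid(v, stack$origin, stack$pixel_size, stack$crs)
}

#' All predictor layers as named grids
#'
#' @param stack A [band_stack()].
#' @param chm Canopy-height [mf_grid()] on the same georeference.
#' @return Named list of 13 [mf_grid()]s in [predictor_names()] order.
#' @export
predictor_layers <- function(stack, chm) {
  ref <- stack_band(stack, "842")
  if (!same_georef(ref, chm)) stop_georef_mismatch("stack and CHM")
  layers <- c(
    stats::setNames(lapply(MF_BANDS, function(b) stack_band(stack, b)),
                    paste0("b", MF_BANDS)),
    stats::setNames(lapply(index_names(), function(n) compute_index(stack, n)),
                    index_names()),
    list(CHM = chm)
  )
  layers[predictor_names()]
}

# Logical matrix of pixels whose centres fall inside the plot footprint
# (half-open axis-aligned square of side `side` centred on (cx, cy)).
footprint_mask <- function(grid, cx, cy, side) {
  cc <- pixel_centers(grid)
  inx <- cc$x >= (cx - side / 2) & cc$x < (cx + side / 2)
  iny <- cc$y > (cy - side / 2) & cc$y <= (cy + side / 2)
  outer(iny, inx, `&`)
}

#' Plot-level predictor means joined to ground LAI
#'
#' For each field plot, averages every predictor layer over the pixels whose
#' centres fall inside the plot footprint (axis-aligned square of side
#' `side_m` centred on the recorded centre), excluding NoData. A plot must
#' retain at least `min_valid` of its footprint pixels for every predictor.
#'
#' @param stack A [band_stack()].
#' @param chm Canopy-height [mf_grid()].
#' @param plots Plot-record tibble ([read_plot_records()] /
#'   [validate_plot_records()]).
#' @param min_valid Minimum valid-pixel fraction per footprint (default 0.25).
#' @return Tibble, one row per plot: `plot_id`, `area_label`, the 13
#'   predictor means, and `lai_mean` (the response).
#' @export
predictor_table <- function(stack, chm, plots, min_valid = 0.25) {
  plots <- validate_plot_records(plots)
  layers <- predictor_layers(stack, chm)
  rows <- purrr::pmap(
    list(plots$plot_id, plots$x, plots$y, plots$side_m),
    function(pid, cx, cy, side) {
      mask <- footprint_mask(layers[[1]], cx, cy, side)
      npix <- sum(mask)
      if (npix == 0) {
        stop("plot '", pid, "' footprint lies outside the raster",
             call. = FALSE)
      }
      means <- vapply(names(layers), function(nm) {
        v <- layers[[nm]]$values[mask]
        ok <- !is.na(v)
        if (sum(ok) < min_valid * npix) {
          stop("plot '", pid, "' has under ", round(100 * min_valid),
               "% valid pixels for predictor ", nm, call. = FALSE)
        }
        mean(v[ok])
      }, numeric(1))
      tibble::as_tibble(as.list(means))
    }
  )
  dplyr::bind_cols(
    plots[c("plot_id", "area_label")],
    dplyr::bind_rows(rows),
    plots["lai_mean"]
  )
}
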