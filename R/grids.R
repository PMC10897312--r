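#' Georeferenced single-layer grid
#'
#' A lightweight container for one raster layer: a numeric matrix plus a
#' map-coordinate anchor. The georeference model is deliberately simple:
#' square pixels of size `pixel_size` metres, anchored at the map coordinates
#' of the *top-left corner* of the grid, rows running south (down) and
#' columns east (right). Missing pixels are `NA` in memory; the NoData
#' sentinel only appears in files.
#'
#' @param values Numeric matrix (rows x cols).
#' @param origin Length-2 numeric, map x/y of the top-left corner (m).
#' @param pixel_size Pixel edge length in metres (> 0).
#' @param crs Free-text CRS label carried through unchanged.
#' @return An object of class `mf_grid`.
#' @export
mf_grid <- function(values, origin = c(0, 0), pixel_size = 1,
                    crs = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values) && !is.logical(values)) {
    stop("grid values must be numeric", call. = FALSE)
  }
  if (length(origin) != 2 || !is.numeric(origin) || anyNA(origin)) {
    stop("origin must be two finite map coordinates", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values,
         origin = as.numeric(origin),
         pixel_size = as.numeric(pixel_size),
         crs = crs),
    class = "mf_grid"
  )
}

#' @export
dim.mf_grid <- function(x) dim(x$values)

#' @export
print.mf_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<mf_grid> %d x %d pixels @ %g m, origin (%g, %g)\n",
              d[1], d[2], x$pixel_size, x$origin[1], x$origin[2]))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  values: [%.4g, %.4g], %d NA of %d\n",
                min(v), max(v), sum(is.na(x$values)), length(x$values)))
  }
  invisible(x)
}

georef_of <- function(g) list(origin = g$origin, pixel_size = g$pixel_size)

same_georef <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    abs(a$pixel_size - b$pixel_size) < tol
}

stop_georef_mismatch <- function(what) {
  stop(sprintf("georeference or shape mismatch between %s", what),
       call. = FALSE)
}

#' Map coordinates of pixel centres
#'
#' @param grid An [mf_grid()].
#' @return List with numeric vectors `x` (per column) and `y` (per row).
#' @keywords internal
pixel_centers <- function(grid) {
  d <- dim(grid$values)
  list(
    x = grid$origin[1] + (seq_len(d[2]) - 0.5) * grid$pixel_size,
    y = grid$origin[2] - (seq_len(d[1]) - 0.5) * grid$pixel_size
  )
}

MF_BANDS <- c("475", "560", "668", "717", "842")

#' Five-band reflectance stack
#'
#' Bundles the five MicaSense-style reflectance layers (475, 560, 668, 717,
#' 842 nm) that all index, mask and prediction steps consume. All bands must
#' share shape and georeference.
#'
#' @param bands Named list of matrices (names `"475"`, `"560"`, `"668"`,
#'   `"717"`, `"842"`), or of [mf_grid()] objects with identical georefs.
#' @inheritParams mf_grid
#' @return An object of class `band_stack`.
#' @export
band_stack <- function(bands, origin = c(0, 0), pixel_size = 1,
                       crs = NA_character_) {
  if (!all(MF_BANDS %in% names(bands))) {
    stop("band_stack needs all five bands: ",
         paste(MF_BANDS, collapse = ", "), call. = FALSE)
  }
  bands <- bands[MF_BANDS]
  if (inherits(bands[[1]], "mf_grid")) {
    ref <- bands[[1]]
    for (b in bands[-1]) {
      if (!same_georef(ref, b)) stop_georef_mismatch("stack bands")
    }
    origin <- ref$origin; pixel_size <- ref$pixel_size; crs <- ref$crs
    bands <- lapply(bands, `[[`, "values")
  }
  bands <- lapply(bands, as.matrix)
  d <- dim(bands[[1]])
  if (!all(vapply(bands, function(m) identical(dim(m), d), logical(1)))) {
    stop("all bands must share the same shape", call. = FALSE)
  }
  structure(
    list(bands = bands, origin = as.numeric(origin),
         pixel_size = as.numeric(pixel_size), crs = crs),
    class = "band_stack"
  )
}

#' @export
dim.band_stack <- function(x) dim(x$bands[[1]])

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<band_stack> 5 bands (%s nm), %d x %d pixels @ %g m\n",
              paste(MF_BANDS, collapse = "/"), d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Extract one band of a stack as a grid
#' @param stack A [band_stack()].
#' @param band Band label, one of `"475"`, `"560"`, `"668"`, `"717"`, `"842"`.
#' @return An [mf_grid()].
#' @export
stack_band <- function(stack, band) {
  band <- as.character(band)
  if (!band %in% MF_BANDS) {
    stop("unknown band '", band, "'; expected one of ",
         paste(MF_BANDS, collapse = ", "), call. = FALSE)
  }
  mf_grid(stack$bands[[band]], stack$origin, stack$pixel_size, stack$crs)
}

#' Turn a grid into a long tibble of pixels
#'
#' One row per pixel with map-coordinate centres; mostly a plotting and
#' inspection aid.
#'
#' @param grid An [mf_grid()].
#' @param drop_na Drop NA pixels?
#' @return Tibble with columns `x`, `y`, `row`, `col`, `value`.
#' @export
grid_to_tibble <- function(grid, drop_na = FALSE) {
  d <- dim(grid$values)
  cc <- pixel_centers(grid)
  out <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    x = rep(cc$x, each = d[1]),
    y = rep(cc$y, times = d[2]),
    value = as.vector(grid$values)
  )
  if (drop_na) out <- out[!is.na(out$value), ]
  out
}
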