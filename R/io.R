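#' Read and write grids as ESRI ASCII rasters
#'
#' Plain-text `.asc` raster exchange: a six-line header
#' (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/`nodata_value`)
#' followed by rows of values, north to south. `NA` pixels round-trip
#' through the NoData sentinel.
#'
#' @param grid An [mf_grid()].
#' @param path File path.
#' @param nodata NoData sentinel written to file.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns an [mf_grid()].
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  d <- dim(grid$values)
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - d[1] * grid$pixel_size),
    sprintf("cellsize %.10g", grid$pixel_size),
    sprintf("nodata_value %.10g", nodata)
  )
  body <- apply(v, 1, function(r) paste(format(r, digits = 10, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param crs Optional CRS label to attach on read.
#' @export
read_ascii_grid <- function(path, crs = NA_character_) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[[`, character(1), 1))
  vals <- as.numeric(vapply(kv, `[[`, character(1), 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  nr <- as.integer(vals["nrows"]); nc <- as.integer(vals["ncols"])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != nr * nc) {
    stop("ASCII grid body has ", length(body), " values, expected ",
         nr * nc, call. = FALSE)
  }
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA_real_
  mf_grid(m,
          origin = c(vals["xllcorner"],
                     vals["yllcorner"] + nr * vals["cellsize"]),
          pixel_size = vals["cellsize"], crs = crs)
}

#' Read and write a five-band stack as per-band ASCII grids
#'
#' Bands are stored as `band_475.asc` ... `band_842.asc` in one directory.
#'
#' @param stack A [band_stack()].
#' @param dir Directory (created if missing).
#' @return `write_band_stack()` returns `dir` invisibly;
#'   `read_band_stack()` a [band_stack()].
#' @export
write_band_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in MF_BANDS) {
    write_ascii_grid(stack_band(stack, b),
                     file.path(dir, paste0("band_", b, ".asc")))
  }
  invisible(dir)
}

#' @rdname write_band_stack
#' @export
read_band_stack <- function(dir) {
  grids <- lapply(MF_BANDS, function(b) {
    f <- file.path(dir, paste0("band_", b, ".asc"))
    if (!file.exists(f)) stop("missing band file ", f, call. = FALSE)
    read_ascii_grid(f)
  })
  names(grids) <- MF_BANDS
  band_stack(grids)
}

#' Read field plot records from CSV
#'
#' Expected columns: `plot_id`, `x`, `y`, `side_m`, `lai_1` ... `lai_5`,
#' `area_label`. `lai_mean` is recomputed as the arithmetic mean of the
#' readings.
#'
#' @param path CSV path.
#' @return A tibble of plot records, one row per plot, with a `lai_mean`
#'   column.
#' @export
read_plot_records <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_plot_records(df)
}

#' Validate (and complete) a plot-record table
#' @param df Data frame of plot records.
#' @return The validated tibble with `lai_mean` recomputed.
#' @export
validate_plot_records <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("plot_id", "x", "y", "side_m", "area_label")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("plot table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lai_cols <- grep("^lai_[0-9]+$", names(df), value = TRUE)
  if (!length(lai_cols)) stop("plot table has no lai_* reading columns",
                              call. = FALSE)
  readings <- as.matrix(df[lai_cols])
  if (any(!is.finite(readings)) || any(readings < 0)) {
    stop("LAI readings must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(df$side_m)) || any(df$side_m <= 0)) {
    stop("plot side_m must be positive", call. = FALSE)
  }
  df$lai_mean <- rowMeans(readings)
  df
}

#' Read leaf-level net photosynthesis records from CSV
#'
#' Expected columns: `area_label`, `local_time` (decimal hours),
#' `a_umol_m2_s` (net photosynthesis, umol CO2 m-2 s-1).
#'
#' @param path CSV path.
#' @return Tibble of leaf-flux records.
#' @export
read_leaf_flux <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("area_label", "local_time", "a_umol_m2_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("flux table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$a_umol_m2_s))) {
    stop("a_umol_m2_s must be finite", call. = FALSE)
  }
  if (any(df$local_time < 0 | df$local_time >= 24)) {
    stop("local_time must be in [0, 24)", call. = FALSE)
  }
  tibble::as_tibble(df)
}
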