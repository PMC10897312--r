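# Spectral endmembers for the synthetic scenes. Canopy band responses move
# from their bare-soil value toward the dense-canopy value with
# 1 - exp(-k * LAI) (Beer-Lambert-style light attenuation); water and soil
# backgrounds are flat spectra chosen to fail the canopy mask.
SCENE_SPECTRA <- list(
  canopy = list(
    ndvi_soil = 0.05, ndvi_veg = 0.92,
    red_soil = 0.15, red_veg = 0.03,
    green_soil = 0.08, green_veg = 0.11,
    blue_soil = 0.07, blue_veg = 0.04,
    re_soil = 0.12, re_veg = 0.35
  ),
  water = c(`475` = 0.07, `560` = 0.06, `668` = 0.05, `717` = 0.03,
            `842` = 0.02),
  soil = c(`475` = 0.15, `560` = 0.22, `668` = 0.30, `717` = 0.28,
           `842` = 0.28)
)

#' Configuration of a synthetic mangrove scene
#'
#' Parameters of the seeded generator used to exercise the full pipeline:
#' a patchy smooth LAI field, five reflectance bands whose NDVI saturates
#' with LAI, a canopy-height surface proportional to LAI, water/soil
#' background that fails the canopy mask, and diurnally declining leaf-flux
#' records. Defaults emulate the study conditions: LAI spanning roughly
#' 0.19-4.34, 119 plots over three areas, pooled mean net photosynthesis
#' 10.35 umol CO2 m-2 s-1 with the highest values in the first morning
#' hours.
#'
#' @param seed Integer seed; fixes every random draw.
#' @param rows,cols Grid size in pixels.
#' @param pixel_size Pixel edge (m).
#' @param n_patches,patch_radius_m Canopy patch count and radius (m).
#' @param lai_min,lai_max Canopy LAI range (m2 m-2).
#' @param k Saturation constant of the index-vs-LAI response (m2 m-2)^-1.
#' @param band_noise_sd Reflectance noise SD added per band.
#' @param chm_gain Canopy height per unit LAI (m).
#' @param chm_noise_sd Height noise SD (m).
#' @param water_fraction Share of background pixels that are water (rest
#'   soil).
#' @param n_plots Field plot count (default 119 over areas A/B/C).
#' @param plot_noise_sd SD of individual below-canopy LAI readings around
#'   the true footprint mean.
#' @param flux_mean Pooled mean net photosynthesis (umol CO2 m-2 s-1).
#' @param flux_decline Decline of net photosynthesis per hour after the
#'   morning maximum (umol CO2 m-2 s-1 h-1).
#' @param flux_noise_sd Record-level flux noise SD.
#' @param flux_area_offsets Named per-area offsets added to the diurnal
#'   profile (umol CO2 m-2 s-1).
#' @param flux_n_per_area Named record counts per area.
#' @param flux_midday_gap Areas with no records between 12:00 and 16:00
#'   (field sampling precluded by heat in the warm seasons).
#' @return List of class `scene_config`.
#' @export
scene_config <- function(seed = 1L,
                         rows = 400L, cols = 400L, pixel_size = 0.5,
                         n_patches = 8L, patch_radius_m = 32,
                         lai_min = 0.15, lai_max = 4.5, k = 0.9,
                         band_noise_sd = 0.01,
                         chm_gain = 0.7, chm_noise_sd = 0.05,
                         water_fraction = 0.5,
                         n_plots = 119L, plot_noise_sd = 0.25,
                         flux_mean = 10.35, flux_decline = 0.6,
                         flux_noise_sd = 4.5,
                         flux_area_offsets = c(A = 3, B = 0, C = -3),
                         flux_n_per_area = c(A = 60, B = 150, C = 80),
                         flux_midday_gap = c("A", "B")) {
  if (rows < 40 || cols < 40) {
    stop("scene grid too small; need at least 40 x 40 pixels",
         call. = FALSE)
  }
  stopifnot(pixel_size > 0, lai_max > lai_min, lai_min >= 0, k > 0,
            band_noise_sd >= 0, chm_gain > 0, n_plots > 0)
  structure(as.list(environment()), class = "scene_config")
}

# Smooth pseudo-random field: coarse Gaussian noise, bilinearly upsampled
# (separable linear interpolation along columns, then rows).
smooth_field <- function(rows, cols, coarse = 12) {
  nr <- max(3, coarse); nc <- max(3, coarse)
  Z <- matrix(stats::rnorm(nr * nc), nr, nc)
  xg <- seq(1, cols, length.out = nc)
  yg <- seq(1, rows, length.out = nr)
  Zx <- t(apply(Z, 1, function(r) stats::approx(xg, r, seq_len(cols))$y))
  apply(Zx, 2, function(cn) stats::approx(yg, cn, seq_len(rows))$y)
}

canopy_band_value <- function(lai, soil, veg, k) {
  soil + (veg - soil) * (1 - exp(-k * lai))
}

#' Generate a synthetic mangrove scene
#'
#' Builds a band stack, DSM/DTM pair, and truth layers (true LAI and true
#' canopy mask) with the statistical structure the pipeline assumes. Canopy
#' NDVI follows `ndvi_soil + (ndvi_veg - ndvi_soil)(1 - exp(-k LAI))`
#' exactly (red declines with LAI and NIR is solved to match), so with zero
#' band noise NDVI can be inverted back to LAI (see [invert_ndvi_lai()]).
#' The DSM equals the DTM plus `chm_gain * LAI` plus noise. Background
#' pixels are water or soil spectra that fail the canopy mask. Output is
#' bit-reproducible per seed.
#'
#' @param config A [scene_config()].
#' @return List of class `mf_scene`: `stack` ([band_stack()]), `dsm`,
#'   `dtm`, `lai` (true LAI [mf_grid()]), `canopy` (logical truth mask),
#'   `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  rows <- config$rows; cols <- config$cols; ps <- config$pixel_size
  sp <- SCENE_SPECTRA$canopy

  # canopy patch mask
  cx <- stats::runif(config$n_patches, 0.1, 0.9) * cols * ps
  cy <- stats::runif(config$n_patches, 0.1, 0.9) * rows * ps
  px <- (seq_len(cols) - 0.5) * ps
  py <- (seq_len(rows) - 0.5) * ps
  canopy <- matrix(FALSE, rows, cols)
  for (i in seq_len(config$n_patches)) {
    dd <- outer((py - cy[i])^2, (px - cx[i])^2, `+`)
    canopy <- canopy | (dd <= config$patch_radius_m^2)
  }

  # smooth LAI field over canopy, 0 elsewhere
  f <- smooth_field(rows, cols)
  f <- (f - min(f)) / (max(f) - min(f))
  lai <- matrix(0, rows, cols)
  lai[canopy] <- config$lai_min +
    (config$lai_max - config$lai_min) * f[canopy]

  # water/soil split of the background
  bg <- smooth_field(rows, cols, coarse = 6)
  is_bg <- !canopy
  thr <- stats::quantile(bg[is_bg], config$water_fraction)
  water <- is_bg & bg <= thr
  soil <- is_bg & !water

  # canopy spectra: red declines with LAI, NIR solved to give the target
  # NDVI response exactly; other bands follow their own saturation curves
  ndvi <- canopy_band_value(lai, sp$ndvi_soil, sp$ndvi_veg, config$k)
  red <- canopy_band_value(lai, sp$red_soil, sp$red_veg, config$k)
  nir <- red * (1 + ndvi) / (1 - ndvi)
  green <- canopy_band_value(lai, sp$green_soil, sp$green_veg, config$k)
  blue <- canopy_band_value(lai, sp$blue_soil, sp$blue_veg, config$k)
  re <- canopy_band_value(lai, sp$re_soil, sp$re_veg, config$k)
  bands <- list(`475` = blue, `560` = green, `668` = red, `717` = re,
                `842` = nir)
  for (b in names(SCENE_SPECTRA$water)) {
    bands[[b]][water] <- SCENE_SPECTRA$water[[b]]
    bands[[b]][soil] <- SCENE_SPECTRA$soil[[b]]
  }
  if (config$band_noise_sd > 0) {
    bands <- lapply(bands, function(m) {
      pmax(m + matrix(stats::rnorm(rows * cols, 0, config$band_noise_sd),
                      rows, cols), 0)
    })
  }

  # terrain and surface models
  dtm_vals <- 0.3 + 0.2 * smooth_field(rows, cols, coarse = 5)
  dsm_vals <- dtm_vals + config$chm_gain * lai
  if (config$chm_noise_sd > 0) {
    dsm_vals <- dsm_vals +
      matrix(stats::rnorm(rows * cols, 0, config$chm_noise_sd), rows, cols)
    dsm_vals <- pmax(dsm_vals, dtm_vals)
  }

  origin <- c(0, rows * ps)
  structure(
    list(
      stack = band_stack(bands, origin = origin, pixel_size = ps),
      dsm = mf_grid(dsm_vals, origin, ps),
      dtm = mf_grid(dtm_vals, origin, ps),
      lai = mf_grid(lai, origin, ps),
      canopy = mf_grid(canopy, origin, ps),
      config = config
    ),
    class = "mf_scene"
  )
}

#' Back-solve LAI from a noise-free synthetic NDVI value
#'
#' Inverts the generator's saturation response; only meaningful for canopy
#' pixels of a zero-noise scene.
#'
#' @param ndvi NDVI values.
#' @param config The [scene_config()] the scene was generated with.
#' @return LAI values (m2 m-2).
#' @export
invert_ndvi_lai <- function(ndvi, config) {
  sp <- SCENE_SPECTRA$canopy
  frac <- (ndvi - sp$ndvi_soil) / (sp$ndvi_veg - sp$ndvi_soil)
  -log(1 - pmin(pmax(frac, 0), 1 - 1e-12)) / config$k
}

#' Sample field plots from a synthetic scene
#'
#' Lays a non-overlapping grid of square plot cells over the scene, keeps
#' cells that are predominantly canopy, and picks `n` of them stratified
#' across the true LAI range. Each plot gets five below-canopy readings:
#' the true footprint-mean LAI plus Gaussian noise, truncated at zero.
#' Plots are split across areas A/B/C by LAI-ordered thirds.
#'
#' @param scene An `mf_scene`.
#' @param n Number of plots (default from the scene config).
#' @param noise_sd Reading noise SD (default from the scene config).
#' @param side Plot side (m).
#' @param min_canopy Minimum canopy fraction for a candidate cell.
#' @return Tibble of plot records (see [read_plot_records()]).
#' @export
sample_plots <- function(scene, n = scene$config$n_plots,
                         noise_sd = scene$config$plot_noise_sd,
                         side = 10, min_canopy = 0.8) {
  set.seed(scene$config$seed + 1L)
  ps <- scene$lai$pixel_size
  cells_per_side <- floor(side / ps)
  if (cells_per_side < 1) stop("plot side below one pixel", call. = FALSE)
  nrc <- floor(nrow(scene$lai$values) / cells_per_side)
  ncc <- floor(ncol(scene$lai$values) / cells_per_side)

  cand <- list()
  for (i in seq_len(nrc)) {
    for (j in seq_len(ncc)) {
      rr <- ((i - 1) * cells_per_side + 1):(i * cells_per_side)
      cc <- ((j - 1) * cells_per_side + 1):(j * cells_per_side)
      frac <- mean(scene$canopy$values[rr, cc])
      if (frac >= min_canopy) {
        cand[[length(cand) + 1]] <- c(i = i, j = j,
                                      lai = mean(scene$lai$values[rr, cc]))
      }
    }
  }
  if (length(cand) < n) {
    stop("canopy too small: only ", length(cand),
         " candidate plot cells for n = ", n, call. = FALSE)
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, "lai"]), , drop = FALSE]
  pick <- unique(round(seq(1, nrow(cand), length.out = n)))
  while (length(pick) < n) {  # fill ties from unused candidates
    pool <- setdiff(seq_len(nrow(cand)), pick)
    pick <- sort(c(pick, pool[seq_len(n - length(pick))]))
  }
  sel <- cand[pick, , drop = FALSE]

  origin <- scene$lai$origin
  centers_x <- origin[1] + (sel[, "j"] - 0.5) * cells_per_side * ps
  centers_y <- origin[2] - (sel[, "i"] - 0.5) * cells_per_side * ps
  readings <- vapply(seq_len(n), function(r) {
    pmax(sel[r, "lai"] + stats::rnorm(5, 0, noise_sd), 0)
  }, numeric(5))
  area <- rep(c("A", "B", "C"), length.out = 3)[
    cut(seq_len(n), 3, labels = FALSE)]
  ord <- sample(n)  # decouple area label from the LAI ordering
  df <- tibble::tibble(
    plot_id = sprintf("P%03d", seq_len(n)),
    x = centers_x[ord], y = centers_y[ord],
    side_m = side,
    lai_1 = readings[1, ord], lai_2 = readings[2, ord],
    lai_3 = readings[3, ord], lai_4 = readings[4, ord],
    lai_5 = readings[5, ord],
    area_label = area,
    true_lai = sel[ord, "lai"]
  )
  validate_plot_records(df)
}

#' Generate synthetic leaf-level net photosynthesis records
#'
#' Records over daylight hours with a linearly declining expected rate
#' (highest in the first morning hours), per-area offsets, Gaussian noise,
#' and an optional midday sampling gap. The deterministic part is shifted
#' so that its pooled mean equals `flux_mean`; with zero noise the pooled
#' sample mean matches it exactly.
#'
#' @param config A [scene_config()] (flux parameters are read from it).
#' @return Tibble of leaf-flux records (`area_label`, `local_time`,
#'   `a_umol_m2_s`).
#' @export
generate_leaf_flux <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed + 2L)
  areas <- names(config$flux_n_per_area)
  recs <- purrr::map(areas, function(ar) {
    n <- config$flux_n_per_area[[ar]]
    t <- sort(stats::runif(n, 6.5, 18))
    if (ar %in% config$flux_midday_gap) {
      gap <- t >= 12 & t < 16
      t[gap] <- ifelse(stats::runif(sum(gap)) < 0.5,
                       stats::runif(sum(gap), 6.5, 12),
                       stats::runif(sum(gap), 16, 18))
      t <- sort(t)
    }
    tibble::tibble(
      area_label = ar,
      local_time = t,
      expected = -config$flux_decline * (t - 6.5) +
        config$flux_area_offsets[[ar]]
    )
  }) |> dplyr::bind_rows()
  recs$expected <- recs$expected + (config$flux_mean - mean(recs$expected))
  recs$a_umol_m2_s <- recs$expected +
    stats::rnorm(nrow(recs), 0, config$flux_noise_sd)
  recs[c("area_label", "local_time", "a_umol_m2_s")]
}
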