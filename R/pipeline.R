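#' Default pipeline configuration
#'
#' One structured list drives every stage. All physical constants are
#' surfaced as named keys with their study-default values: daylight hours
#' 11.6 h, molar mass of carbon 12.011 g mol-1, 365 days, mask thresholds
#' NDVI > 0.1 / NIR > 0.1 / Red < 0.2, and the optional native pixel-area
#' override of 51.41 cm2 (`pixel_area_cm2`, unset by default so the area
#' comes from the raster georeference).
#'
#' @param output_dir Directory where all stage artifacts are written.
#' @param seed Seed for the `simulate` stage.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(output_dir = "mangroveflux_run",
                                    seed = 1L) {
  list(
    output_dir = output_dir,
    seed = seed,
    scene = list(),  # scene_config() overrides for simulate
    constants = list(
      daylight_hours = 11.6,
      molar_mass_c = 12.011,
      days_per_year = 365,
      pixel_area_cm2 = NULL
    ),
    mask = list(ndvi_min = 0.1, nir_min = 0.1, red_max = 0.2),
    paths = list(
      stack_dir = file.path(output_dir, "stack"),
      dsm = file.path(output_dir, "dsm.asc"),
      dtm = file.path(output_dir, "dtm.asc"),
      plots_csv = file.path(output_dir, "plots.csv"),
      flux_csv = file.path(output_dir, "leaf_flux.csv"),
      chm = file.path(output_dir, "chm.asc"),
      indices_dir = file.path(output_dir, "indices"),
      predictor_csv = file.path(output_dir, "predictor_table.csv"),
      model_json = file.path(output_dir, "lai_model.json"),
      importance_csv = file.path(output_dir, "importance.csv"),
      lai_map = file.path(output_dir, "lai_map.asc"),
      carbon_map = file.path(output_dir, "carbon_map.asc"),
      carbon_summary = file.path(output_dir, "carbon_summary.json"),
      truth_lai = file.path(output_dir, "truth_lai.asc"),
      truth_json = file.path(output_dir, "truth.json")
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected with their key path; missing keys fall back to
#' [default_pipeline_config()] values.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_pipeline_config(
    output_dir = user$output_dir %||% "mangroveflux_run",
    seed = user$seed %||% 1L
  )
  merge_config(base, user, "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    path <- paste0(prefix, key)
    if (!key %in% names(base) && prefix %in% c("", "constants.", "mask.",
                                               "paths.", "scene.") &&
        prefix != "scene.") {
      stop("unknown config key: ", path, call. = FALSE)
    }
    if (is.list(user[[key]]) && is.list(base[[key]]) &&
        !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  paste0(path, "."))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

config_constants <- function(config) {
  cc <- config$constants
  carbon_constants(
    daylight_hours = cc$daylight_hours,
    molar_mass_c = cc$molar_mass_c,
    days_per_year = cc$days_per_year,
    pixel_area = if (!is.null(cc$pixel_area_cm2)) cc$pixel_area_cm2 * 1e-4
  )
}

require_artifact <- function(path, produced_by) {
  ok <- if (grepl("\\.asc$|\\.csv$|\\.json$", path)) file.exists(path)
        else dir.exists(path)
  if (!ok) {
    stop("missing input '", path, "'; run stage '", produced_by,
         "' first", call. = FALSE)
  }
}

write_manifest <- function(config, stage, inputs, outputs, extra = list()) {
  manifest <- c(list(
    stage = stage,
    inputs = inputs,
    outputs = outputs,
    parameters = list(constants = config$constants, mask = config$mask,
                      seed = config$seed),
    package_version = as.character(utils::packageVersion("mangroveflux")),
    timestamp = format(Sys.time(), tz = "UTC")
  ), extra)
  path <- file.path(config$output_dir,
                    sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (write a synthetic scene, plots, flux records and
#' truth bundle), `calibrate` (raw frame + calibration JSON to reflectance;
#' only when raw inputs are configured), `indices` (CHM and the seven
#' vegetation indices), `fit-lai` (plot predictor table, regression fit,
#' LOOCV, LMG importances), `predict-lai` (wall-to-wall LAI map), `carbon`
#' (flux summary, carbon map under the canopy mask, area summary), and
#' `all` (everything in dependency order). Each stage writes its artifacts
#' plus a JSON run manifest recording inputs, parameters and quality
#' counts; missing upstream artifacts raise an error naming the stage to
#' run first.
#'
#' @param stage Stage name.
#' @param config Configuration list ([default_pipeline_config()] /
#'   [read_pipeline_config()]).
#' @return Invisibly, a named list of artifact paths written by the
#'   stage(s).
#' @export
run_stage <- function(stage = c("all", "simulate", "indices", "fit-lai",
                                "predict-lai", "carbon"),
                      config = default_pipeline_config()) {
  stage <- match.arg(stage)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    out <- list()
    for (s in c("indices", "fit-lai", "predict-lai", "carbon")) {
      out <- c(out, run_stage(s, config))
    }
    return(invisible(out))
  }
  p <- config$paths
  switch(stage,
    simulate = {
      sc_args <- c(list(seed = config$seed), config$scene)
      sc <- do.call(scene_config, sc_args)
      scene <- generate_scene(sc)
      plots <- sample_plots(scene)
      flux <- generate_leaf_flux(sc)
      write_band_stack(scene$stack, p$stack_dir)
      write_ascii_grid(scene$dsm, p$dsm)
      write_ascii_grid(scene$dtm, p$dtm)
      readr::write_csv(plots, p$plots_csv)
      readr::write_csv(flux, p$flux_csv)
      write_ascii_grid(scene$lai, p$truth_lai)
      truth <- list(
        mean_canopy_lai = mean(scene$lai$values[scene$canopy$values]),
        canopy_pixels = sum(scene$canopy$values),
        pixel_size = scene$lai$pixel_size
      )
      jsonlite::write_json(truth, p$truth_json, auto_unbox = TRUE,
                           digits = NA)
      write_manifest(config, "simulate", inputs = list(seed = config$seed),
                     outputs = p[c("stack_dir", "dsm", "dtm", "plots_csv",
                                   "flux_csv", "truth_lai", "truth_json")])
      invisible(p[c("stack_dir", "dsm", "dtm", "plots_csv", "flux_csv",
                    "truth_lai", "truth_json")])
    },
    indices = {
      require_artifact(p$stack_dir, "simulate")
      require_artifact(p$dsm, "simulate")
      require_artifact(p$dtm, "simulate")
      stack <- read_band_stack(p$stack_dir)
      chm <- compute_chm(read_ascii_grid(p$dsm), read_ascii_grid(p$dtm))
      write_ascii_grid(chm, p$chm)
      dir.create(p$indices_dir, showWarnings = FALSE, recursive = TRUE)
      for (nm in index_names()) {
        write_ascii_grid(compute_index(stack, nm),
                         file.path(p$indices_dir, paste0(nm, ".asc")))
      }
      write_manifest(config, "indices",
                     inputs = p[c("stack_dir", "dsm", "dtm")],
                     outputs = p[c("chm", "indices_dir")])
      invisible(p[c("chm", "indices_dir")])
    },
    `fit-lai` = {
      require_artifact(p$stack_dir, "simulate")
      require_artifact(p$chm, "indices")
      require_artifact(p$plots_csv, "simulate")
      stack <- read_band_stack(p$stack_dir)
      chm <- read_ascii_grid(p$chm)
      plots <- read_plot_records(p$plots_csv)
      tab <- predictor_table(stack, chm, plots)
      readr::write_csv(tab, p$predictor_csv)
      model <- fit_lai_model(tab)
      write_lai_model(model, p$model_json)
      readr::write_csv(model$importance_pct, p$importance_csv)
      write_manifest(config, "fit-lai",
                     inputs = p[c("stack_dir", "chm", "plots_csv")],
                     outputs = p[c("predictor_csv", "model_json",
                                   "importance_csv")],
                     extra = list(fit = unclass(glance(model))))
      invisible(p[c("predictor_csv", "model_json", "importance_csv")])
    },
    `predict-lai` = {
      require_artifact(p$stack_dir, "simulate")
      require_artifact(p$chm, "indices")
      require_artifact(p$model_json, "fit-lai")
      stack <- read_band_stack(p$stack_dir)
      chm <- read_ascii_grid(p$chm)
      model <- read_lai_model(p$model_json)
      lai_map <- predict_lai_map(model, stack, chm)
      write_ascii_grid(lai_map, p$lai_map)
      write_manifest(config, "predict-lai",
                     inputs = p[c("stack_dir", "chm", "model_json")],
                     outputs = p["lai_map"])
      invisible(p["lai_map"])
    },
    carbon = {
      require_artifact(p$lai_map, "predict-lai")
      require_artifact(p$stack_dir, "simulate")
      require_artifact(p$flux_csv, "simulate")
      stack <- read_band_stack(p$stack_dir)
      lai_map <- read_ascii_grid(p$lai_map)
      flux <- read_leaf_flux(p$flux_csv)
      constants <- config_constants(config)
      fs <- flux_summary(flux, molar_mass_c = constants$molar_mass_c)
      mask <- do.call(mangrove_mask, c(list(stack), config$mask))
      carbon <- annual_pixel_carbon(fs$mean_a, lai_map, constants)
      write_ascii_grid(carbon, p$carbon_map)
      summary <- area_carbon_summary(carbon, mask, constants)
      out <- list(
        flux = as.list(fs),
        carbon = as.list(summary),
        n_negative_lai = sum(lai_map$values < 0, na.rm = TRUE),
        n_nodata = sum(is.na(lai_map$values))
      )
      jsonlite::write_json(out, p$carbon_summary, auto_unbox = FALSE,
                           digits = NA)
      write_manifest(config, "carbon",
                     inputs = p[c("lai_map", "stack_dir", "flux_csv")],
                     outputs = p[c("carbon_map", "carbon_summary")],
                     extra = list(mangrove_pixels = summary$mangrove_pixels))
      invisible(p[c("carbon_map", "carbon_summary")])
    }
  )
}
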