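#' Synthetic scene configuration
#'
#' Bundles everything [generate_dataset()] needs: which experiments to
#' simulate, the flight schedule, the cultivar catalog, image geometry and
#' noise, growth-model parameters, and the weather window.
#'
#' @param experiments subset of `c("E1","E2","E3")`.
#' @param flights data.frame as from [flight_schedule()].
#' @param cultivars data.frame as from [cultivar_catalog()].
#' @param image_size per-plot raster size in pixels (scalar or `c(H, W)`).
#' @param noise_sd per-pixel reflectance noise sd.
#' @param clumped spatially clumped vegetation placement (see
#'   [render_plot_image()]).
#' @param endmembers soil/vegetation endmember spectra.
#' @param veg_jitter_sd,soil_jitter_sd,senescence_onset,senescence_strength
#'   spectral-variability parameters passed to [render_plot_image()].
#' @param params growth-model parameters from [growth_params()].
#' @param weather_start,weather_end weather simulation window (must cover
#'   emergence through the last flight).
#' @return list of class `scene_config`.
#' @export
scene_config <- function(experiments = c("E1", "E2", "E3"),
                         flights = flight_schedule(),
                         cultivars = cultivar_catalog(),
                         image_size = 48, noise_sd = 0.01, clumped = TRUE,
                         endmembers = default_endmembers(),
                         veg_jitter_sd = 0.05, soil_jitter_sd = 0.05,
                         senescence_onset = 0.75, senescence_strength = 0.5,
                         params = growth_params(),
                         weather_start = "2023-06-01",
                         weather_end = "2023-08-31") {
  structure(as.list(environment()), class = "scene_config")
}

#' Generate the full synthetic study
#'
#' Builds the experiment designs, simulates weather and per-plot ground
#' truth (AGB and canopy cover) at every flight date, and (optionally)
#' renders one multiband raster per plot per flight. With the default
#' three-experiment, four-flight configuration this yields
#' 4 x (18 + 40 + 36) = 376 plot-date samples.
#'
#' @param config list from [scene_config()].
#' @param seed master integer seed; all child seeds derive from it, so the
#'   ground truth regenerates bit-identically.
#' @param dir optional output directory; when given, rasters (multi-page
#'   32-bit float TIFF), plot polygons (GeoJSON), weather and ground truth
#'   (CSV, ISO-8601 dates) are written there.
#' @param overwrite allow writing into an existing non-empty `dir`.
#' @param render if `FALSE`, skip raster rendering (designs, weather and
#'   ground-truth table only; much faster).
#' @return object of class `uav_scene`: list with `truth` (data.frame, one
#'   row per plot-date, including design factors), `stacks` (named list of
#'   `band_stack`, or `NULL` when `render = FALSE`), `weather`, `polygons`,
#'   `config`, `seed`.
#' @export
generate_dataset <- function(config = scene_config(), seed = 1L, dir = NULL,
                             overwrite = FALSE, render = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  exps <- config$experiments
  if (!all(exps %in% c("E1", "E2", "E3"))) {
    stop("unknown experiment id in config: ",
         paste(setdiff(exps, c("E1", "E2", "E3")), collapse = ", "))
  }
  weather <- simulate_weather(config$weather_start, config$weather_end,
                              seed = derive_seed(seed, 1))
  designs <- do.call(rbind, lapply(seq_along(exps), function(i) {
    build_design(exps[i], seed = derive_seed(seed, 10 + i))
  }))
  flights <- config$flights[config$flights$experiment_id %in% exps, ]
  cat <- config$cultivars

  grid <- merge(designs, flights, by = "experiment_id")
  grid <- grid[order(grid$plot_id, grid$flight_date), ]
  rownames(grid) <- NULL

  size <- config$image_size
  if (length(size) == 1) size <- c(size, size)

  truth_rows <- vector("list", nrow(grid))
  stacks <- if (render) vector("list", nrow(grid)) else NULL
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    cv <- cat[cat$cultivar_id == row$cultivar_id, , drop = FALSE]
    if (nrow(cv) != 1) stop("cultivar ", row$cultivar_id, " not in catalog")
    gt <- simulate_agb(row, cv, row$flight_date, params = config$params,
                       seed = derive_seed(seed, 100 + i), stage = row$stage)
    truth_rows[[i]] <- cbind(
      gt[, c("plot_id", "flight_date", "stage", "gpr", "true_agb", "true_cc")],
      row[, c("experiment_id", "cultivar_id", "density", "n_rate", "k_rate",
              "replicate", "block")]
    )
    if (render) {
      stk <- render_plot_image(gt, size = size,
                               endmembers = config$endmembers,
                               noise_sd = config$noise_sd,
                               clumped = config$clumped,
                               gpr = gt$gpr,
                               senescence_onset = config$senescence_onset,
                               senescence_strength = config$senescence_strength,
                               veg_jitter_sd = config$veg_jitter_sd,
                               soil_jitter_sd = config$soil_jitter_sd,
                               seed = derive_seed(seed, 100000 + i))
      stacks[[i]] <- stk
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  if (render) names(stacks) <- paste(truth$plot_id, truth$flight_date, sep = "_")

  # one rectangular polygon per plot, in pixel coordinates of its raster
  plots <- unique(truth$plot_id)
  polygons <- stats::setNames(
    lapply(plots, function(p) full_extent_polygon(size)), plots)

  scene <- structure(list(truth = truth, stacks = stacks, weather = weather,
                          polygons = polygons, config = config, seed = seed),
                     class = "uav_scene")
  if (!is.null(dir)) write_scene(scene, dir, overwrite = overwrite)
  scene
}

#' @export
print.uav_scene <- function(x, ...) {
  cat("<uav_scene>", nrow(x$truth), "plot-date samples,",
      length(unique(x$truth$plot_id)), "plots,",
      length(unique(x$truth$flight_date)), "flight dates",
      if (is.null(x$stacks)) "(truth only)" else "(rendered)", "\n")
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' Layout: `rasters/<plot>_<date>_ms.tif` (six float32 pages, band1..band6),
#' `rasters/<plot>_<date>_rgb.tif`, `plots.geojson`, `weather.csv`,
#' `ground_truth.csv`.
#'
#' @param scene `uav_scene` object.
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stop("output directory ", dir, " exists and is not empty; ",
         "use overwrite = TRUE")
  }
  dir.create(file.path(dir, "rasters"), recursive = TRUE, showWarnings = FALSE)
  truth <- scene$truth
  truth$flight_date <- format(as_date(truth$flight_date))
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  wx <- scene$weather
  wx$date <- format(as_date(wx$date))
  utils::write.csv(wx, file.path(dir, "weather.csv"), row.names = FALSE)

  feats <- lapply(names(scene$polygons), function(p) {
    ring <- scene$polygons[[p]]
    coords <- lapply(c(seq_len(nrow(ring)), 1), function(i) unname(ring[i, ]))
    list(type = "Feature", properties = list(plot_id = p),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file.path(dir, "plots.geojson"),
                       auto_unbox = TRUE, digits = NA)

  if (!is.null(scene$stacks)) {
    for (nm in names(scene$stacks)) {
      stk <- scene$stacks[[nm]]
      pages <- lapply(seq_len(6), function(b) stk$ms[, , b])
      tiff::writeTIFF(pages, file.path(dir, "rasters", paste0(nm, "_ms.tif")),
                      bits.per.sample = 32L)
      tiff::writeTIFF(stk$rgb, file.path(dir, "rasters", paste0(nm, "_rgb.tif")),
                      bits.per.sample = 32L)
    }
  }
  invisible(dir)
}

#' Read a synthetic scene back from disk
#'
#' @param dir directory written by [write_scene()].
#' @return `uav_scene` object (config and seed are not recoverable from
#'   disk and are `NULL`).
#' @export
read_scene <- function(dir) {
  truth <- utils::read.csv(file.path(dir, "ground_truth.csv"),
                           stringsAsFactors = FALSE)
  truth$flight_date <- as.Date(truth$flight_date)
  weather <- utils::read.csv(file.path(dir, "weather.csv"),
                             stringsAsFactors = FALSE)
  weather$date <- as.Date(weather$date)
  gj <- jsonlite::read_json(file.path(dir, "plots.geojson"))
  polygons <- stats::setNames(
    lapply(gj$features, function(f) {
      ring <- f$geometry$coordinates[[1]]
      m <- do.call(rbind, lapply(ring, unlist))
      colnames(m) <- c("x", "y")
      m[-nrow(m), , drop = FALSE]
    }),
    vapply(gj$features, function(f) f$properties$plot_id, character(1)))

  stacks <- NULL
  rdir <- file.path(dir, "rasters")
  if (dir.exists(rdir) && length(list.files(rdir)) > 0) {
    keys <- paste(truth$plot_id, format(truth$flight_date), sep = "_")
    stacks <- stats::setNames(lapply(seq_along(keys), function(i) {
      pages <- tiff::readTIFF(file.path(rdir, paste0(keys[i], "_ms.tif")),
                              all = TRUE)
      h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
      ms <- array(0, dim = c(h, w, 6),
                  dimnames = list(NULL, NULL, names(band_roles())))
      for (b in seq_len(6)) ms[, , b] <- pages[[b]]
      rgb <- tiff::readTIFF(file.path(rdir, paste0(keys[i], "_rgb.tif")))
      structure(list(ms = ms, rgb = rgb, band_roles = band_roles(),
                     mask = NULL, plot_id = truth$plot_id[i],
                     flight_date = truth$flight_date[i]),
                class = "band_stack")
    }), keys)
  }
  structure(list(truth = truth, stacks = stacks, weather = weather,
                 polygons = polygons, config = NULL, seed = NULL),
            class = "uav_scene")
}
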