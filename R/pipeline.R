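#' Pipeline run configuration
#'
#' A fully serializable description of an end-to-end run: a run is
#' reproducible from the config plus its seed alone.
#'
#' @param outdir output directory for all stage artifacts.
#' @param seed master integer seed.
#' @param experiments experiments to simulate.
#' @param image_size per-plot raster size (pixels).
#' @param noise_sd per-pixel reflectance noise sd.
#' @param selection selection routes to run: `"boruta"`, `"pearson"` or
#'   `"both"`.
#' @param models model kinds to compare.
#' @param fraction train fraction of the holdout split.
#' @param vif_threshold VIF cut-off applied after Boruta.
#' @param boruta_iter,boruta_trees Boruta iteration cap and forest size.
#' @param with_texture extract GLCM texture features.
#' @param overwrite allow overwriting an existing scene directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir = "agbfusion_run", seed = 1L,
                       experiments = c("E1", "E2", "E3"),
                       image_size = 48, noise_sd = 0.01,
                       selection = c("both", "boruta", "pearson"),
                       models = c("RF", "PLSR", "MLR", "SLR", "Ridge", "Lasso"),
                       fraction = 2/3, vif_threshold = 10,
                       boruta_iter = 100, boruta_trees = 200,
                       with_texture = TRUE, overwrite = FALSE) {
  selection <- match.arg(selection)
  structure(as.list(environment()), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [run_config()] list (for `read_run_config`).
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- do.call(run_config, vals[intersect(names(vals),
                                            names(formals(run_config)))])
  cfg
}

#' @rdname read_run_config
#' @param config `run_config` object to serialize.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stamp a CSV with the config hash on a comment line, then the table.
write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# agbfusion config ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

pipeline_log <- function(...) message("[agbfusion] ", ...)

#' Pipeline stage: simulate the synthetic scene
#'
#' Generates and writes the synthetic study to `<outdir>/scene`, logging
#' per-experiment plot counts.
#'
#' @param config [run_config()].
#' @return the `uav_scene`, invisibly.
#' @export
pipeline_simulate <- function(config) {
  sc <- scene_config(experiments = config$experiments,
                     image_size = config$image_size,
                     noise_sd = config$noise_sd)
  scene <- generate_dataset(sc, seed = config$seed,
                            dir = file.path(config$outdir, "scene"),
                            overwrite = config$overwrite)
  counts <- table(unique(scene$truth[, c("experiment_id", "plot_id")])$experiment_id)
  pipeline_log("simulated plots: ",
               paste(names(counts), counts, sep = "=", collapse = ", "),
               "; ", nrow(scene$truth), " plot-date samples")
  invisible(scene)
}

#' Pipeline stage: extract the feature table
#'
#' @param config [run_config()].
#' @param scene optional in-memory scene; read from `<outdir>/scene`
#'   otherwise.
#' @return the feature table, invisibly.
#' @export
pipeline_extract <- function(config, scene = NULL) {
  scene <- scene %||% read_scene(file.path(config$outdir, "scene"))
  feats <- build_feature_table(scene, with_texture = config$with_texture)
  write_stamped_csv(feats, file.path(config$outdir, "features.csv"),
                    config_hash(unclass(config)))
  pipeline_log("feature table: ", nrow(feats), " rows x ", ncol(feats),
               " columns")
  invisible(feats)
}

#' Pipeline stage: feature selection
#'
#' Runs the configured routes: Boruta (followed by VIF screening of the
#' confirmed set) and/or Pearson top-k. Reports are written as JSON and the
#' score tables as stamped CSV.
#'
#' @param config [run_config()].
#' @param features feature table; read from `<outdir>/features.csv`
#'   otherwise.
#' @return named list of `selection_result`, invisibly.
#' @export
pipeline_select <- function(config, features = NULL) {
  features <- features %||% read_stamped_csv(file.path(config$outdir,
                                                       "features.csv"))
  routes <- if (config$selection == "both") c("boruta", "pearson")
            else config$selection
  hash <- config_hash(unclass(config))
  out <- list()
  for (route in routes) {
    sel <- if (route == "boruta") {
      s <- boruta_select(features, max_iter = config$boruta_iter,
                         num_trees = config$boruta_trees,
                         seed = derive_seed(config$seed, 77))
      if (length(s$confirmed) >= 2) {
        vif <- vif_screen(features, s$confirmed,
                          threshold = config$vif_threshold)
        s$vif <- vif
        s$rejected <- c(s$rejected, vif$feature[!vif$retained])
        s$confirmed <- vif$feature[vif$retained]
      }
      s
    } else {
      pearson_rank(features)
    }
    out[[route]] <- sel
    rep <- list(method = sel$method, confirmed = sel$confirmed,
                rejected = sel$rejected, tentative = sel$tentative,
                seed = config$seed, config_hash = unname(hash))
    jsonlite::write_json(rep, file.path(config$outdir,
                                        paste0("selection_", route, ".json")),
                         auto_unbox = TRUE, digits = NA)
    write_stamped_csv(
      data.frame(feature = names(sel$scores), score = unname(sel$scores)),
      file.path(config$outdir, paste0("selection_", route, "_scores.csv")),
      hash)
    pipeline_log("selection (", route, "): ", length(sel$confirmed),
                 " confirmed of ", length(sel$scores))
  }
  invisible(out)
}

#' Pipeline stage: model comparison
#'
#' Runs [run_comparison()] per selection route and writes the results table,
#' a JSON summary, and a plain-text report of the best fusion per model.
#'
#' @param config [run_config()].
#' @param features feature table (read from disk when `NULL`).
#' @param selections named list from [pipeline_select()] (recomputed when
#'   `NULL`).
#' @return the `eval_report`, invisibly.
#' @export
pipeline_model <- function(config, features = NULL, selections = NULL) {
  features <- features %||% read_stamped_csv(file.path(config$outdir,
                                                       "features.csv"))
  selections <- selections %||% pipeline_select(config, features)
  rep <- run_comparison(features, selections = selections,
                        models = config$models,
                        fraction = config$fraction, seed = config$seed)
  hash <- config_hash(unclass(config))
  write_stamped_csv(rep$results, file.path(config$outdir, "results.csv"), hash)
  jsonlite::write_json(
    list(best = rep$best, config_hash = unname(hash), seed = config$seed),
    file.path(config$outdir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  pipeline_report(config, rep)
  pipeline_log("model grid: ", nrow(rep$results), " evaluations, ",
               if (is.null(rep$errors)) 0 else nrow(rep$errors), " failures")
  invisible(rep)
}

#' Pipeline stage: plain-text report
#'
#' Writes `report.txt`: per selection route and model, the best feature
#' fusion with train/test metrics.
#'
#' @param config [run_config()].
#' @param report `eval_report` (read back from results.csv when `NULL`).
#' @return path to the report, invisibly.
#' @export
pipeline_report <- function(config, report = NULL) {
  if (is.null(report)) {
    res <- read_stamped_csv(file.path(config$outdir, "results.csv"))
    parts <- split(res, list(res$route, res$model), drop = TRUE)
    best <- do.call(rbind, lapply(parts, function(d) {
      d[order(-d$r2_test, d$rrmse_test, d$combo), ][1, ]
    }))
    report <- list(best = best)
  }
  path <- file.path(config$outdir, "report.txt")
  hash <- config_hash(unclass(config))
  lines <- c(paste0("# agbfusion config ", hash),
             "Optimal feature fusion per model (ranked by test R2)",
             "")
  b <- report$best
  for (i in seq_len(nrow(b))) {
    lines <- c(lines, sprintf(
      "%-8s %-6s %-28s train R2=%.2f rRMSE=%.2f MAE=%.2f | test R2=%.2f rRMSE=%.2f MAE=%.2f",
      b$route[i], b$model[i], b$combo[i],
      b$r2_train[i], b$rrmse_train[i], b$mae_train[i],
      b$r2_test[i], b$rrmse_test[i], b$mae_test[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the requested stages in order: simulate, extract, select,
#' model, report. Each stage reads its inputs from `config$outdir` when an
#' earlier stage was not run in the same call.
#'
#' @param config [run_config()].
#' @param stages subset of `c("simulate","extract","select","model","report")`.
#' @return list with whatever stages produced, invisibly.
#' @export
pipeline_run <- function(config,
                         stages = c("simulate", "extract", "select",
                                    "model", "report")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(config$outdir, "config.yaml"))
  out <- list()
  if ("simulate" %in% stages) out$scene <- pipeline_simulate(config)
  if ("extract" %in% stages) out$features <- pipeline_extract(config, out$scene)
  if ("select" %in% stages) out$selections <- pipeline_select(config, out$features)
  if ("model" %in% stages) {
    out$report <- pipeline_model(config, out$features, out$selections)
  } else if ("report" %in% stages) {
    pipeline_report(config)
  }
  invisible(out)
}
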