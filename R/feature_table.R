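#' Build the plot-date feature table from a rendered scene
#'
#' One row per plot-date sample with namespaced feature columns:
#' `band.<role>` mean reflectances, `vi.<NAME>` vegetation indices,
#' `tex.band<k>.<STAT>` texture statistics, `cc` canopy cover, `gdd` growing
#' degree days from emergence to the flight date, `gpr` growth process
#' ratio, and the target `agb` (true AGB, ton/ha). Design factors and stage
#' labels are carried through as identifier columns.
#'
#' @param scene rendered `uav_scene` from [generate_dataset()].
#' @param cultivars cultivar catalog (for emergence dates and base
#'   temperatures); defaults to the scene config's catalog.
#' @param with_texture compute GLCM texture features (the slowest block;
#'   can be disabled when only spectral/agromet groups are needed).
#' @param with_cc compute canopy cover by bimodal segmentation.
#' @param levels,distance GLCM quantization levels and displacement.
#' @return data.frame, one row per plot-date.
#' @export
build_feature_table <- function(scene, cultivars = NULL, with_texture = TRUE,
                                with_cc = TRUE, levels = 32, distance = 1) {
  if (is.null(scene$stacks)) {
    stop("scene has no rendered rasters; run generate_dataset(render = TRUE)")
  }
  cultivars <- cultivars %||% (if (!is.null(scene$config)) scene$config$cultivars
                               else cultivar_catalog())
  truth <- scene$truth
  keys <- paste(truth$plot_id, format(as_date(truth$flight_date)), sep = "_")
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    stk <- scene$stacks[[keys[i]]]
    poly <- scene$polygons[[truth$plot_id[i]]]
    bm <- extract_band_means(stk, poly)
    vis <- compute_vis(bm)
    cv <- cultivars[cultivars$cultivar_id == truth$cultivar_id[i], ]
    gdd <- accumulate_gdd(scene$weather, t_b = cv$base_temp,
                          start_date = cv$emergence_date,
                          end_date = truth$flight_date[i])
    t1 <- as.numeric(as_date(truth$flight_date[i]) - as_date(cv$emergence_date))
    g <- suppressWarnings(gpr(t1, cv$total_period_days))
    row <- data.frame(plot_id = truth$plot_id[i],
                      flight_date = as_date(truth$flight_date[i]),
                      experiment_id = truth$experiment_id[i],
                      cultivar_id = truth$cultivar_id[i],
                      stage = truth$stage[i],
                      density = truth$density[i], n_rate = truth$n_rate[i],
                      k_rate = truth$k_rate[i],
                      stringsAsFactors = FALSE)
    roles <- stk$band_roles
    row[paste0("band.", roles)] <- bm[roles]
    row[paste0("vi.", names(vis))] <- as.list(as.numeric(vis))
    if (with_texture) {
      tex <- texture_features(stk, poly, levels = levels, distance = distance)
      row[names(tex)] <- as.list(tex)
    }
    if (with_cc) {
      row$cc <- suppressWarnings(canopy_cover(stk, poly)$cc)
    }
    row$gdd <- gdd
    row$gpr <- g
    row$agb <- truth$true_agb[i]
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map feature-table columns to fusion groups
#'
#' @param names character vector of column names.
#' @return character vector: `"VIs"`, `"Texture"`, `"CC"`, `"GDD"`, `"GPR"`
#'   for feature columns, `NA` for identifier/target columns.
#' @export
feature_groups <- function(names) {
  out <- rep(NA_character_, length(names))
  out[startsWith(names, "vi.")] <- "VIs"
  out[startsWith(names, "tex.")] <- "Texture"
  out[names == "cc"] <- "CC"
  out[names == "gdd"] <- "GDD"
  out[names == "gpr"] <- "GPR"
  out
}
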