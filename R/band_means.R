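#' Extract mean reflectance per band over a plot polygon
#'
#' Arithmetic mean of each multispectral band over the pixels whose centers
#' fall inside the polygon (center-point test).
#'
#' @param stack `band_stack` object.
#' @param polygon two-column vertex matrix in pixel coordinates
#'   (x = column, y = row, origin at the top-left corner); default covers
#'   the full raster extent.
#' @return one-row data.frame: `plot_id`, `flight_date`, and one mean per
#'   band role (`blue`, `green`, `pan`, `red`, `red_edge`, `nir`).
#' @export
extract_band_means <- function(stack, polygon = NULL) {
  dims <- dim(stack$ms)[1:2]
  polygon <- polygon %||% full_extent_polygon(dims)
  mask <- pixel_mask_from_polygon(dims, polygon)
  if (!any(mask)) {
    stop("polygon does not intersect raster for plot ", stack$plot_id)
  }
  roles <- stack$band_roles
  means <- vapply(seq_len(6), function(b) mean(stack$ms[, , b][mask]),
                  numeric(1))
  out <- data.frame(plot_id = stack$plot_id,
                    flight_date = as_date(stack$flight_date),
                    stringsAsFactors = FALSE)
  out[roles] <- as.list(means)
  out
}
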