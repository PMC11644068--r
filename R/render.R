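#' Band slot/role mapping of the six-band multispectral stack
#'
#' Slots band1--band6 map to blue, green, panchromatic, red, red edge, NIR.
#'
#' @param roles optional character override, length 6, a permutation of
#'   `c("blue","green","pan","red","red_edge","nir")` in slot order.
#' @return named character vector, names `band1`..`band6`.
#' @export
band_roles <- function(roles = NULL) {
  r <- roles %||% c("blue", "green", "pan", "red", "red_edge", "nir")
  stopifnot(length(r) == 6,
            setequal(r, c("blue", "green", "pan", "red", "red_edge", "nir")))
  stats::setNames(r, paste0("band", 1:6))
}

#' Default soil and vegetation endmember spectra
#'
#' Per-band reflectance of the two pure materials mixed pixel-wise in the
#' synthetic imagery: soil roughly flat at 0.22--0.30 across all bands,
#' vegetation with the classic red absorption (~0.05) and high NIR (~0.50).
#'
#' @return list with numeric vectors `soil` and `veg`, named by band role.
#' @export
default_endmembers <- function() {
  roles <- c("blue", "green", "pan", "red", "red_edge", "nir")
  list(
    soil = stats::setNames(c(0.22, 0.24, 0.26, 0.28, 0.29, 0.30), roles),
    veg  = stats::setNames(c(0.06, 0.12, 0.10, 0.05, 0.30, 0.50), roles)
  )
}

#' Render a synthetic per-plot image from ground truth
#'
#' Places a spatially clumped vegetation mask covering a fraction
#' `true_cc` of the pixels (threshold of a Gaussian-smoothed random field at
#' the matching quantile, so the realized fraction is exact to within one
#' pixel), fills vegetation/soil pixels from the endmember spectra, adds
#' per-pixel Gaussian sensor noise clipped to \[0, 1\], and renders an RGB
#' image from the blue/green/red slots.
#'
#' @param truth one-row data.frame from [simulate_agb()] (uses `true_cc`,
#'   `plot_id`, `flight_date`).
#' @param size image size, `c(H, W)` or a scalar; minimum 16 x 16.
#' @param endmembers list as from [default_endmembers()].
#' @param noise_sd per-pixel Gaussian reflectance noise sd.
#' @param clumped if `TRUE` (default) vegetation forms smooth blobs so
#'   texture features carry signal; if `FALSE`, i.i.d. pixel placement
#'   (degenerate option for oracle tests).
#' @param clump_sigma Gaussian smoothing sigma (pixels) of the latent field.
#' @param gpr optional growth process ratio of the plot-date; when supplied
#'   and past `senescence_onset`, the vegetation endmember is shifted toward
#'   the soil spectrum (chlorophyll breakdown late in the cycle), decoupling
#'   late-season greenness from fresh biomass.
#' @param senescence_onset,senescence_strength GPR at which senescence
#'   starts, and the maximum fraction of the vegetation-to-soil spectral
#'   shift reached at GPR = 1.
#' @param veg_jitter_sd,soil_jitter_sd sd of the per-plot-date lognormal
#'   brightness jitter applied to each endmember (canopy chlorophyll and
#'   soil moisture variability between plots and dates).
#' @param seed integer seed.
#' @return object of class `band_stack`: list with `ms` (H x W x 6
#'   reflectance array), `rgb` (H x W x 3), `band_roles`, `mask` (the true
#'   vegetation mask), `plot_id`, `flight_date`.
#' @export
render_plot_image <- function(truth, size = c(48, 48),
                              endmembers = default_endmembers(),
                              noise_sd = 0.01, clumped = TRUE,
                              clump_sigma = 4, gpr = NA_real_,
                              senescence_onset = 0.75,
                              senescence_strength = 0.5,
                              veg_jitter_sd = 0.05, soil_jitter_sd = 0.05,
                              seed = 1L) {
  if (length(size) == 1) size <- c(size, size)
  if (any(size < 16)) stop("image size must be at least 16 x 16")
  em_soil <- endmembers$soil
  em_veg <- endmembers$veg
  if (any(c(em_soil, em_veg) < 0) || any(c(em_soil, em_veg) > 1)) {
    stop("endmember spectra must lie in [0, 1]")
  }
  if (!(em_veg["nir"] > em_soil["nir"]) || !(em_veg["red"] < em_soil["red"])) {
    stop("endmembers must satisfy vegetation NIR > soil NIR and vegetation red < soil red")
  }
  if (!is.na(gpr) && gpr > senescence_onset) {
    sen <- senescence_strength *
      min((gpr - senescence_onset) / (1 - senescence_onset), 1)
    em_veg <- em_veg + sen * (em_soil - em_veg)
  }
  h <- size[1]; w <- size[2]
  cc <- truth$true_cc
  withr::with_seed(seed, {
    em_veg <- pmin(em_veg * stats::rlnorm(1, 0, veg_jitter_sd), 1)
    em_soil <- pmin(em_soil * stats::rlnorm(1, 0, soil_jitter_sd), 1)
    mask <- if (cc <= 0) {
      matrix(FALSE, h, w)
    } else if (cc >= 1) {
      matrix(TRUE, h, w)
    } else if (clumped) {
      field <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w),
                              sigma = clump_sigma)
      field >= stats::quantile(field, 1 - cc)
    } else {
      matrix(stats::runif(h * w) < cc, h, w)
    }
    ms <- array(0, dim = c(h, w, 6),
                dimnames = list(NULL, NULL, names(band_roles())))
    roles <- band_roles()
    for (b in seq_len(6)) {
      base <- ifelse(mask, em_veg[roles[b]], em_soil[roles[b]])
      ms[, , b] <- pmin(pmax(base + stats::rnorm(h * w, 0, noise_sd), 0), 1)
    }
    rgb <- array(0, dim = c(h, w, 3), dimnames = list(NULL, NULL, c("r", "g", "b")))
    rgb[, , 1] <- ms[, , which(roles == "red")]
    rgb[, , 2] <- ms[, , which(roles == "green")]
    rgb[, , 3] <- ms[, , which(roles == "blue")]
    structure(list(ms = ms, rgb = rgb, band_roles = roles, mask = mask,
                   plot_id = truth$plot_id,
                   flight_date = as_date(truth$flight_date)),
              class = "band_stack")
  })
}

#' @export
print.band_stack <- function(x, ...) {
  cat("<band_stack>", x$plot_id, format(x$flight_date),
      paste0(dim(x$ms)[1], "x", dim(x$ms)[2]), "px, 6 MS bands + RGB\n")
  invisible(x)
}
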