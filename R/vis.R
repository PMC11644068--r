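#' Names of the vegetation-index bank
#'
#' The 14 indices computed from the blue/green/red/red-edge/NIR band means.
#'
#' @param include_grndvi also list the optional green-red NDVI variant.
#' @return character vector of index names.
#' @export
vi_bank <- function(include_grndvi = FALSE) {
  base <- c("GRVI", "MCARI", "MCARI2", "NDRE", "NDVI", "RDVI", "SR",
            "TCARI", "WDRVI", "NDI", "MSR", "GCI", "RECI", "TDVI")
  if (include_grndvi) c(base, "GRNDVI") else base
}

#' Compute the vegetation-index bank from band means
#'
#' Evaluates the 14-index bank. Index formulas (reflectances: `G` green,
#' `R` red, `RE` red edge, `NIR` near-infrared):
#' \itemize{
#' \item GRVI = NIR/G; SR = NIR/R; GCI = NIR/G - 1; RECI = NIR/RE - 1
#' \item NDVI = (NIR-R)/(NIR+R); NDRE = (NIR-RE)/(NIR+RE)
#' \item RDVI = (NIR-R)/sqrt(NIR+R); TDVI = (0.5 + NDVI)^2
#' \item WDRVI = (0.1 NIR - R)/(0.1 NIR + R)
#' \item MSR = (NIR/R - 1)/(sqrt(NIR/R) + 1)
#' \item MCARI = ((RE-R) - 0.2 (RE-G)) (RE/R)
#' \item TCARI = 3 ((RE-R) - 0.2 (RE-G) (RE/R))
#' \item NDI = (NIR-RE)/(NIR+R) (`variant = "printed"` uses (NIR-RE)/(NIR+RE+R)
#'   read literally from a garbled source expression; the default reads the
#'   denominator as NIR+R)
#' \item MCARI2 = 1.5 (2.5 (NIR-R) - 1.3 (NIR-G)) /
#'   sqrt((2 NIR + 1)^2 - (6 NIR - 5 sqrt(R)) - 0.5) (canonical form;
#'   `variant = "printed"` evaluates 1.52 (NIR-R) - 1.3 (NIR-G)/sqrt(...))
#' \item GRNDVI = (NIR - (G+R))/(NIR + (G+R)) (optional 15th index)
#' }
#' Indices whose denominator is zero (or whose square-root argument is
#' negative) are returned as `NA` and listed in the `"flagged"` attribute.
#'
#' @param means one-row data.frame from [extract_band_means()], or any list
#'   with elements `green`, `red`, `red_edge`, `nir` (and `blue` unused).
#' @param include_grndvi add GRNDVI as a 15th index.
#' @param mcari2_variant,ndi_variant `"canonical"` (default) or `"printed"`.
#' @return named numeric vector of indices, with attribute `flagged` naming
#'   any indices returned as missing.
#' @export
compute_vis <- function(means, include_grndvi = FALSE,
                        mcari2_variant = c("canonical", "printed"),
                        ndi_variant = c("canonical", "printed")) {
  mcari2_variant <- match.arg(mcari2_variant)
  ndi_variant <- match.arg(ndi_variant)
  G <- means$green; R <- means$red; RE <- means$red_edge; NIR <- means$nir
  if (any(vapply(list(G, R, RE, NIR), is.null, logical(1)))) {
    stop("band means must include green, red, red_edge and nir")
  }
  safe_div <- function(num, den) if (abs(den) < .Machine$double.eps) NA_real_ else num / den
  safe_sqrt <- function(x) if (x < 0) NA_real_ else sqrt(x)

  ndvi <- safe_div(NIR - R, NIR + R)
  sr <- safe_div(NIR, R)
  m2_den <- safe_sqrt((2 * NIR + 1)^2 - (6 * NIR - 5 * safe_sqrt(R)) - 0.5)
  mcari2 <- if (is.na(m2_den) || m2_den == 0) NA_real_ else {
    if (mcari2_variant == "canonical") {
      1.5 * (2.5 * (NIR - R) - 1.3 * (NIR - G)) / m2_den
    } else {
      1.52 * (NIR - R) - 1.3 * (NIR - G) / m2_den
    }
  }
  rdvi_den <- safe_sqrt(NIR + R)
  out <- c(
    GRVI = safe_div(NIR, G),
    MCARI = if (R == 0) NA_real_ else ((RE - R) - 0.2 * (RE - G)) * (RE / R),
    MCARI2 = mcari2,
    NDRE = safe_div(NIR - RE, NIR + RE),
    NDVI = ndvi,
    RDVI = if (is.na(rdvi_den) || rdvi_den == 0) NA_real_ else (NIR - R) / rdvi_den,
    SR = sr,
    TCARI = if (R == 0) NA_real_ else 3 * ((RE - R) - 0.2 * (RE - G) * (RE / R)),
    WDRVI = safe_div(0.1 * NIR - R, 0.1 * NIR + R),
    NDI = if (ndi_variant == "canonical") safe_div(NIR - RE, NIR + R)
          else safe_div(NIR - RE, NIR + RE + R),
    MSR = if (is.na(sr) || sr < 0) NA_real_ else (sr - 1) / (sqrt(sr) + 1),
    GCI = if (G == 0) NA_real_ else NIR / G - 1,
    RECI = if (RE == 0) NA_real_ else NIR / RE - 1,
    TDVI = if (is.na(ndvi)) NA_real_ else (0.5 + ndvi)^2
  )
  if (include_grndvi) {
    out <- c(out, GRNDVI = safe_div(NIR - (G + R), NIR + (G + R)))
  }
  flagged <- names(out)[is.na(out)]
  attr(out, "flagged") <- flagged
  out
}
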