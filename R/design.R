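#' Cultivar catalog
#'
#' Default catalog of the five potato cultivars: total growth period
#' (days from emergence to maturity), emergence date, base temperature for
#' development, and the growth-process-ratio anchor at the first
#' (tuber-formation) flight of the cultivar's experiment.
#'
#' Z5 and Z35 are early-maturing (75 d), Z27 mid-maturing (95 d), Z19 and
#' Z49 late-maturing (105/110 d) -- a 35-day maximum spread in growth period.
#' Emergence dates are back-computed from each cultivar's first-flight GPR
#' anchor so that `round(gpr_s1 * total_period_days)` days after emergence
#' lands on the first flight date of its experiment.
#'
#' @param emergence named character/Date overrides of emergence dates.
#' @param base_temp base temperature in degrees C (default 7, potato).
#' @return data.frame with columns `cultivar_id`, `experiment_id`,
#'   `total_period_days`, `emergence_date`, `base_temp`, `gpr_s1`.
#' @export
cultivar_catalog <- function(emergence = NULL, base_temp = 7) {
  cat <- data.frame(
    cultivar_id = c("Z27", "Z19", "Z5", "Z49", "Z35"),
    experiment_id = c("E1", "E1", "E2", "E2", "E3"),
    total_period_days = c(95L, 105L, 75L, 110L, 75L),
    emergence_date = as.Date(c("2023-06-15", "2023-06-16", "2023-06-15",
                               "2023-06-14", "2023-06-15")),
    base_temp = base_temp,
    gpr_s1 = c(0.20, 0.17, 0.27, 0.19, 0.28),
    stringsAsFactors = FALSE
  )
  if (!is.null(emergence)) {
    idx <- match(names(emergence), cat$cultivar_id)
    if (anyNA(idx)) stop("unknown cultivar in emergence overrides: ",
                         paste(names(emergence)[is.na(idx)], collapse = ", "))
    cat$emergence_date[idx] <- as_date(unlist(emergence, use.names = FALSE))
  }
  cat
}

#' Flight schedule
#'
#' Default UAV flight dates, four per experiment, one per growth stage:
#' S1 tuber formation, S2 tuber expansion, S3 starch accumulation,
#' S4 mature harvest.
#'
#' @return data.frame with columns `experiment_id`, `stage`, `flight_date`.
#' @export
flight_schedule <- function() {
  data.frame(
    experiment_id = rep(c("E1", "E2", "E3"), each = 4),
    stage = rep(c("S1", "S2", "S3", "S4"), times = 3),
    flight_date = as.Date(c(
      "2023-07-04", "2023-07-17", "2023-08-03", "2023-08-13",  # E1
      "2023-07-05", "2023-07-18", "2023-08-03", "2023-08-14",  # E2
      "2023-07-06", "2023-07-20", "2023-08-05", "2023-08-18"   # E3
    )),
    stringsAsFactors = FALSE
  )
}

# Management levels held constant in experiments where a factor is not varied.
.default_density <- 60000
.default_n_rate <- 120
.default_k_rate <- 120

#' Build a factorial field-experiment design
#'
#' Lays out one of the three randomized-block experiments:
#' \describe{
#'   \item{E1}{cultivar (Z27, Z19) x planting density
#'     (52,500 / 60,000 / 75,000 plants/ha) x 3 blocks = 18 plots.}
#'   \item{E2}{cultivar (Z5, Z49) x nitrogen rate
#'     (0/50/100/250/400 kg/ha) x 4 blocks = 40 plots.}
#'   \item{E3}{cultivar Z35, nitrogen (0/120/240 kg/ha) x potassium
#'     (0/120/240/360 kg/ha) x 3 blocks = 36 plots.}
#' }
#' Treatments are randomized to positions within each block; the layout is
#' deterministic given `seed`.
#'
#' @param experiment_id one of `"E1"`, `"E2"`, `"E3"`.
#' @param seed integer seed for within-block randomization.
#' @param densities density levels for E1, plants/ha.
#' @return data.frame of plots with columns `experiment_id`, `plot_id`,
#'   `cultivar_id`, `density`, `n_rate`, `k_rate`, `replicate`, `block`.
#' @export
build_design <- function(experiment_id, seed = 1L,
                         densities = c(52500, 60000, 75000)) {
  if (!is.character(experiment_id) || length(experiment_id) != 1 ||
      !experiment_id %in% c("E1", "E2", "E3")) {
    stop("unknown experiment_id: ", paste(experiment_id, collapse = ", "),
         " (expected one of E1, E2, E3)")
  }
  trt <- switch(experiment_id,
    E1 = expand.grid(cultivar_id = c("Z27", "Z19"), density = densities,
                     n_rate = .default_n_rate, k_rate = .default_k_rate,
                     stringsAsFactors = FALSE),
    E2 = expand.grid(cultivar_id = c("Z5", "Z49"), density = .default_density,
                     n_rate = c(0, 50, 100, 250, 400), k_rate = .default_k_rate,
                     stringsAsFactors = FALSE),
    E3 = expand.grid(cultivar_id = "Z35", density = .default_density,
                     n_rate = c(0, 120, 240), k_rate = c(0, 120, 240, 360),
                     stringsAsFactors = FALSE)
  )
  n_blocks <- switch(experiment_id, E1 = 3L, E2 = 4L, E3 = 3L)
  n_trt <- nrow(trt)
  design <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      ord <- sample.int(n_trt)
      out <- trt[ord, , drop = FALSE]
      out$replicate <- b
      out$block <- b
      out
    }))
  })
  design$experiment_id <- experiment_id
  design$plot_id <- sprintf("%s-%02d", experiment_id, seq_len(nrow(design)))
  rownames(design) <- NULL
  design[, c("experiment_id", "plot_id", "cultivar_id", "density",
             "n_rate", "k_rate", "replicate", "block")]
}
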