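#' Scale per-plant biomass to per-hectare AGB
#'
#' `AGB = AGB_ave x n`, harmonized to ton/ha.
#'
#' @param agb_ave average biomass per plant.
#' @param n plants per hectare.
#' @param units units of `agb_ave`: `"kg"` per plant (default) or `"ton"`.
#' @return AGB in ton/ha.
#' @export
agb_per_ha <- function(agb_ave, n, units = c("kg", "ton")) {
  units <- match.arg(units)
  if (any(agb_ave < 0)) stop("agb_ave must be non-negative")
  if (any(n <= 0)) stop("n (plants/ha) must be positive")
  agb_ave * n / if (units == "kg") 1000 else 1
}

#' Accumulate growing degree days
#'
#' `GDD = sum over days of (T_max + T_min)/2 - T_b`, with daily increments
#' floored at zero by default (days colder than the base temperature do not
#' subtract heat).
#'
#' @param weather data.frame with columns `date`, `t_max`, `t_min`.
#' @param t_b base temperature, degrees C (default 7, potato).
#' @param start_date,end_date inclusive accumulation window.
#' @param allow_negative if `TRUE`, keep negative daily increments.
#' @return accumulated GDD in degree C days.
#' @export
accumulate_gdd <- function(weather, t_b = 7, start_date, end_date,
                           allow_negative = FALSE) {
  start_date <- as_date(start_date)
  end_date <- as_date(end_date)
  if (start_date > end_date) stop("reversed date range")
  wanted <- seq(start_date, end_date, by = "day")
  idx <- match(wanted, as_date(weather$date))
  if (anyNA(idx)) {
    stop("weather series has gaps: ",
         paste(format(wanted[is.na(idx)]), collapse = ", "))
  }
  inc <- (weather$t_max[idx] + weather$t_min[idx]) / 2 - t_b
  if (!allow_negative) inc <- pmax(inc, 0)
  sum(inc)
}

#' Growth process ratio
#'
#' `GPR = T1 / TO`: days after emergence divided by the cultivar's total
#' growth period. Values above 1 (observation past the nominal period) are
#' allowed with a warning, not clipped. Full precision is returned; use
#' `round(gpr(...), 2)` for reporting.
#'
#' @param t1 days after emergence (>= 0).
#' @param t_o total growth period in days (> 0).
#' @return the ratio, full precision.
#' @export
gpr <- function(t1, t_o) {
  if (any(t_o <= 0)) stop("total growth period t_o must be positive")
  if (any(t1 < 0)) stop("t1 (days after emergence) must be non-negative")
  out <- t1 / t_o
  if (any(out > 1)) warning("GPR exceeds 1 (observation past nominal growth period)")
  out
}

#' Reconstruct days-after-emergence from a first-flight GPR anchor
#'
#' Given the GPR observed at the first (tuber-formation) flight, back out
#' the whole-day count `T1 = round(gpr_s1 x TO)` at that flight, then add
#' the calendar gap to any later flight date.
#'
#' @param gpr_s1 GPR at the anchor (first) flight, in (0, 1).
#' @param t_o total growth period in days.
#' @param s1_date anchor flight date.
#' @param flight_date target flight date (>= `s1_date`).
#' @return days after emergence (integer-valued numeric) at `flight_date`.
#' @export
anchor_t1 <- function(gpr_s1, t_o, s1_date, flight_date) {
  stopifnot(gpr_s1 > 0, gpr_s1 < 1)
  s1_date <- as_date(s1_date)
  flight_date <- as_date(flight_date)
  if (any(flight_date < s1_date)) stop("flight_date precedes the anchor date")
  round(gpr_s1 * t_o) + as.numeric(flight_date - s1_date)
}

#' Reconstructed GPR schedule for all cultivars and stages
#'
#' Applies [anchor_t1()] at every flight of each cultivar's experiment and
#' reports GPR rounded to two decimals (the reporting convention), plus the
#' full-precision value.
#'
#' @param cultivars data.frame as from [cultivar_catalog()].
#' @param flights data.frame as from [flight_schedule()].
#' @return data.frame: `cultivar_id`, `stage`, `flight_date`, `t1`,
#'   `gpr`, `gpr_2dp`.
#' @export
gpr_schedule <- function(cultivars = cultivar_catalog(),
                         flights = flight_schedule()) {
  rows <- lapply(seq_len(nrow(cultivars)), function(i) {
    cv <- cultivars[i, ]
    fl <- flights[flights$experiment_id == cv$experiment_id, ]
    s1 <- fl$flight_date[fl$stage == "S1"]
    t1 <- anchor_t1(cv$gpr_s1, cv$total_period_days, s1, fl$flight_date)
    g <- t1 / cv$total_period_days
    data.frame(cultivar_id = cv$cultivar_id, stage = fl$stage,
               flight_date = fl$flight_date, t1 = t1, gpr = g,
               gpr_2dp = round(g, 2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
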