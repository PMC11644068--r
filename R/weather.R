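#' Simulate a daily weather series
#'
#' One record per day with daily maximum and minimum air temperature. The
#' daily mean follows a sinusoidal seasonal cycle (peaking around mid July,
#' day of year `peak_doy`) plus Gaussian noise; the diurnal range is drawn
#' from a truncated normal so that `t_max > t_min` always holds and the
#' range never exceeds 20 degrees C.
#'
#' @param start_date,end_date inclusive date range (Date or ISO-8601 string).
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @param mean_peak seasonal peak of the daily mean temperature, degrees C.
#' @param mean_amp peak-to-trough seasonal amplitude, degrees C.
#' @param peak_doy day of year at which the seasonal mean peaks.
#' @param diurnal_mean,diurnal_sd mean and sd of the diurnal range, degrees C.
#' @param noise_sd sd of day-to-day noise on the daily mean, degrees C.
#' @return data.frame with columns `date`, `t_max`, `t_min`.
#' @export
simulate_weather <- function(start_date, end_date, seed = 1L,
                             mean_peak = 21, mean_amp = 14, peak_doy = 199,
                             diurnal_mean = 11, diurnal_sd = 2.5,
                             noise_sd = 1.5) {
  start_date <- as_date(start_date)
  end_date <- as_date(end_date)
  if (start_date > end_date) stop("reversed date range: start_date > end_date")
  dates <- seq(start_date, end_date, by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  seasonal <- mean_peak - mean_amp / 2 +
    (mean_amp / 2) * cos(2 * pi * (doy - peak_doy) / 365)
  withr::with_seed(seed, {
    tmean <- seasonal + stats::rnorm(length(dates), 0, noise_sd)
    rng <- stats::rnorm(length(dates), diurnal_mean, diurnal_sd)
    rng <- pmin(pmax(rng, 1), 19.5)
    data.frame(date = dates,
               t_max = tmean + rng / 2,
               t_min = tmean - rng / 2)
  })
}
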