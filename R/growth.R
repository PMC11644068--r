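#' Default growth-model parameters
#'
#' Parameters of the latent AGB trajectory used by the synthetic scene:
#' a logistic curve in the growth process ratio (GPR), with its asymptote
#' modulated by planting density (power law around a 60,000 plants/ha
#' reference), nitrogen rate (saturating, diminishing returns), and potassium
#' rate (mild saturating effect); multiplicative mean-one lognormal noise;
#' and canopy cover as a saturating (exponential) function of AGB.
#'
#' @param asymptote peak fresh AGB at reference management, ton/ha.
#' @param rate logistic growth rate on the GPR scale.
#' @param midpoint GPR at which the logistic reaches half its asymptote.
#' @param dens_ref,dens_exp reference density (plants/ha) and power-law
#'   exponent of the density response.
#' @param n_floor,n_half nitrogen response: fraction of the asymptote reached
#'   at N = 0, and the half-saturation rate (kg/ha).
#' @param k_floor,k_half potassium response, same parameterization.
#' @param cc_rate rate of the canopy-cover saturation, 1/(ton/ha). The
#'   default saturates cover above roughly 3 ton/ha, emulating the spectral
#'   saturation of closed canopies.
#' @param cc_noise_sd sd of additive canopy-architecture noise on true
#'   cover (clipped to \[0, 1\]).
#' @param noise_sdlog sd of the lognormal AGB noise on the log scale.
#' @return named list of parameters.
#' @export
growth_params <- function(asymptote = 4.5, rate = 8, midpoint = 0.55,
                          dens_ref = 60000, dens_exp = 0.4,
                          n_floor = 0.7, n_half = 100,
                          k_floor = 0.9, k_half = 120,
                          cc_rate = 1.0, cc_noise_sd = 0.02,
                          noise_sdlog = 0.15) {
  as.list(environment())
}

#' Deterministic mean AGB response
#'
#' The noise-free latent growth curve: expected above-ground biomass (ton/ha)
#' at a given growth process ratio under the plot's management factors.
#'
#' @param gpr growth process ratio (days after emergence / total period).
#' @param density plants/ha.
#' @param n_rate,k_rate nitrogen and potassium rates, kg/ha.
#' @param params list from [growth_params()].
#' @return numeric vector of expected AGB, ton/ha.
#' @export
agb_response <- function(gpr, density = 60000, n_rate = 120, k_rate = 120,
                         params = growth_params()) {
  a <- params$asymptote *
    (density / params$dens_ref)^params$dens_exp *
    (params$n_floor + (1 - params$n_floor) * n_rate / (n_rate + params$n_half)) *
    (params$k_floor + (1 - params$k_floor) * k_rate / (k_rate + params$k_half))
  a * stats::plogis(params$rate * (gpr - params$midpoint))
}

#' Simulate ground truth for one plot at one flight date
#'
#' Computes the plot's GPR from the cultivar's emergence date and total
#' growth period, evaluates the latent logistic AGB curve under the plot's
#' management factors, applies multiplicative mean-one lognormal noise, and
#' derives true canopy cover as a saturating function of the noisy AGB,
#' clipped to \[0, 1\].
#'
#' @param plot one-row data.frame as returned by [build_design()].
#' @param cultivar one-row data.frame as in [cultivar_catalog()].
#' @param flight_date flight date (Date or string); must not precede
#'   emergence.
#' @param params list from [growth_params()].
#' @param seed integer seed for the noise draw.
#' @param stage optional growth-stage label (S1--S4) carried through.
#' @return one-row data.frame: `plot_id`, `flight_date`, `stage`,
#'   `gpr`, `true_agb` (ton/ha), `true_cc` (fraction).
#' @export
simulate_agb <- function(plot, cultivar, flight_date, params = growth_params(),
                         seed = 1L, stage = NA_character_) {
  flight_date <- as_date(flight_date)
  emergence <- as_date(cultivar$emergence_date)
  if (flight_date < emergence) {
    stop("flight_date ", format(flight_date), " precedes emergence ",
         format(emergence), " for cultivar ", cultivar$cultivar_id)
  }
  t1 <- as.numeric(flight_date - emergence)
  g <- t1 / cultivar$total_period_days
  mu <- agb_response(g, plot$density, plot$n_rate, plot$k_rate, params)
  draws <- withr::with_seed(seed, list(
    agb_noise = if (params$noise_sdlog > 0) {
      stats::rlnorm(1, -params$noise_sdlog^2 / 2, params$noise_sdlog)
    } else 1,
    cc_noise = if (params$cc_noise_sd > 0) {
      stats::rnorm(1, 0, params$cc_noise_sd)
    } else 0
  ))
  agb <- mu * draws$agb_noise
  cc <- min(max(1 - exp(-params$cc_rate * agb) + draws$cc_noise, 0), 1)
  data.frame(plot_id = plot$plot_id, flight_date = flight_date, stage = stage,
             gpr = g, true_agb = agb, true_cc = cc,
             stringsAsFactors = FALSE)
}
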