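#' Sinusoidal-seasonal daily demand generator
#'
#' Generates a daily arrival-count series for one patient class from the
#' cyclical model `D_t = floor(max(0, |sin(t / tau)| * mu + sigma * z_t))`
#' with `z_t ~ Normal(1, 0.1^2)`. `tau` controls the cycle length, `mu` the
#' demand scale and `sigma` the additive noise scale. Counts are clamped at
#' zero before flooring so negative noise draws cannot produce negative
#' arrivals.
#'
#' @param T_horizon Number of days to generate (>= 1).
#' @param tau Cycle length parameter (> 0), in days.
#' @param mu Demand scale (>= 0), in expected-count units.
#' @param sigma Additive noise scale (>= 0), in counts.
#' @param seed Optional integer seed; with a seed the series is a pure
#'   function of its arguments. Without one the current RNG stream is used.
#' @param class_label Label attached to the series (`"urgent"` or `"regular"`).
#' @return A tibble with columns `t`, `weekday` (1..5, Monday-anchored 5-day
#'   workweek), `class_label` and integer `count`.
#' @examples
#' gen_sinusoidal_demand(5, tau = 3, mu = 3, sigma = 1, seed = 1)
#' @export
gen_sinusoidal_demand <- function(T_horizon, tau, mu, sigma, seed = NULL,
                                  class_label = "urgent") {
  check_scalar_number(T_horizon, "T_horizon", lower = 1)
  if (T_horizon != floor(T_horizon)) abort("`T_horizon` must be an integer.")
  check_scalar_number(tau, "tau", lower = 1e-12)
  check_scalar_number(mu, "mu", lower = 0)
  check_scalar_number(sigma, "sigma", lower = 0)
  t <- seq_len(T_horizon)
  z <- with_seed_if(seed, rnorm(T_horizon, mean = 1, sd = 0.1))
  tibble(
    t = as.integer(t),
    weekday = workday_of(t),
    class_label = class_label,
    count = count_floor(abs(sin(t / tau)) * mu + sigma * z)
  )
}

# release fraction at day t given a standard normal draw z:
# |sin(t/6)| * N(0.5, 0.2^2), clipped into [0, 1] so a release never exceeds
# the occupied census
release_fraction <- function(t, z) clip01(abs(sin(t / 6)) * (0.5 + 0.2 * z))

#' Cyclical random bed release
#'
#' Number of beds released by discharges on day `t` out of `B_t` occupied
#' beds, following `eps_t = floor(frac_t * B_t)` with
#' `frac_t = |sin(t / 6)| * N(0.5, 0.2^2)` clipped to `[0, 1]`. The clip
#' guarantees `0 <= eps_t <= B_t`.
#'
#' @param B_t Occupied-bed count (>= 0).
#' @param t Day index.
#' @param seed Optional integer seed.
#' @return A single nonnegative integer, at most `B_t`.
#' @examples
#' gen_released_beds(40, t = 9, seed = 1)
#' @export
gen_released_beds <- function(B_t, t, seed = NULL) {
  check_scalar_number(B_t, "B_t", lower = 0)
  check_scalar_number(t, "t")
  z <- with_seed_if(seed, rnorm(1))
  int_floor(release_fraction(t, z) * B_t)
}

#' Feature-tagged two-class demand history
#'
#' Generates a weekday-tagged demand history with an annual seasonal cycle,
#' for demonstrating and testing the feature-based (kernel-optimization)
#' newsvendor solver. Daily total demand follows
#' `total_mean * (1 + season_amp * sin(2 pi t / year_length)) * wd_mult[wd]`
#' split between classes by `urgent_share`, plus Gaussian noise, clamped and
#' floored to counts.
#'
#' @param n Number of periods (>= 1).
#' @param seed Optional integer seed (same seed, identical history).
#' @param urgent_share Long-run share of demand that is urgent (default 0.24,
#'   i.e. roughly one urgent for three regular arrivals).
#' @param total_mean Mean daily total demand at seasonal baseline.
#' @param year_length Length of one seasonal cycle in workdays (260 = one
#'   year of 5-day weeks).
#' @param wd_mult Length-5 weekday multipliers (Monday..Friday).
#' @param sd1,sd2 Noise standard deviations for the urgent/regular counts.
#' @return A tibble with columns `t`, `weekday`, `season_sin`, `season_cos`,
#'   `D1`, `D2`.
#' @examples
#' gen_feature_history(10, seed = 1)
#' @export
gen_feature_history <- function(n, seed = NULL, urgent_share = 0.24,
                                total_mean = 25, year_length = 260,
                                wd_mult = c(1.15, 1, 0.95, 1, 0.9),
                                sd1 = 1.5, sd2 = 3) {
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(urgent_share, "urgent_share", lower = 0, upper = 1)
  check_scalar_number(total_mean, "total_mean", lower = 0)
  stopifnot(length(wd_mult) == 5L)
  t <- seq_len(n)
  wd <- workday_of(t)
  season <- 1 + 0.3 * sin(2 * pi * t / year_length)
  mu_tot <- total_mean * season * wd_mult[wd]
  zz <- with_seed_if(seed, list(z1 = rnorm(n), z2 = rnorm(n)))
  tibble(
    t = as.integer(t),
    weekday = wd,
    season_sin = sin(2 * pi * t / year_length),
    season_cos = cos(2 * pi * t / year_length),
    D1 = count_floor(urgent_share * mu_tot + sd1 * zz$z1 + 0.5),
    D2 = count_floor((1 - urgent_share) * mu_tot + sd2 * zz$z2 + 0.5)
  )
}

#' Default configuration for the hospital-trace generator
#'
#' The defaults emulate a saturated 140-bed specialty care unit on a 5-day
#' workweek: a waiting list of about 340 patients of which roughly one in six
#' is urgent, near-100% bed occupancy, Friday-peaked discharge rates, and a
#' few same-day admissions per day.
#'
#' @param K Total standard beds.
#' @param W1_0,W2_0 Initial urgent/regular waiting censuses.
#' @param B1_0,B2_0,X_0 Initial urgent/regular inpatient censuses and bed
#'   slack; must satisfy `B1_0 + B2_0 + X_0 = K`.
#' @param mu1,mu2 Mean daily urgent/regular arrival scales.
#' @param season_amp,season_cycle Amplitude and period (days) of the seasonal
#'   modulation of arrivals.
#' @param sd1,sd2 Arrival noise standard deviations.
#' @param E_mean Mean number of same-day admissions per day (Poisson).
#' @param gamma1_profile,gamma2_profile Length-5 weekday discharge-fraction
#'   profiles (Monday..Friday), Friday-peaked by default.
#' @param gamma_cv Coefficient of variation of the daily discharge fractions.
#' @export
trace_config <- function(K = 140, W1_0 = 54, W2_0 = 286,
                         B1_0 = 22, B2_0 = 118, X_0 = 0,
                         mu1 = 2.4, mu2 = 10.4,
                         season_amp = 0.2, season_cycle = 50,
                         sd1 = 1, sd2 = 2, E_mean = 2,
                         gamma1_profile = c(0.08, 0.08, 0.08, 0.09, 0.12),
                         gamma2_profile = c(0.10, 0.09, 0.09, 0.10, 0.14),
                         gamma_cv = 0.15) {
  cfg <- list(K = K, W1_0 = W1_0, W2_0 = W2_0, B1_0 = B1_0, B2_0 = B2_0,
              X_0 = X_0, mu1 = mu1, mu2 = mu2, season_amp = season_amp,
              season_cycle = season_cycle, sd1 = sd1, sd2 = sd2,
              E_mean = E_mean, gamma1_profile = gamma1_profile,
              gamma2_profile = gamma2_profile, gamma_cv = gamma_cv)
  if (cfg$B1_0 + cfg$B2_0 + cfg$X_0 != cfg$K) {
    abort("Inconsistent initial state: B1_0 + B2_0 + X_0 must equal K.")
  }
  stopifnot(length(cfg$gamma1_profile) == 5L, length(cfg$gamma2_profile) == 5L)
  cfg
}

new_hospital_trace <- function(days, init_state, K) {
  structure(as_tibble(days), init_state = init_state, K = as.integer(K),
            class = c("hospital_trace", class(as_tibble(days))))
}

#' @export
print.hospital_trace <- function(x, ...) {
  init <- attr(x, "init_state")
  cat("<hospital_trace> ", nrow(x), " workdays, K = ", attr(x, "K"),
      ", initial W = (", init$W1, ", ", init$W2, "), B = (", init$B1, ", ",
      init$B2, "), X = ", init$X, "\n", sep = "")
  NextMethod()
}

#' Synthetic hospital trace
#'
#' Generates the per-day exogenous record consumed by the multiperiod
#' revenue-plus-equity pipeline: two-class arrivals with mild seasonality,
#' same-day admissions, and weekday-profiled random discharge fractions,
#' plus a consistent initial state. The defaults (see [trace_config()]) are
#' calibrated so that running the admission model with its default controls
#' over ~193 workdays keeps the total waiting census near 340, the urgent
#' share of the waiting list near one sixth, and the ward essentially full.
#'
#' @param T_horizon Number of workdays (>= 1).
#' @param config A [trace_config()] list.
#' @param seed Optional integer seed.
#' @return A `hospital_trace`: a tibble with columns `day`, `weekday`, `D1`,
#'   `D2`, `E`, `gamma1`, `gamma2`, carrying attributes `init_state`
#'   (`W1`, `W2`, `B1`, `B2`, `X`) and `K`.
#' @examples
#' gen_hospital_trace(5, seed = 1)
#' @export
gen_hospital_trace <- function(T_horizon, config = trace_config(), seed = NULL) {
  check_scalar_number(T_horizon, "T_horizon", lower = 1)
  if (T_horizon != floor(T_horizon)) abort("`T_horizon` must be an integer.")
  cfg <- do.call(trace_config, config[names(config) %in% names(formals(trace_config))])
  t <- seq_len(T_horizon)
  wd <- workday_of(t)
  season <- 1 + cfg$season_amp * sin(2 * pi * t / cfg$season_cycle)
  draws <- with_seed_if(seed, list(
    z1 = rnorm(T_horizon), z2 = rnorm(T_horizon),
    E = rpois(T_horizon, cfg$E_mean),
    g1 = rnorm(T_horizon), g2 = rnorm(T_horizon)
  ))
  days <- tibble(
    day = as.integer(t),
    weekday = wd,
    D1 = count_floor(cfg$mu1 * season + cfg$sd1 * draws$z1),
    D2 = count_floor(cfg$mu2 * season + cfg$sd2 * draws$z2),
    E = as.integer(draws$E),
    gamma1 = clip01(cfg$gamma1_profile[wd] * (1 + cfg$gamma_cv * draws$g1)),
    gamma2 = clip01(cfg$gamma2_profile[wd] * (1 + cfg$gamma_cv * draws$g2))
  )
  new_hospital_trace(
    days,
    init_state = list(W1 = as.integer(cfg$W1_0), W2 = as.integer(cfg$W2_0),
                      B1 = as.integer(cfg$B1_0), B2 = as.integer(cfg$B2_0),
                      X = as.integer(cfg$X_0)),
    K = cfg$K
  )
}
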