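#' Configuration of the daily-series simulator
#'
#' Defines a seeded generating process with the statistical structure the
#' case-crossover C-RF method assumes: daily Poisson event counts with
#' day-of-week and seasonal variation, a seasonal autocorrelated
#' non-negative exposure, seasonal temperature and humidity, a
#' temperature-to-count confounding path (temperature and exposure share
#' the seasonal cycle), and a known true concentration-response acting on
#' lagged exposure.
#'
#' The log mean count on day t is
#' `log(baseline) + dow + seasonal + sum_L lag_effects[L+1] *
#' beta_true(Z[t-L]) + confounding`, with
#' `beta_true(Z) = theta * log(1 + Z/A) * LWF(Z; mu, tau, r)` evaluated at
#' the fixed reference range `true_r`. Every non-constant term is centred
#' to mean zero over the simulated window, so `baseline` is the marginal
#' mean daily count regardless of effect or confounding settings (the
#' within-stratum contrasts that drive estimation are unaffected by
#' centring).
#'
#' `lag_effects[L+1]` multiplies the full true curve at lag L: `c(1)` puts
#' the whole effect at lag 0; `c(rep(1, 9), 0)` reproduces the situation
#' of equal positive effects at lags 0-8 and none at lag 9.
#'
#' @param n_days number of simulated days (>= 60).
#' @param start first calendar day.
#' @param baseline marginal mean daily count (> 0).
#' @param dow_effects 7 log-scale day-of-week effects (Mon..Sun), centred
#'   internally.
#' @param season_amp log-scale amplitude of the seasonal count cycle.
#' @param season_peak_doy day-of-year of the count peak (default mid
#'   January, a winter-peaking respiratory outcome).
#' @param exposure_mean,exposure_amp seasonal mean and amplitude of the
#'   exposure (ppb), peaking at `exposure_peak_doy` (default mid July,
#'   summer-peaking ozone).
#' @param exposure_ar,exposure_sd AR(1) coefficient (in \[0, 1)) and
#'   innovation SD of the exposure noise; the series is truncated at 0.
#' @param temp_mean,temp_amp,temp_sd temperature cycle (deg C), peaking at
#'   `exposure_peak_doy` (the shared cycle is the confounding channel).
#' @param hum_mean,hum_amp,hum_sd relative humidity (%), clamped to
#'   \[0, 100\], peaking with the count season.
#' @param theta true C-RF slope (0 for a null series).
#' @param true_crf a [transform_spec()] giving the true curve shape (any
#'   family; an unweighted identity spec gives a log-linear truth).
#' @param true_r fixed reference concentration range (ppb) of the true
#'   curve's LWF.
#' @param lag_effects per-lag multipliers of the true curve (lags
#'   0..length-1).
#' @param temp_lin,temp_quad confounding coefficients on the standardised
#'   temperature and its square (log scale); defaults give a mild U-shape
#'   (excess events in cold and hot spells).
#' @param seed integer seed used by [simulate_daily_series()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_days = 3652, start = "1992-04-01", baseline = 80,
                       dow_effects = c(0.04, 0.01, 0, 0, 0.01, -0.03, -0.03),
                       season_amp = 0.10, season_peak_doy = 15,
                       exposure_mean = 25, exposure_amp = 10,
                       exposure_ar = 0.7, exposure_sd = 6,
                       exposure_peak_doy = 196,
                       temp_mean = 4, temp_amp = 16, temp_sd = 3,
                       hum_mean = 65, hum_amp = 8, hum_sd = 8,
                       theta = 0.05,
                       true_crf = transform_spec("scaled_log", A = 20,
                                                 mu = 12, tau = 0.02),
                       true_r = 50,
                       lag_effects = c(rep(1, 9), 0),
                       temp_lin = -0.02, temp_quad = 0.015,
                       seed = 1L) {
  if (n_days < 60) stop("n_days must be >= 60")
  if (baseline <= 0) stop("baseline must be > 0")
  if (exposure_ar < 0 || exposure_ar >= 1) stop("exposure_ar must be in [0, 1)")
  if (length(dow_effects) != 7) stop("dow_effects must have 7 values (Mon..Sun)")
  stopifnot(inherits(true_crf, "transform_spec"), true_r > 0,
            all(lag_effects >= 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Preset emulating a decade-long urban ED-visit series
#'
#' Ten years (3652 consecutive days from 1992-04-01) of respiratory
#' emergency-department-style counts averaging ~80/day (~292,000 events in
#' total), with a summer-peaking ozone-like exposure (seasonal mean 25
#' ppb, AR(1) day-to-day persistence), a cold-winter temperature cycle,
#' winter-peaking counts, temperature confounding, and a true scaled-log
#' C-RF acting equally at lags 0-8 with no effect at lag 9. All choices
#' are the [sim_config()] defaults; override any of them through `...`.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
edmonton_like_config <- function(...) sim_config(...)

#' Generate a seeded daily series with a known true C-RF
#'
#' See [sim_config()] for the generating process. The returned series
#' carries the truth record (true parameters, reference range, lag
#' multipliers, seed) as attribute `"truth"`, which
#' [write_daily_series()] can save as a JSON sidecar.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed`.
#' @return a [daily_series()] of `config$n_days` rows.
#' @export
simulate_daily_series <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  cf <- config
  lead <- max(length(cf$lag_effects) - 1L, 0L) + 60L   # AR burn-in + lag lead
  N <- cf$n_days + lead
  dates_full <- as.Date(cf$start) - lead + seq_len(N) - 1L
  doy <- as.POSIXlt(dates_full)$yday + 1
  cyc <- function(peak) cospi(2 * (doy - peak) / 365.25)

  ar_noise <- as.numeric(stats::filter(stats::rnorm(N, 0, cf$exposure_sd),
                                       cf$exposure_ar, method = "recursive",
                                       init = stats::rnorm(1, 0, cf$exposure_sd /
                                                             sqrt(1 - cf$exposure_ar^2))))
  Z <- pmax(0, cf$exposure_mean + cf$exposure_amp * cyc(cf$exposure_peak_doy) +
                 ar_noise)
  temp <- cf$temp_mean + cf$temp_amp * cyc(cf$exposure_peak_doy) +
    stats::rnorm(N, 0, cf$temp_sd)
  hum <- pmin(100, pmax(0, cf$hum_mean + cf$hum_amp * cyc(cf$season_peak_doy) +
                             stats::rnorm(N, 0, cf$hum_sd)))

  beta_true <- cf$theta * apply_transform(Z, cf$true_crf, r = cf$true_r)
  effect <- numeric(N)
  for (L in seq_along(cf$lag_effects) - 1L) {
    if (cf$lag_effects[L + 1L] == 0) next
    idx <- (lead + 1L):N
    effect[idx] <- effect[idx] + cf$lag_effects[L + 1L] * beta_true[idx - L]
  }

  idx <- (lead + 1L):N
  wday <- as.POSIXlt(dates_full[idx])$wday
  wday <- ifelse(wday == 0L, 7L, wday)
  ctr <- function(x) x - mean(x)
  ts_std <- (temp[idx] - cf$temp_mean) / 10
  lp <- log(cf$baseline) +
    ctr((cf$dow_effects - mean(cf$dow_effects))[wday]) +
    ctr(cf$season_amp * cyc(cf$season_peak_doy)[idx]) +
    ctr(effect[idx]) +
    ctr(cf$temp_lin * ts_std + cf$temp_quad * ts_std^2)
  counts <- stats::rpois(cf$n_days, exp(lp))

  out <- daily_series(dates_full[idx], counts, Z[idx], temp[idx], hum[idx])
  attr(out, "truth") <- list(theta = cf$theta, family = cf$true_crf$family,
                             A = cf$true_crf$A, mu = cf$true_crf$mu,
                             tau = cf$true_crf$tau, r = cf$true_r,
                             lag_effects = cf$lag_effects,
                             baseline = cf$baseline, seed = as.integer(seed))
  out
}

#' True relative risk of a simulation configuration
#'
#' Evaluates the generating concentration-response curve
#' `exp(theta * log(1 + z/A) * LWF(z; mu, tau, true_r))` of a
#' [sim_config()] (per unit of lag multiplier).
#'
#' @param config a `sim_config`.
#' @param z concentrations (ppb).
#' @return numeric vector of true RR values.
#' @export
true_rr <- function(config, z) {
  stopifnot(inherits(config, "sim_config"))
  exp(config$theta * apply_transform(z, config$true_crf, r = config$true_r))
}
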