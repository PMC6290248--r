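#' Configuration of the synthetic weather generator
#'
#' Daily mean temperature is a seasonal sinusoid (warmest in mid-July) plus
#' lag-1 autocorrelated Gaussian noise; minimum and maximum are the mean
#' minus/plus half the diurnal range. Defaults emulate a mid-elevation
#' central-France orchard climate.
#'
#' @param start_date First day of the series.
#' @param n_days Series length in days.
#' @param annual_mean Annual mean temperature (deg C).
#' @param amplitude Seasonal half-amplitude (deg C).
#' @param diurnal_range Daily tmax - tmin (deg C).
#' @param noise_sd Marginal standard deviation of the day-to-day noise
#'   (deg C).
#' @param ar1 Lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `weather_config` list.
#' @export
weather_config <- function(start_date = "2008-08-20",
                           n_days = 300L,
                           annual_mean = 11,
                           amplitude = 8,
                           diurnal_range = 8,
                           noise_sd = 3,
                           ar1 = 0.7,
                           seed = 1L) {
  if (amplitude < 0) stop("amplitude must be nonnegative", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must lie in [0, 1)", call. = FALSE)
  if (n_days < 1L) stop("n_days must be >= 1", call. = FALSE)
  structure(list(start_date = as.Date(start_date), n_days = as.integer(n_days),
                 annual_mean = annual_mean, amplitude = amplitude,
                 diurnal_range = diurnal_range, noise_sd = noise_sd,
                 ar1 = ar1, seed = as.integer(seed)),
            class = "weather_config")
}

#' Generate a synthetic daily weather series
#'
#' @param cfg A [weather_config()] object.
#' @return Data frame with `date`, `tmin`, `tmean`, `tmax`.
#' @export
generate_weather <- function(cfg = weather_config()) {
  stopifnot(inherits(cfg, "weather_config"))
  dates <- seq(cfg$start_date, by = "day", length.out = cfg$n_days)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- cfg$annual_mean +
    cfg$amplitude * cos(2 * pi * (doy - 196) / 365.25)
  eps <- with_local_seed(cfg$seed, {
    e <- numeric(cfg$n_days)
    if (cfg$noise_sd > 0) {
      e[1L] <- stats::rnorm(1L, 0, cfg$noise_sd)
      innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar1^2)
      innov <- stats::rnorm(cfg$n_days, 0, innov_sd)
      for (t in seq_len(cfg$n_days - 1L))
        e[t + 1L] <- cfg$ar1 * e[t] + innov[t + 1L]
    }
    e
  })
  tmean <- seasonal + eps
  data.frame(date = dates,
             tmin = tmean - cfg$diurnal_range / 2,
             tmean = tmean,
             tmax = tmean + cfg$diurnal_range / 2)
}

#' Ground-truth model parameters of the default synthetic fixture
#'
#' A parameter set per variant producing the canonical winter pattern:
#' starch falls and GFS rises from autumn into midwinter (cold hydrolysis
#' around 0 deg C, mild hydrolysis around 17 deg C active in autumn), then
#' the trend reverses in late winter as re-synthesis (optimum 13 deg C)
#' strengthens with the phenological stage. The optimal temperatures are the
#' same across variants; rate magnitudes are rescaled to each variant's
#' units.
#'
#' @param variant Model variant.
#' @return A [model_params()] object.
#' @export
default_true_params <- function(variant = c("intermediate", "simple",
                                            "complete")) {
  variant <- match.arg(variant)
  resp <- respiration_params(r_max = 0.3, a3 = -10, b3 = 0.8, q10 = 2.64)
  switch(variant,
    intermediate = model_params(
      "intermediate",
      k1c = reaction_params(0.020, d_endo = 0.015, d_eco = -0.015,
                            mu = -0.1, sigma = 8),
      k1m = reaction_params(0.004, d_endo = -0.012, d_eco = -0.004,
                            mu = 17, sigma = 15),
      k2 = reaction_params(0.010, d_endo = 0.010, d_eco = 0.010,
                           mu = 13, sigma = 10),
      resp = resp),
    simple = model_params(
      "simple",
      k1c = reaction_params(1.5, d_endo = 1.0, d_eco = -1.0,
                            mu = -0.1, sigma = 8),
      k1m = reaction_params(0.4, d_endo = -0.8, d_eco = -0.4,
                            mu = 17, sigma = 15),
      k2 = reaction_params(0.8, d_endo = 0.8, d_eco = 0.8,
                           mu = 13, sigma = 10),
      resp = resp),
    complete = model_params(
      "complete",
      k1c = reaction_params(3.0, d_endo = 2.0, d_eco = -2.0,
                            mu = -0.1, sigma = 8, km = 100),
      k1m = reaction_params(0.6, d_endo = -1.8, d_eco = -0.6,
                            mu = 17, sigma = 15, km = 100),
      k2 = reaction_params(1.5, d_endo = 1.5, d_eco = 1.5,
                           mu = 13, sigma = 10, km = 100),
      resp = resp))
}

#' Configuration of the synthetic field-monitoring generator
#'
#' Emulates monthly destructive sampling of one latent branch trajectory:
#' the carbon model is run under known true parameters, sampled every
#' `sampling_interval` days, and independent Gaussian observation noise is
#' added per variable. Water content follows a piecewise-linear seasonal
#' profile (an observed input in the field, not a modelled state).
#'
#' @param true_params Ground-truth [model_params()].
#' @param fh True osmo-hydric coefficients ([fh_params()]) generating the
#'   frost-hardiness observations.
#' @param init Named initial state (`gfs`, `starch`, mg g DM^-1) at the
#'   start of the leafless window.
#' @param wc_knots Optional data frame `date`, `wc` of water-content profile
#'   knots; defaults to a declining-then-recovering seasonal profile over
#'   the simulated window.
#' @param sampling_interval Days between destructive samplings.
#' @param noise_gfs,noise_starch Observation noise SD (mg g DM^-1).
#' @param noise_wc Observation noise SD (g g^-1).
#' @param noise_fh Observation noise SD (deg C).
#' @param pheno_params [phenology_params()] for the dormancy model.
#' @param seed Integer seed.
#' @return A `field_config` list.
#' @export
field_config <- function(true_params = default_true_params("intermediate"),
                         fh = fh_params(),
                         init = c(gfs = 25, starch = 90),
                         wc_knots = NULL,
                         sampling_interval = 30L,
                         noise_gfs = 5,
                         noise_starch = 5,
                         noise_wc = 0.03,
                         noise_fh = 1,
                         pheno_params = phenology_params(),
                         seed = 1L) {
  stopifnot(inherits(true_params, "model_params"),
            inherits(fh, "fh_params"),
            inherits(pheno_params, "phenology_params"))
  if (any(c(noise_gfs, noise_starch, noise_wc, noise_fh) < 0))
    stop("noise SDs must be nonnegative", call. = FALSE)
  if (any(init < 0)) stop("initial pools must be nonnegative", call. = FALSE)
  structure(list(true_params = true_params, fh = fh, init = init,
                 wc_knots = wc_knots,
                 sampling_interval = as.integer(sampling_interval),
                 noise_gfs = noise_gfs, noise_starch = noise_starch,
                 noise_wc = noise_wc, noise_fh = noise_fh,
                 pheno_params = pheno_params, seed = as.integer(seed)),
            class = "field_config")
}

default_wc_knots <- function(start, end) {
  offs <- c(0L, 90L, 180L, 270L)
  vals <- c(0.85, 0.70, 0.75, 0.95)
  kd <- start + offs
  keep <- kd < end
  kd <- c(kd[keep], end)
  vals <- c(vals[keep], vals[sum(keep) + 1L])
  if (is.na(vals[length(vals)])) vals[length(vals)] <- 0.95
  data.frame(date = kd, wc = vals)
}

#' Generate a synthetic field observation series with its latent truth
#'
#' Runs phenology, the carbon simulator and the osmo-hydric predictor under
#' the configured true parameters over the leafless window of `weather`,
#' samples the latent trajectory at regular intervals and adds observation
#' noise.
#'
#' @param weather Daily weather data frame (e.g. from [generate_weather()]).
#' @param cfg A [field_config()] object.
#' @return A `field_dataset` list: `observations` (data frame `date`, `gfs`,
#'   `starch`, `wc`, `fh`), `latent` (noiseless `carbon_trajectory`),
#'   `pheno`, `wc_knots`, `weather`, `config`.
#' @export
generate_field_dataset <- function(weather, cfg = field_config()) {
  stopifnot(inherits(cfg, "field_config"))
  pheno <- accumulate_phenology(weather, cfg$pheno_params,
                                stop_at_budburst = TRUE)
  dates <- as.Date(pheno$date)
  knots <- cfg$wc_knots
  if (is.null(knots))
    knots <- default_wc_knots(dates[1L], dates[length(dates)])
  latent <- simulate_carbon(weather, knots, pheno, cfg$init, cfg$true_params)
  n <- nrow(latent) - 1L  # dated, driven days
  s_idx <- seq(1L, n, by = cfg$sampling_interval)
  lat <- latent[s_idx, , drop = FALSE]
  fh_lat <- predict_fh(lat$gfs, lat$wc, cfg$fh)
  obs <- with_local_seed(cfg$seed, {
    m <- length(s_idx)
    data.frame(date = lat$date,
               gfs = pmax(0, lat$gfs + stats::rnorm(m, 0, cfg$noise_gfs)),
               starch = pmax(0, lat$starch +
                               stats::rnorm(m, 0, cfg$noise_starch)),
               wc = pmax(0.01, lat$wc + stats::rnorm(m, 0, cfg$noise_wc)),
               fh = fh_lat + stats::rnorm(m, 0, cfg$noise_fh))
  })
  structure(list(observations = obs, latent = latent, pheno = pheno,
                 wc_knots = knots, weather = weather, config = cfg),
            class = "field_dataset")
}

#' Emulate a controlled-temperature branch-storage experiment
#'
#' Detached branches sampled from the field on a given date are held at
#' constant temperatures for fixed durations. The branch state at sampling
#' is taken from the latent field trajectory; water content stays fixed at
#' its sampling-day value (cut ends sealed), while chilling/forcing
#' accumulation continues at the treatment temperature.
#'
#' @param field A `field_dataset` from [generate_field_dataset()].
#' @param date Sampling date (must lie on the latent trajectory).
#' @param temps Treatment temperatures (deg C); default the seven-level
#'   grid -3 to +25.
#' @param durations Storage durations in days; default 7 and 20.
#' @param params Model parameters driving the storage dynamics; default the
#'   field truth.
#' @return Data frame with one row per temperature x duration: initial and
#'   final pools, per-day changes, and the normalised responses
#'   `dgfs_norm` (delta GFS/day over initial starch) and `dstarch_norm`
#'   (delta starch/day over initial GFS).
#' @export
generate_cc_experiment <- function(field, date,
                                   temps = c(-3, 1, 5, 10, 15, 20, 25),
                                   durations = c(7L, 20L),
                                   params = field$config$true_params) {
  stopifnot(inherits(field, "field_dataset"))
  date <- as.Date(date)
  i <- match(date, as.Date(field$latent$date))
  if (is.na(i))
    stop("date is outside the simulated field trajectory", call. = FALSE)
  j <- match(date, as.Date(field$pheno$date))
  gfs0 <- field$latent$gfs[i]; starch0 <- field$latent$starch[i]
  wc0 <- field$latent$wc[i]
  cu0 <- field$pheno$cu[j]; fu0 <- field$pheno$fu[j]
  pp <- field$config$pheno_params
  dmax <- max(durations)
  rows <- list()
  for (temp in temps) {
    if (dmax > 0L) {
      cu <- cu0 + chilling_increment(temp, pp) * (seq_len(dmax) - 1L)
      fu <- numeric(dmax); fu[1L] <- fu0
      finc <- forcing_increment(temp, pp)
      for (t in seq_len(dmax - 1L))
        fu[t + 1L] <- if (cu[t] >= pp$cu_crit) fu[t] + finc else 0
      ps <- pmin(pmin(cu / pp$cu_crit, 1) + pmin(fu / pp$fu_crit, 1), 2)
      core <- simulate_core(rep(temp, dmax), rep(wc0, dmax), ps,
                            gfs0, starch0, params)
    }
    for (d in durations) {
      if (d == 0L) {
        g <- gfs0; st <- starch0
      } else {
        g <- core$gfs[d + 1L]; st <- core$starch[d + 1L]
      }
      dg <- if (d == 0L) 0 else (g - gfs0) / d
      dst <- if (d == 0L) 0 else (st - starch0) / d
      rows[[length(rows) + 1L]] <- data.frame(
        temperature = temp, duration = d,
        gfs0 = gfs0, starch0 = starch0, gfs = g, starch = st,
        dgfs_per_day = dg, dstarch_per_day = dst,
        dgfs_norm = if (starch0 > 0) dg / starch0 else NA_real_,
        dstarch_norm = if (gfs0 > 0) dst / gfs0 else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Derive a carbohydrate-depleted scenario configuration
#'
#' Mirrors the field manipulation in which trees were defoliated during the
#' growing season to deplete their non-structural carbohydrate reserves:
#' returns the same configuration with initial starch reduced by `fraction`.
#'
#' @param cfg A [field_config()] object.
#' @param fraction Fraction of initial starch removed, in `[0, 1]`
#'   (default 0.6).
#' @return A modified `field_config`.
#' @export
generate_depleted_scenario <- function(cfg, fraction = 0.6) {
  stopifnot(inherits(cfg, "field_config"))
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  cfg$init[["starch"]] <- cfg$init[["starch"]] * (1 - fraction)
  cfg
}
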