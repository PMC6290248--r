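# Shared fixtures: small weather makers, an independent phenology oracle,
# and a toy reaction used across kinetics tests.

make_constant_weather <- function(theta, n_days,
                                  start = as.Date("2008-08-25")) {
  data.frame(date = seq(start, by = "day", length.out = n_days),
             tmean = rep(theta, n_days))
}

make_random_weather <- function(n_days, seed,
                                start = as.Date("2008-08-25")) {
  set.seed(seed)
  data.frame(date = seq(start, by = "day", length.out = n_days),
             tmean = stats::runif(n_days, -10, 30))
}

# Day-by-day re-accumulation of CU/FU/PS written directly from the model
# definitions, independent of the package's vectorised bookkeeping.
naive_phenology <- function(weather, p = phenology_params()) {
  dates <- as.Date(weather$date)
  theta <- weather$tmean
  doy <- as.integer(format(dates, "%j"))
  i0 <- which(doy == p$start_doy)[1]
  idx <- i0:length(dates)
  cu <- fu <- ps <- numeric(length(idx))
  for (k in seq_along(idx)[-1]) {
    th <- theta[idx[k - 1]]
    cu[k] <- cu[k - 1] + max(min(p$t_high - th, p$t_high - p$t_low), 0)
    fu[k] <- if (cu[k - 1] >= p$cu_crit)
      fu[k - 1] + 1 / (1 + exp(-p$slp * (th - p$t50))) else 0
  }
  for (k in seq_along(idx))
    ps[k] <- min(cu[k] / p$cu_crit, 1) + min(fu[k] / p$fu_crit, 1)
  data.frame(date = dates[idx], cu = cu, fu = fu, ps = ps)
}

toy_reaction <- function(k_trans = 4, d_endo = 2, d_eco = -1, mu = 10,
                         sigma = 20, km = NULL) {
  reaction_params(k_trans = k_trans, d_endo = d_endo, d_eco = d_eco,
                  mu = mu, sigma = sigma, km = km)
}

# A small noiseless field world shared by calibration/evaluation tests.
make_noiseless_world <- function(seed = 11L) {
  w <- generate_weather(weather_config(seed = seed))
  cfg <- field_config(seed = seed, noise_gfs = 0, noise_starch = 0,
                      noise_wc = 0, noise_fh = 0)
  fd <- generate_field_dataset(w, cfg)
  list(weather = w, field = fd,
       data = suppressWarnings(prepare_calibration_data(w, fd$observations)))
}
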