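test_that("degenerate weather configs give a constant series", {
  cfg <- weather_config(n_days = 50, annual_mean = 9, amplitude = 0,
                        noise_sd = 0, diurnal_range = 6)
  w <- generate_weather(cfg)
  expect_equal(w$tmean, rep(9, 50))
  expect_equal(w$tmax - w$tmin, rep(6, 50))
})

test_that("weather generation is a pure function of its seed", {
  w1 <- generate_weather(weather_config(seed = 21))
  w2 <- generate_weather(weather_config(seed = 21))
  w3 <- generate_weather(weather_config(seed = 22))
  expect_identical(w1, w2)
  expect_false(isTRUE(all.equal(w1$tmean, w3$tmean)))
})

test_that("the noise process has the configured lag-1 autocorrelation", {
  cfg <- weather_config(n_days = 3650, ar1 = 0.7, seed = 13)
  w <- generate_weather(cfg)
  doy <- as.integer(format(as.Date(w$date), "%j"))
  seasonal <- cfg$annual_mean +
    cfg$amplitude * cos(2 * pi * (doy - 196) / 365.25)
  resid <- w$tmean - seasonal
  ac1 <- cor(resid[-1], resid[-length(resid)])
  expect_lt(abs(ac1 - 0.7), 0.1)
  expect_lt(abs(sd(resid) - cfg$noise_sd), 0.5)
})

test_that("zero observation noise puts samples exactly on the latent truth", {
  world <- make_noiseless_world()
  obs <- world$field$observations
  lat <- world$field$latent
  idx <- match(as.Date(obs$date), as.Date(lat$date))
  expect_equal(obs$gfs, lat$gfs[idx])
  expect_equal(obs$starch, lat$starch[idx])
  expect_equal(obs$wc, lat$wc[idx])
  expect_equal(obs$fh, predict_fh(lat$gfs[idx], lat$wc[idx],
                                  world$field$config$fh))
  # closes the loop with calibration
  expect_equal(carbon_objective(world$field$config$true_params, world$data),
               0)
})

test_that("observation noise has the configured second moment", {
  w <- generate_weather(weather_config(seed = 31))
  cfg <- field_config(seed = 31, sampling_interval = 3L, noise_gfs = 5,
                      noise_starch = 0, noise_wc = 0, noise_fh = 0)
  fd <- generate_field_dataset(w, cfg)
  idx <- match(as.Date(fd$observations$date), as.Date(fd$latent$date))
  dev <- fd$observations$gfs - fd$latent$gfs[idx]
  expect_gt(length(dev), 60)
  expect_lt(abs(mean(dev^2) - 25), 10)
})

test_that("the default fixture reproduces the midwinter sugar peak", {
  w <- generate_weather(weather_config(seed = 11))
  fd <- generate_field_dataset(w, field_config(seed = 11))
  lat <- fd$latent
  n <- nrow(lat)
  peak <- which.max(lat$gfs)
  expect_gt(peak, n %/% 4)          # peak well inside the season
  expect_lt(peak, 3 * n %/% 4)
  expect_gt(lat$gfs[peak], lat$gfs[1])       # GFS rises into midwinter
  expect_lt(lat$gfs[n], lat$gfs[peak])       # and falls back afterwards
  trough <- which.min(lat$starch)
  expect_lt(lat$starch[trough], lat$starch[1])  # starch is drawn down
  expect_gt(lat$starch[n], lat$starch[trough])  # then re-synthesised
})

test_that("controlled-temperature treatments hold state and continue phenology", {
  w <- generate_weather(weather_config(seed = 11))
  fd <- generate_field_dataset(w, field_config(seed = 11))
  date <- as.Date(fd$latent$date[60])
  cc <- generate_cc_experiment(fd, date)
  expect_identical(nrow(cc), 14L)   # 7 temperatures x 2 durations
  expect_setequal(unique(cc$temperature), c(-3, 1, 5, 10, 15, 20, 25))
  expect_setequal(unique(cc$duration), c(7, 20))

  cc0 <- generate_cc_experiment(fd, date, temps = 5, durations = 0L)
  expect_equal(cc0$gfs, cc0$gfs0)
  expect_equal(cc0$dgfs_norm, 0)

  expect_error(generate_cc_experiment(fd, as.Date("1999-01-01")),
               "outside")
})

test_that("cold storage at the cold-hydrolysis optimum converts starch to GFS", {
  w <- generate_weather(weather_config(seed = 11))
  p <- default_true_params("intermediate")
  p$k1c <- reaction_params(0.05, 0.015, -0.015, mu = -0.1, sigma = 8)
  fd <- generate_field_dataset(w, field_config(true_params = p, seed = 11))
  date <- as.Date(fd$latent$date[120])
  cc <- generate_cc_experiment(fd, date, temps = -0.1, durations = c(7L, 20L))
  expect_true(all(cc$starch < cc$starch0))
  expect_true(all(cc$gfs > cc$gfs0))
  expect_true(all(cc$dgfs_norm > 0))
})

test_that("the depleted scenario only changes the initial starch", {
  cfg <- field_config(seed = 5)
  expect_equal(generate_depleted_scenario(cfg, 0), cfg)
  dep <- generate_depleted_scenario(cfg, 0.6)
  expect_equal(dep$init[["starch"]], 0.4 * cfg$init[["starch"]])
  expect_equal(dep$init[["gfs"]], cfg$init[["gfs"]])
  full <- generate_depleted_scenario(cfg, 1)
  expect_equal(full$init[["starch"]], 0)
  # with no starch, intermediate-variant hydrolysis is silent on day 1
  out <- carbon_step(c(gfs = full$init[["gfs"]], starch = 0), theta = 0,
                     wc = 0.8, ps = 0.5, cfg$true_params)
  expect_equal(out$state[["starch"]],
               catalytic_rate(0, 0.5, cfg$true_params$k2) *
                 full$init[["gfs"]],
               tolerance = 1e-12)
  w <- generate_weather(weather_config(seed = 5))
  a <- generate_field_dataset(w, cfg)
  b <- generate_field_dataset(w, dep)
  expect_identical(a$pheno, b$pheno)
  expect_false(isTRUE(all.equal(a$latent$starch, b$latent$starch)))
})
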