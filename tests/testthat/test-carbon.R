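zero_params <- function(variant) {
  km <- if (variant == "complete") 50 else NULL
  z <- function() reaction_params(0, 0, 0, mu = 5, sigma = 10, km = km)
  model_params(variant, k1c = z(), k1m = z(), k2 = z(),
               resp = respiration_params(0, -10, 0.8, 2))
}

test_that("water content interpolates linearly and holds outside the span", {
  d <- as.Date(c("2008-10-01", "2008-10-31"))
  expect_equal(interpolate_wc(d, c(0.8, 1.0), d[1]), 0.8)
  expect_equal(interpolate_wc(d, c(0.8, 1.0), d[2]), 1.0)
  expect_equal(interpolate_wc(d, c(0.8, 1.0), as.Date("2008-10-16")), 0.9)
  expect_warning(w0 <- interpolate_wc(d, c(0.8, 1.0),
                                      as.Date("2008-09-20")),
                 "extrapolated")
  expect_equal(w0, 0.8)
  expect_error(interpolate_wc(as.Date(character()), numeric(), d[1]),
               "no water-content")
})

test_that("model_params enforces the variant/km contract", {
  r <- function(km = NULL) reaction_params(1, 0, 0, mu = 0, sigma = 5,
                                           km = km)
  resp <- respiration_params(0.1, -10, 0.8, 2)
  expect_error(model_params("complete", r(), r(), r(), resp), "km")
  expect_error(model_params("intermediate", r(50), r(50), r(50), resp),
               "km")
  expect_identical(n_free_params(model_params("intermediate", r(), r(), r(),
                                              resp)), 19L)
  expect_identical(n_free_params(model_params("complete", r(50), r(50),
                                              r(50), resp)), 22L)
})

test_that("a step with no fluxes leaves the state unchanged", {
  for (variant in c("simple", "intermediate", "complete")) {
    out <- carbon_step(c(gfs = 30, starch = 80), theta = 5, wc = 0.8,
                       ps = 0.5, zero_params(variant))
    expect_equal(out$state, c(gfs = 30, starch = 80))
    expect_equal(out$respiration, 0)
    expect_false(out$floored)
  }
})

test_that("substrate limitation kills hydrolysis when starch is exhausted", {
  p <- default_true_params("intermediate")
  p$k2 <- reaction_params(0, 0, 0, mu = 13, sigma = 10)
  p$resp <- respiration_params(0, -10, 0.8, 2)
  out <- carbon_step(c(gfs = 40, starch = 0), theta = 0, wc = 0.8, ps = 0.9,
                     p)
  expect_equal(out$state, c(gfs = 40, starch = 0))
})

test_that("an interior step conserves NSC up to the respired amount", {
  p <- default_true_params("intermediate")
  st0 <- c(gfs = 40, starch = 60)
  out <- carbon_step(st0, theta = 3, wc = 0.75, ps = 0.8, p)
  expect_false(out$floored)
  expect_equal(sum(out$state) - sum(st0), -out$respiration)
})

test_that("flooring rescales outgoing fluxes instead of overdrawing pools", {
  p <- zero_params("intermediate")
  p$resp <- respiration_params(r_max = 50, a3 = -10, b3 = 0.8, q10 = 2)
  out <- carbon_step(c(gfs = 1, starch = 0), theta = 25, wc = 1.4, ps = 0.5,
                     p)
  expect_true(out$floored)
  expect_true(all(out$state >= 0))
  expect_equal(out$state[["gfs"]], 0)
  # realized respiration is capped at what the GFS pool could supply
  expect_equal(out$respiration, 1)
  expect_lt(out$respiration, respiration_rate(25, 1.4, p$resp))
})

test_that("NSC declines by exactly the realized respiration on every day", {
  w <- generate_weather(weather_config(seed = 7))
  for (variant in c("simple", "intermediate", "complete")) {
    cfg <- field_config(true_params = default_true_params(variant),
                        seed = 7)
    fd <- generate_field_dataset(w, cfg)
    lat <- fd$latent
    n <- nrow(lat) - 1L
    nsc <- lat$gfs + lat$starch
    resid <- diff(nsc) + lat$respiration[seq_len(n)]
    ok <- !lat$floored[seq_len(n)]
    expect_true(any(ok))
    expect_lt(max(abs(resid[ok])), 1e-10)
    expect_true(all(lat$gfs >= 0 & lat$starch >= 0))
  }
})

test_that("the complete variant collapses to the intermediate one for large Km", {
  km_big <- 1e6
  pi_ <- default_true_params("intermediate")
  scale_r <- function(rp) reaction_params(rp$k_trans * km_big,
                                          rp$d_endo * km_big,
                                          rp$d_eco * km_big,
                                          mu = rp$mu, sigma = rp$sigma,
                                          km = km_big)
  pc <- model_params("complete", k1c = scale_r(pi_$k1c),
                     k1m = scale_r(pi_$k1m), k2 = scale_r(pi_$k2),
                     resp = pi_$resp)
  w <- generate_weather(weather_config(seed = 3))
  fdi <- generate_field_dataset(w, field_config(true_params = pi_, seed = 3))
  fdc <- generate_field_dataset(w, field_config(true_params = pc, seed = 3))
  expect_equal(fdc$latent$gfs, fdi$latent$gfs, tolerance = 0.01)
  expect_equal(fdc$latent$starch, fdi$latent$starch, tolerance = 0.01)
})

test_that("simulation is deterministic and a one-day series gives two rows", {
  w1 <- data.frame(date = as.Date("2008-12-01"), tmean = -3)
  pheno <- data.frame(date = as.Date("2008-12-01"), ps = 0.8)
  wc_obs <- data.frame(date = as.Date("2008-12-01"), wc = 0.8)
  p <- default_true_params("intermediate")
  traj <- simulate_carbon(w1, wc_obs, pheno, c(gfs = 30, starch = 70), p)
  expect_identical(nrow(traj), 2L)
  manual <- carbon_step(c(gfs = 30, starch = 70), -3, 0.8, 0.8, p)
  expect_equal(traj$gfs[2], manual$state[["gfs"]])
  expect_equal(traj$starch[2], manual$state[["starch"]])
  traj2 <- simulate_carbon(w1, wc_obs, pheno, c(gfs = 30, starch = 70), p)
  expect_identical(traj, traj2)
})

test_that("a constant cold week matches repeated manual stepping", {
  days <- seq(as.Date("2009-01-10"), by = "day", length.out = 7)
  w <- data.frame(date = days, tmean = -3)
  pheno <- data.frame(date = days, ps = seq(0.9, 0.96, length.out = 7))
  wc_obs <- data.frame(date = range(days), wc = c(0.7, 0.7))
  p <- default_true_params("intermediate")
  traj <- simulate_carbon(w, wc_obs, pheno, c(gfs = 35, starch = 65), p)
  state <- c(gfs = 35, starch = 65)
  for (i in 1:7)
    state <- carbon_step(state, -3, 0.7, pheno$ps[i], p)$state
  expect_equal(traj$gfs[8], state[["gfs"]])
  expect_equal(traj$starch[8], state[["starch"]])
})

test_that("season-long NSC loss equals the summed realized respiration", {
  w <- generate_weather(weather_config(seed = 5))
  fd <- generate_field_dataset(w, field_config(seed = 5))
  lat <- fd$latent
  n <- nrow(lat)
  loss <- (lat$gfs[1] + lat$starch[1]) - (lat$gfs[n] + lat$starch[n])
  expect_equal(loss, sum(lat$respiration[-n]), tolerance = 1e-10)
})

test_that("disjoint weather and phenology windows are rejected", {
  w <- make_constant_weather(5, 10, start = as.Date("2010-01-01"))
  pheno <- data.frame(date = seq(as.Date("2012-01-01"), by = "day",
                                 length.out = 10), ps = 0)
  expect_error(simulate_carbon(w, data.frame(date = w$date[1], wc = 0.8),
                               pheno, c(gfs = 10, starch = 10),
                               default_true_params("intermediate")),
               "overlap")
})
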