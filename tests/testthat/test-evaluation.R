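test_that("efficiency behaves like Nash-Sutcliffe", {
  obs <- c(3, 7, 5, 9, 2)
  expect_equal(efficiency(obs, obs), 1)
  expect_equal(efficiency(obs, rep(mean(obs), 5)), 0)
  expect_equal(efficiency(c(0, 2), c(1, 1)), 0)
  expect_lt(efficiency(obs, rev(obs)), 1)
  expect_error(efficiency(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(efficiency(1:3, 1:4), "equal length")
})

test_that("rmse is the root mean squared residual", {
  expect_equal(rmse(c(1, -1), c(0, 0)), 1)
  expect_equal(rmse(c(5, 6), c(5, 6)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_error(rmse(numeric(), numeric()), "length")
})

test_that("rmse is zero exactly when efficiency is one", {
  set.seed(2)
  obs <- rnorm(20)
  sim <- obs + rnorm(20, 0, 0.1)
  expect_true(xor(rmse(obs, sim) == 0, efficiency(obs, sim) < 1))
  expect_true(rmse(obs, obs) == 0 && efficiency(obs, obs) == 1)
})

make_scan_weather <- function(n = 1200, seed = 99) {
  w <- generate_weather(weather_config(n_days = n, seed = seed))
  w
}

test_that("the scan recovers a planted 22-day integration window", {
  w <- make_scan_weather()
  dates <- seq(as.Date(w$date[40]), by = "15 days", length.out = 70)
  trail22 <- vapply(dates, function(d) {
    mean(w$tmax[match(seq(d - 21, d, by = 1), as.Date(w$date))])
  }, numeric(1))
  fh <- 1.2 * trail22 - 30          # exact linear function of the window
  scan <- window_correlation_scan(w, dates, fh, statistic = "max")
  best <- scan$best[scan$best$statistic == "max", ]
  expect_identical(best$window, 22L)
  expect_equal(abs(best$rho), 1, tolerance = 1e-12)
})

test_that("a zero-width window on the series itself correlates perfectly", {
  w <- make_scan_weather(400)
  dates <- as.Date(w$date[seq(10, 390, by = 10)])
  vals <- w$tmax[seq(10, 390, by = 10)]
  scan <- window_correlation_scan(w, dates, vals, statistic = "max",
                                  windows = 0:5)
  expect_equal(scan$table$rho[scan$table$window == 0], 1, tolerance = 1e-12)
})

test_that("the scan matches a brute-force recomputation and is affine-invariant", {
  w <- make_scan_weather(600, seed = 4)
  set.seed(4)
  dates <- as.Date(w$date[sort(sample(45:590, 25))])
  vals <- rnorm(25)
  scan <- window_correlation_scan(w, dates, vals, statistic = "mean",
                                  windows = c(0L, 5L, 13L, 30L))
  for (i in seq_len(nrow(scan$table))) {
    wdw <- scan$table$window[i]
    pred <- vapply(dates, function(d) {
      span <- if (wdw == 0) d else seq(d - wdw + 1, d, by = 1)
      mean(w$tmean[match(span, as.Date(w$date))])
    }, numeric(1))
    expect_equal(scan$table$rho[i], cor(pred, vals))
  }
  scan2 <- window_correlation_scan(w, dates, 3.5 * vals - 12,
                                   statistic = "mean",
                                   windows = c(0L, 5L, 13L, 30L))
  expect_equal(scan2$table$rho, scan$table$rho)
})

test_that("sampling dates without enough history are dropped with a warning", {
  w <- make_scan_weather(100)
  dates <- as.Date(w$date[c(5, 50, 90)])
  expect_warning(
    scan <- window_correlation_scan(w, dates, c(1, 5, 3),
                                    statistic = "max", windows = 10L),
    "dropped")
  expect_identical(scan$table$n, 2L)
})

test_that("three-Gaussian decomposition round-trips known components", {
  truth <- data.frame(amplitude = c(0.02, 0.012, 0.015),
                      mu = c(-1, 16, 11),
                      sigma = c(3, 4, 2.5))
  temps <- seq(-6, 26, by = 1)
  g <- function(x, m, s) exp(-(x - m)^2 / (2 * s^2))
  resp <- truth$amplitude[1] * g(temps, truth$mu[1], truth$sigma[1]) +
    truth$amplitude[2] * g(temps, truth$mu[2], truth$sigma[2]) -
    truth$amplitude[3] * g(temps, truth$mu[3], truth$sigma[3])
  fit <- fit_three_gaussian_response(temps, resp, n_starts = 80, seed = 2)
  expect_lt(fit$rmse, 1e-6)
  expect_equal(fit$components$amplitude, truth$amplitude, tolerance = 1e-4)
  expect_equal(fit$components$mu, truth$mu, tolerance = 1e-4)
  expect_equal(abs(fit$components$sigma), truth$sigma, tolerance = 1e-4)
})

test_that("degenerate response curves are handled", {
  expect_error(fit_three_gaussian_response(c(-3, 1, 5, 10, 15, 20),
                                           rep(0.1, 6)), "at least 7")
  fit0 <- fit_three_gaussian_response(c(-3, 1, 5, 10, 15, 20, 25),
                                      rep(0, 7))
  expect_equal(fit0$components$amplitude, rep(0, 3))
  expect_equal(fit0$rmse, 0)
})

test_that("metric reports label calibration RMSE and validation RMSEP", {
  world <- make_noiseless_world()
  p <- world$field$config$true_params
  rep_cal <- metric_report(p, world$data, role = "calibration")
  expect_identical(rep_cal$metric, c("RMSE", "RMSE"))
  expect_equal(rep_cal$rmse, c(0, 0), tolerance = 1e-10)
  expect_equal(rep_cal$eff, c(1, 1), tolerance = 1e-10)
  rep_val <- metric_report(p, world$data, role = "validation")
  expect_identical(rep_val$metric, c("RMSEP", "RMSEP"))
})
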