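#' Nash-Sutcliffe model efficiency
#'
#' `Eff = (SS_tot - SS_res) / SS_tot`, with `SS_tot` taken about the observed
#' mean. 1 means a perfect fit, 0 no better than the observed mean, negative
#' worse than the mean.
#'
#' @param observed,simulated Numeric vectors of equal length (>= 2).
#' @return Scalar efficiency (<= 1).
#' @export
efficiency <- function(observed, simulated) {
  if (length(observed) != length(simulated) || length(observed) < 2L)
    stop("observed and simulated must have equal length >= 2", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("efficiency undefined: observed values have zero variance",
         call. = FALSE)
  (ss_tot - sum((observed - simulated)^2)) / ss_tot
}

#' Root mean square error
#'
#' @param observed,simulated Numeric vectors of equal length (>= 1).
#' @return `sqrt(mean((observed - simulated)^2))`, in the variable's units.
#' @export
rmse <- function(observed, simulated) {
  if (length(observed) != length(simulated) || length(observed) < 1L)
    stop("observed and simulated must have equal length >= 1", call. = FALSE)
  sqrt(mean((observed - simulated)^2))
}

#' Sliding-window correlation between temperature and a physiological series
#'
#' For each window width `w` in `windows` and each requested daily statistic
#' (minimum, mean or maximum temperature), averages the statistic over the
#' `w` days up to and including each sampling date (`w = 0` is the
#' sampling-day value alone) and computes Pearson's product-moment
#' correlation with the physiological values. Physiological variables in
#' walnut branches (frost hardiness, sugar and water contents) respond to
#' temperature integrated over two to four weeks, which this scan localises.
#'
#' @param weather Daily weather data frame with `date`, `tmin`, `tmax` and
#'   optionally `tmean`.
#' @param obs_dates Sampling dates of the physiological variable.
#' @param obs_values Physiological values, same length.
#' @param statistic Character vector among `"min"`, `"mean"`, `"max"`.
#' @param windows Integer window widths in days (default 0 to 30).
#' @return A list of class `window_scan`: `table` (columns `statistic`,
#'   `window`, `n`, `rho`, `p_value`) and `best` (the row maximising `|rho|`
#'   per statistic).
#' @export
window_correlation_scan <- function(weather, obs_dates, obs_values,
                                    statistic = c("min", "mean", "max"),
                                    windows = 0:30) {
  statistic <- match.arg(statistic, several.ok = TRUE)
  stopifnot(length(obs_dates) == length(obs_values))
  wdates <- as.Date(weather$date)
  obs_dates <- as.Date(obs_dates)
  series <- list(min = weather$tmin,
                 mean = tryCatch(daily_mean_temperature(weather),
                                 error = function(e) NULL),
                 max = weather$tmax)
  rows <- list()
  for (st in statistic) {
    x <- series[[st]]
    if (is.null(x))
      stop("weather lacks the columns for statistic '", st, "'",
           call. = FALSE)
    for (w in windows) {
      pred <- vapply(obs_dates, function(d) {
        span <- if (w == 0L) d else seq(d - w + 1L, d, by = 1L)
        idx <- match(span, wdates)
        if (anyNA(idx)) NA_real_ else mean(x[idx])
      }, numeric(1))
      ok <- is.finite(pred) & is.finite(obs_values)
      if (sum(!ok))
        warning(sum(!ok), " sampling date(s) dropped for window ", w,
                " (insufficient weather history)", call. = FALSE)
      if (sum(ok) >= 3L && stats::sd(pred[ok]) > 0 &&
          stats::sd(obs_values[ok]) > 0) {
        ct <- stats::cor.test(pred[ok], obs_values[ok], method = "pearson")
        rows[[length(rows) + 1L]] <-
          data.frame(statistic = st, window = w, n = sum(ok),
                     rho = unname(ct$estimate), p_value = ct$p.value)
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(statistic = st, window = w, n = sum(ok),
                     rho = NA_real_, p_value = NA_real_)
      }
    }
  }
  tab <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(tab, tab$statistic), function(d) {
    d <- d[is.finite(d$rho), , drop = FALSE]
    if (!nrow(d)) return(NULL)
    d[which.max(abs(d$rho)), , drop = FALSE]
  }))
  rownames(best) <- NULL
  structure(list(table = tab, best = best), class = "window_scan")
}

gauss_bump <- function(theta, mu, sigma) exp(-(theta - mu)^2 / (2 * sigma^2))

#' Decompose a temperature-response curve into three Gaussian components
#'
#' Fits the normalised response (e.g. daily change in GFS divided by initial
#' starch) measured across constant-temperature treatments as the
#' superposition of two positive Gaussian components (cold- and mild-optimum
#' hydrolysis) and one negative component (re-synthesis):
#' `r(theta) = A1c g(theta; mu1c, s1c) + A1m g(theta; mu1m, s1m)
#'  - A2 g(theta; mu2, s2)`, with all amplitudes constrained nonnegative.
#' The fit is nonlinear least squares restarted from a Latin hypercube of
#' initial component placements, keeping the best solution.
#'
#' @param temps Treatment temperatures (deg C); at least 7 distinct values.
#' @param response Normalised response, same length (per day).
#' @param n_starts Number of random multistart initialisations.
#' @param seed Integer seed for the starts.
#' @return A list of class `gaussian_decomposition`: `components` (data
#'   frame with `component`, `amplitude`, `mu`, `sigma`), `rmse`,
#'   `fitted`, `converged`.
#' @export
fit_three_gaussian_response <- function(temps, response, n_starts = 60L,
                                        seed = 1L) {
  stopifnot(length(temps) == length(response))
  if (length(unique(temps)) < 7L)
    stop("need at least 7 distinct treatment temperatures", call. = FALSE)
  comp_names <- c("cold_hydrolysis", "mild_hydrolysis", "resynthesis")
  if (all(response == 0)) {
    components <- data.frame(component = comp_names, amplitude = 0,
                             mu = NA_real_, sigma = NA_real_)
    return(structure(list(components = components, rmse = 0,
                          fitted = rep(0, length(temps)), converged = TRUE),
                     class = "gaussian_decomposition"))
  }
  dat <- data.frame(x = temps, y = response)
  amp <- max(abs(response))
  rng <- range(temps)
  span <- diff(rng)
  start_bounds <- data.frame(
    name = c("a1", "m1", "s1", "a2", "m2", "s2", "a3", "m3", "s3"),
    lower = c(0, rng[1], span / 20, 0, rng[1], span / 20, 0, rng[1],
              span / 20),
    upper = c(2 * amp, rng[2], span, 2 * amp, rng[2], span, 2 * amp, rng[2],
              span))
  starts <- lhs_starts(start_bounds, n_starts, seed)
  lower <- c(a1 = 0, m1 = rng[1] - span, s1 = 1e-3,
             a2 = 0, m2 = rng[1] - span, s2 = 1e-3,
             a3 = 0, m3 = rng[1] - span, s3 = 1e-3)
  upper <- c(a1 = Inf, m1 = rng[2] + span, s1 = 10 * span,
             a2 = Inf, m2 = rng[2] + span, s2 = 10 * span,
             a3 = Inf, m3 = rng[2] + span, s3 = 10 * span)
  best <- NULL; best_rss <- Inf
  for (s in seq_len(n_starts)) {
    st <- as.list(starts[s, ])
    # keep the two positive bumps ordered cold < mild at the start
    if (st$m1 > st$m2) { tmp <- st$m1; st$m1 <- st$m2; st$m2 <- tmp }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * gauss_bump(x, m1, s1) + a2 * gauss_bump(x, m2, s2) -
          a3 * gauss_bump(x, m3, s3),
        data = dat, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) { best_rss <- rss; best <- fit }
    }
  }
  if (is.null(best))
    stop("three-Gaussian decomposition did not converge from any start",
         call. = FALSE)
  cf <- stats::coef(best)
  # order the two positive components by optimum temperature
  pos <- if (cf[["m1"]] <= cf[["m2"]]) c(1L, 2L) else c(2L, 1L)
  idx <- function(k, what) cf[[paste0(what, k)]]
  components <- data.frame(
    component = comp_names,
    amplitude = c(idx(pos[1L], "a"), idx(pos[2L], "a"), cf[["a3"]]),
    mu = c(idx(pos[1L], "m"), idx(pos[2L], "m"), cf[["m3"]]),
    sigma = c(idx(pos[1L], "s"), idx(pos[2L], "s"), cf[["s3"]]))
  structure(list(components = components,
                 rmse = sqrt(best_rss / length(temps)),
                 fitted = stats::fitted(best),
                 converged = TRUE),
            class = "gaussian_decomposition")
}
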