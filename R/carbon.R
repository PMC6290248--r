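#' Full parameter set of the carbon-metabolism model
#'
#' Bundles the three reactions and the respiration term, tagged with the
#' model variant that fixes the functional form of the daily update:
#' \describe{
#'   \item{simple}{zero-order: hydrolysis `H = k1c + k1m`, re-synthesis
#'     `S = k2` (rates in mg g DM^-1 day^-1).}
#'   \item{intermediate}{substrate-limited first order:
#'     `H = (k1c + k1m) * Starch`, `S = k2 * GFS` (rates in day^-1).}
#'   \item{complete}{Michaelis-Menten:
#'     `H = (v1c/(km1c + Starch) + v1m/(km1m + Starch)) * Starch`,
#'     `S = v2/(km2 + GFS) * GFS`, where each `v` follows the same
#'     temperature-by-stage law as the `k`s.}
#' }
#' GFS is updated as `GFS(t+1) = GFS(t) + H - S - R` and starch closes the
#' balance, `Starch(t+1) = Starch(t) - dGFS - R`, so that total NSC declines
#' by exactly the respired amount each day.
#'
#' @param variant One of `"simple"`, `"intermediate"`, `"complete"`.
#' @param k1c,k1m,k2 [reaction_params()] for cold hydrolysis, mild hydrolysis
#'   and re-synthesis. The complete variant requires `km` on all three; the
#'   other variants forbid it.
#' @param resp A [respiration_params()] object.
#' @return An object of class `model_params`.
#' @export
model_params <- function(variant = c("simple", "intermediate", "complete"),
                         k1c, k1m, k2, resp) {
  variant <- match.arg(variant)
  for (rp in list(k1c, k1m, k2))
    stopifnot(inherits(rp, "reaction_params"))
  stopifnot(inherits(resp, "respiration_params"))
  has_km <- !vapply(list(k1c, k1m, k2), function(r) is.null(r$km), logical(1))
  if (variant == "complete" && !all(has_km))
    stop("complete variant requires km on all three reactions", call. = FALSE)
  if (variant != "complete" && any(has_km))
    stop(variant, " variant does not use km; drop it", call. = FALSE)
  structure(list(variant = variant, k1c = k1c, k1m = k1m, k2 = k2,
                 resp = resp),
            class = "model_params")
}

#' Number of free parameters of a model variant
#'
#' 19 for the simple and intermediate variants (3 reactions x 5 + 4
#' respiration parameters), 22 for the complete variant (3 extra `km`).
#'
#' @param params A [model_params()] object.
#' @return Integer count.
#' @export
n_free_params <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$variant == "complete") 22L else 19L
}

#' Interpolate water content between sampling dates
#'
#' Piecewise-linear interpolation through the observed water contents,
#' holding the nearest observed value (with a warning) outside the observed
#' span, as branch water content is treated as a measured input.
#'
#' @param obs_dates Dates of the water-content observations.
#' @param obs_wc Observed water contents (g g^-1), same length.
#' @param day Date(s) at which to evaluate.
#' @return Interpolated water content(s).
#' @export
interpolate_wc <- function(obs_dates, obs_wc, day) {
  obs_dates <- as.Date(obs_dates)
  day <- as.Date(day)
  if (length(obs_dates) == 0L) stop("no water-content observations", call. = FALSE)
  stopifnot(length(obs_dates) == length(obs_wc))
  o <- order(obs_dates)
  obs_dates <- obs_dates[o]; obs_wc <- obs_wc[o]
  if (any(day < obs_dates[1L] | day > obs_dates[length(obs_dates)]))
    warning("water content extrapolated by holding the nearest observation",
            call. = FALSE)
  if (length(obs_dates) == 1L) return(rep(obs_wc, length(day)))
  stats::approx(as.numeric(obs_dates), obs_wc, xout = as.numeric(day),
                method = "linear", rule = 2)$y
}

# Tight state loop shared by carbon_step / simulate_carbon / the calibration
# objective. theta, wc, ps are day vectors (length n); returns pools of
# length n + 1 plus realized respiration and flooring flags of length n.
# The catalytic and respiration rates depend only on the (precomputable)
# forcing, so the per-day work is a handful of scalar operations; the
# variant dispatch happens once, outside the loop, to keep repeated
# objective evaluations cheap.
simulate_core <- function(theta, wc, ps, init_gfs, init_starch, params) {
  n <- length(theta)
  r1c <- catalytic_rate(theta, ps, params$k1c)
  r1m <- catalytic_rate(theta, ps, params$k1m)
  r2 <- catalytic_rate(theta, ps, params$k2)
  rr <- respiration_rate(theta, wc, params$resp)
  rhyd <- r1c + r1m
  km1c <- params$k1c$km; km1m <- params$k1m$km; km2 <- params$k2$km
  vcode <- match(params$variant, c("simple", "intermediate", "complete"))
  if (is.na(vcode))
    stop("unknown model variant: ", params$variant, call. = FALSE)

  gfs <- starch <- numeric(n + 1L)
  resp <- numeric(n)
  floored <- logical(n)
  gfs[1L] <- init_gfs; starch[1L] <- init_starch
  for (t in seq_len(n)) {
    g <- gfs[t]; st <- starch[t]
    if (vcode == 2L) {
      h <- rhyd[t] * st; s <- r2[t] * g
    } else if (vcode == 1L) {
      h <- rhyd[t]; s <- r2[t]
    } else {
      h <- (r1c[t] / (km1c + st) + r1m[t] / (km1m + st)) * st
      s <- r2[t] / (km2 + g) * g
    }
    r <- rr[t]
    fday <- FALSE
    if (h > st) { h <- st; fday <- TRUE }           # starch cannot overdraw
    out <- s + r
    avail <- g + h
    if (out > avail) {                               # GFS cannot overdraw
      f <- if (out > 0) avail / out else 0
      s <- s * f; r <- r * f
      fday <- TRUE
    }
    gfs[t + 1L] <- max(0, g + h - s - r)
    starch[t + 1L] <- max(0, st - h + s)
    resp[t] <- r
    floored[t] <- fday
  }
  list(gfs = gfs, starch = starch, respiration = resp, floored = floored)
}

#' Advance the carbon state by one day
#'
#' Applies the daily update of the selected model variant to a single state,
#' returning the new state, the respiration actually realized (after any
#' pool-exhaustion flooring), and whether flooring occurred. When a pool
#' would go negative, its outgoing fluxes are rescaled by the ratio of
#' available to demanded carbon, preserving the mass balance.
#'
#' @param state Named numeric or list with `gfs` and `starch`
#'   (mg g DM^-1), both nonnegative.
#' @param theta Daily mean temperature (deg C).
#' @param wc Water content (g g^-1).
#' @param ps Phenological stage in `[0, 2]`.
#' @param params A [model_params()] object.
#' @return List with `state` (gfs, starch), `respiration`, `floored`.
#' @export
carbon_step <- function(state, theta, wc, ps, params) {
  stopifnot(inherits(params, "model_params"))
  g <- state[["gfs"]]; st <- state[["starch"]]
  if (g < 0 || st < 0) stop("pools must be nonnegative", call. = FALSE)
  out <- simulate_core(theta, wc, ps, g, st, params)
  list(state = c(gfs = out$gfs[2L], starch = out$starch[2L]),
       respiration = out$respiration[1L], floored = out$floored[1L])
}

#' Simulate the daily GFS/starch trajectory over the leafless period
#'
#' Runs the daily update from an initial measured state over the window where
#' the weather and phenology series overlap, with water content linearly
#' interpolated between observations. Each day of the window drives one step,
#' so the trajectory has one more row than there are days; the first row
#' equals the initial state exactly, and each row's `respiration` and
#' `floored` describe the step taken from that day to the next (NA on the
#' final row, which carries the state the morning after the last driven day).
#'
#' @param weather Daily weather data frame (`date` + temperature columns).
#' @param wc_obs Data frame with `date` and `wc` observations.
#' @param pheno A `phenology_series` from [accumulate_phenology()].
#' @param init Named numeric or list with initial `gfs` and `starch`
#'   (mg g DM^-1), measured on the first simulated day.
#' @param params A [model_params()] object.
#' @return A data frame (`carbon_trajectory`) with columns `date`, `theta`,
#'   `wc`, `ps`, `gfs`, `starch`, `respiration`, `floored`; one more row than
#'   simulated days.
#' @export
simulate_carbon <- function(weather, wc_obs, pheno, init, params) {
  stopifnot(inherits(params, "model_params"))
  wdates <- as.Date(weather$date)
  pdates <- as.Date(pheno$date)
  common <- as.Date(intersect(wdates, pdates), origin = "1970-01-01")
  if (length(common) == 0L)
    stop("weather and phenology series do not overlap", call. = FALSE)
  common <- sort(common)
  if (any(diff(as.integer(common)) != 1L))
    stop("weather/phenology overlap is not a contiguous daily window",
         call. = FALSE)
  theta <- daily_mean_temperature(weather)[match(common, wdates)]
  ps <- pheno$ps[match(common, pdates)]
  wc <- interpolate_wc(wc_obs$date, wc_obs$wc, common)

  n <- length(common)   # each day drives one step
  core <- simulate_core(theta, wc, ps, init[["gfs"]], init[["starch"]], params)
  out <- data.frame(date = c(common, common[n] + 1L),
                    theta = c(theta, NA_real_),
                    wc = c(wc, wc[n]),
                    ps = c(ps, ps[n]),
                    gfs = core$gfs, starch = core$starch,
                    respiration = c(core$respiration, NA_real_),
                    floored = c(core$floored, NA))
  class(out) <- c("carbon_trajectory", "data.frame")
  out
}
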