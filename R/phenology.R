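#' Parameters of the sequential dormancy (chilling/forcing) model
#'
#' Constants of the two-phase phenology model for walnut: endodormancy is
#' released by accumulated chilling units (CU, inverse-Richardson function of
#' daily mean temperature), after which ecodormancy is released by accumulated
#' forcing units (FU, temperature sigmoid). Defaults are the published
#' literature values for *Juglans regia* cv. Franquette.
#'
#' @param start_doy Day of year on which chilling accumulation starts
#'   (beginning of endodormancy).
#' @param t_low Temperature (deg C) below which the daily chilling effect is
#'   maximal (plateau).
#' @param t_high Temperature (deg C) above which the daily chilling effect is
#'   zero.
#' @param cu_crit Chilling units required to complete endodormancy.
#' @param slp Slope (per deg C) of the forcing sigmoid at its midpoint;
#'   positive, so forcing increases with temperature.
#' @param t50 Temperature (deg C) giving half the maximal daily forcing unit.
#' @param fu_crit Forcing units required to complete ecodormancy (budburst).
#'
#' @return An object of class `phenology_params`.
#' @export
#' @examples
#' p <- phenology_params()
#' chilling_increment(3.1, p)  # plateau value t_high - t_low
phenology_params <- function(start_doy = 244,
                             t_low = 3.1,
                             t_high = 26.7,
                             cu_crit = 2298.8,
                             slp = 0.244,
                             t50 = 13.46,
                             fu_crit = 21.2) {
  stopifnot(is.numeric(start_doy), length(start_doy) == 1L,
            start_doy >= 1, start_doy <= 366)
  if (!(t_low < t_high)) stop("t_low must be below t_high", call. = FALSE)
  if (cu_crit <= 0) stop("cu_crit must be positive", call. = FALSE)
  if (fu_crit <= 0) stop("fu_crit must be positive", call. = FALSE)
  if (slp <= 0) stop("slp must be positive", call. = FALSE)
  structure(list(start_doy = as.integer(start_doy), t_low = t_low,
                 t_high = t_high, cu_crit = cu_crit, slp = slp,
                 t50 = t50, fu_crit = fu_crit),
            class = "phenology_params")
}

#' Daily chilling increment
#'
#' Inverse-Richardson chilling function: zero above `t_high`, increasing
#' linearly as temperature drops, and saturating at `t_high - t_low` below
#' `t_low`.
#'
#' @param theta Daily mean air temperature (deg C); vectorised.
#' @param params A [phenology_params()] object.
#' @return Chilling units per day, in `[0, t_high - t_low]`.
#' @export
chilling_increment <- function(theta, params = phenology_params()) {
  stopifnot(inherits(params, "phenology_params"))
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("theta must be finite numeric", call. = FALSE)
  pmax(pmin(params$t_high - theta, params$t_high - params$t_low), 0)
}

#' Daily forcing increment
#'
#' Sigmoid forcing function of daily mean temperature: 1/2 at `t50`,
#' saturating at one daily forcing unit for warm days.
#'
#' @inheritParams chilling_increment
#' @return Forcing units per day, in (0, 1).
#' @export
forcing_increment <- function(theta, params = phenology_params()) {
  stopifnot(inherits(params, "phenology_params"))
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("theta must be finite numeric", call. = FALSE)
  1 / (1 + exp(-params$slp * (theta - params$t50)))
}

#' Daily mean temperature from a weather table
#'
#' Uses the `tmean` column when present and complete; otherwise falls back to
#' `(tmin + tmax) / 2` with a message.
#'
#' @param weather Data frame with columns `date`, `tmin`, `tmax` and
#'   optionally `tmean`.
#' @return Numeric vector of daily mean temperatures (deg C).
#' @export
daily_mean_temperature <- function(weather) {
  if (!is.null(weather$tmean) && !anyNA(weather$tmean))
    return(as.numeric(weather$tmean))
  if (is.null(weather$tmin) || is.null(weather$tmax))
    stop("weather needs either a complete tmean column or tmin and tmax",
         call. = FALSE)
  message("daily mean temperature computed as (tmin + tmax) / 2")
  (as.numeric(weather$tmin) + as.numeric(weather$tmax)) / 2
}

#' Accumulate chilling, forcing and the phenological stage index
#'
#' Runs the sequential dormancy model over a daily weather series. Chilling
#' starts at zero on the first day whose day-of-year equals
#' `params$start_doy`; forcing accumulates only once cumulative chilling has
#' reached `cu_crit` (sequential endo -> eco transition). The stage index is
#' `PS = min(CU/cu_crit, 1) + min(FU/fu_crit, 1)`, ranging 0 (endodormancy
#' onset) to 2 (budburst). The raw, uncapped CU is kept in the output for
#' diagnostics; only the PS formula caps it.
#'
#' @param weather Data frame with `date` (Date or ISO-8601 string, strictly
#'   increasing, daily step) and temperature columns (see
#'   [daily_mean_temperature()]).
#' @param params A [phenology_params()] object.
#' @param stop_at_budburst If `TRUE` (default) the series is truncated at the
#'   first day reaching PS = 2.
#' @return A data frame (`phenology_series`) with columns `date`, `theta`,
#'   `cu`, `fu`, `ps`, starting on the `start_doy` day.
#' @export
#' @examples
#' w <- data.frame(date = seq(as.Date("2008-08-25"), by = "day", length.out = 200),
#'                 tmean = 3.1)
#' ph <- accumulate_phenology(w, stop_at_budburst = FALSE)
#' head(ph)
accumulate_phenology <- function(weather, params = phenology_params(),
                                 stop_at_budburst = TRUE) {
  stopifnot(inherits(params, "phenology_params"))
  dates <- as.Date(weather$date)
  if (anyNA(dates)) stop("unparseable dates in weather", call. = FALSE)
  if (length(dates) < 1L) stop("empty weather series", call. = FALSE)
  dd <- diff(as.integer(dates))
  if (any(dd != 1L))
    stop("weather dates must be strictly increasing with a daily step ",
         "(gap or duplicate near row ", which(dd != 1L)[1L] + 1L, ")",
         call. = FALSE)
  theta <- daily_mean_temperature(weather)
  doy <- as.integer(format(dates, "%j"))
  i0 <- which(doy == params$start_doy)[1L]
  if (is.na(i0))
    stop("weather does not cover the accumulation start day (DOY ",
         params$start_doy, "); series starting after it is not usable",
         call. = FALSE)

  n <- length(dates) - i0 + 1L
  th <- theta[i0:length(dates)]
  cu <- fu <- numeric(n)
  cinc <- chilling_increment(th, params)
  finc <- forcing_increment(th, params)
  for (t in seq_len(n - 1L)) {
    cu[t + 1L] <- cu[t] + cinc[t]
    fu[t + 1L] <- if (cu[t] >= params$cu_crit) fu[t] + finc[t] else 0
  }
  ps <- pmin(cu / params$cu_crit, 1) + pmin(fu / params$fu_crit, 1)
  out <- data.frame(date = dates[i0:length(dates)], theta = th,
                    cu = cu, fu = fu, ps = ps)
  if (stop_at_budburst) {
    hit <- which(ps >= 2)[1L]
    if (!is.na(hit)) out <- out[seq_len(hit), , drop = FALSE]
  }
  class(out) <- c("phenology_series", "data.frame")
  out
}
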