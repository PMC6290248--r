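#' Coefficients of the osmo-hydric frost-hardiness relation
#'
#' Frost hardiness (FH, deg C; the highest temperature inducing frost damage,
#' typically negative, lower = hardier) is predicted from the ratio of
#' osmotically active sugars to tissue water:
#' `FH = a * ln(GFS) / WC + b`. Defaults are the coefficients calibrated on
#' measured walnut branch data.
#'
#' @param a Slope (deg C per unit ln(GFS)/WC); expected negative.
#' @param b Intercept (deg C).
#' @return An object of class `fh_params`.
#' @export
fh_params <- function(a = -5.32, b = 1.71) {
  structure(list(a = a, b = b), class = "fh_params")
}

#' Predict frost hardiness from GFS and water content
#'
#' @param gfs Soluble sugar content (mg g DM^-1); > 0, vectorised.
#' @param wc Water content (g g^-1); > 0, vectorised.
#' @param params An [fh_params()] object.
#' @return Predicted frost hardiness (deg C).
#' @export
#' @examples
#' predict_fh(100, 1.0)  # about -22.8 deg C with the default coefficients
predict_fh <- function(gfs, wc, params = fh_params()) {
  stopifnot(inherits(params, "fh_params"))
  if (any(gfs <= 0)) stop("gfs must be strictly positive", call. = FALSE)
  if (any(wc <= 0)) stop("wc must be strictly positive", call. = FALSE)
  params$a * log(gfs) / wc + params$b
}

#' Calibrate the osmo-hydric coefficients by least squares
#'
#' Ordinary least-squares regression of measured frost hardiness on
#' `x = ln(GFS) / WC`; the slope is `a` and the intercept `b`.
#'
#' @param fh Measured frost hardiness (deg C).
#' @param gfs Measured GFS (mg g DM^-1); > 0.
#' @param wc Measured water content (g g^-1); > 0.
#' @return A list of class `fh_fit`: `params` ([fh_params()]), `r_squared`,
#'   `rmse` (residual, deg C), `n`.
#' @export
calibrate_fh <- function(fh, gfs, wc) {
  ok <- is.finite(fh) & is.finite(gfs) & is.finite(wc)
  fh <- fh[ok]; gfs <- gfs[ok]; wc <- wc[ok]
  if (length(fh) < 3L)
    stop("need at least 3 valid (fh, gfs, wc) triples", call. = FALSE)
  if (any(gfs <= 0) || any(wc <= 0))
    stop("gfs and wc must be strictly positive", call. = FALSE)
  x <- log(gfs) / wc
  if (stats::var(x) == 0)
    stop("degenerate design: ln(gfs)/wc is constant", call. = FALSE)
  fit <- stats::lm(fh ~ x)
  res <- stats::residuals(fit)
  ss_tot <- sum((fh - mean(fh))^2)
  structure(list(params = fh_params(a = unname(stats::coef(fit)[2L]),
                                    b = unname(stats::coef(fit)[1L])),
                 r_squared = 1 - sum(res^2) / ss_tot,
                 rmse = sqrt(mean(res^2)),
                 n = length(fh)),
            class = "fh_fit")
}
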