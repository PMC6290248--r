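#' Parameters of one catalytic reaction
#'
#' Each of the three reactions (cold-optimum starch hydrolysis `k1c`,
#' mild-optimum hydrolysis `k1m`, starch re-synthesis `k2`) follows the same
#' rate law: a Gaussian temperature response times a piecewise-linear function
#' of the phenological stage. The stage dependence is parameterised by the
#' rate at the endo/eco transition (`k_trans`) and the slope differences
#' `d_endo`, `d_eco`, which guarantees continuity of the rate at PS = 1.
#'
#' Units of `k_trans` (and of the `d`s) depend on the model variant:
#' mg g DM^-1 day^-1 for the zero-order (simple) variant, day^-1 for the
#' substrate-limited (intermediate) variant, and mg g DM^-1 day^-1 as a
#' maximal velocity `v_max` for the Michaelis-Menten (complete) variant, which
#' additionally needs the half-saturation constant `km` (mg g DM^-1).
#'
#' @param k_trans Catalytic rate at the endo->eco transition (PS = 1); >= 0.
#' @param d_endo,d_eco Difference a - b between the stage-slope coefficients
#'   in the endo- and ecodormancy branches.
#' @param mu Optimal temperature (deg C) of the reaction.
#' @param sigma Width parameter of the Gaussian temperature response; the
#'   exponent is -(theta - mu)^2 / (sigma * 2 * pi), so sigma is a free width
#'   on a 2*pi-scaled square-degree scale; > 0.
#' @param km Optional Michaelis constant (mg g DM^-1), required by the
#'   complete variant only; > 0.
#' @return An object of class `reaction_params`.
#' @export
reaction_params <- function(k_trans, d_endo = 0, d_eco = 0, mu, sigma,
                            km = NULL) {
  if (k_trans < 0) stop("k_trans must be nonnegative", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (!is.null(km) && km <= 0) stop("km must be positive", call. = FALSE)
  structure(list(k_trans = k_trans, d_endo = d_endo, d_eco = d_eco,
                 mu = mu, sigma = sigma, km = km),
            class = "reaction_params")
}

#' Stage-slope coefficients (a, b) of a reaction at a given stage
#'
#' Returns the coefficients of the linear stage term `a * PS + b`. The
#' endodormancy branch (PS < 1) uses `a = (k_trans + d_endo)/2`,
#' `b = (k_trans - d_endo)/2`; the ecodormancy branch (PS >= 1) the same with
#' `d_eco`. In both branches `a + b = k_trans`, so the rate is continuous at
#' the transition by construction.
#'
#' @param rp A [reaction_params()] object.
#' @param ps Phenological stage index in `[0, 2]`; vectorised.
#' @return A list with numeric components `a` and `b` (same length as `ps`).
#' @export
stage_coefficients <- function(rp, ps) {
  stopifnot(inherits(rp, "reaction_params"))
  if (any(ps < 0 | ps > 2)) stop("ps must lie in [0, 2]", call. = FALSE)
  eco <- ps >= 1
  d <- rep.int(rp$d_endo, length(ps))
  d[eco] <- rp$d_eco
  list(a = (rp$k_trans + d) / 2, b = (rp$k_trans - d) / 2)
}

#' Catalytic rate as a function of temperature and phenological stage
#'
#' Rate law `max(0, (a*PS + b) * exp(-(theta - mu)^2 / (sigma * 2 * pi)))`:
#' a symmetric Gaussian temperature response (optimal at `mu`) modulated
#' linearly by the phenological stage, clamped at zero.
#'
#' @param theta Daily mean temperature (deg C); vectorised.
#' @param ps Phenological stage in `[0, 2]`; vectorised (recycled with
#'   `theta`).
#' @param rp A [reaction_params()] object.
#' @return Nonnegative rate, in the units of `k_trans`.
#' @export
catalytic_rate <- function(theta, ps, rp) {
  cf <- stage_coefficients(rp, ps)
  if (any(!is.finite(theta))) stop("theta must be finite", call. = FALSE)
  pmax(0, (cf$a * ps + cf$b) * exp(-(theta - rp$mu)^2 / (rp$sigma * 2 * pi)))
}

#' Parameters of maintenance respiration
#'
#' Respiration is zero-order in substrate: a logistic function of tissue
#' water content times a Q10 temperature factor referenced to `t_ref`.
#' With `a3 < 0` respiration increases with water content, matching the
#' observation that well-hydrated branches lose carbon faster in the warm.
#'
#' @param r_max Maximal respiration rate at `t_ref` (mg g DM^-1 day^-1); >= 0.
#' @param a3 Water-content sensitivity ((g g^-1)^-1); negative values make
#'   respiration increase with water content.
#' @param b3 Water content at which the logistic term is 1/2 (g g^-1).
#' @param q10 Temperature coefficient (rate multiplier per 10 K); > 0.
#' @param t_ref Reference temperature (deg C), 15 by convention.
#' @return An object of class `respiration_params`.
#' @export
respiration_params <- function(r_max, a3, b3, q10, t_ref = 15) {
  if (r_max < 0) stop("r_max must be nonnegative", call. = FALSE)
  if (q10 <= 0) stop("q10 must be positive", call. = FALSE)
  structure(list(r_max = r_max, a3 = a3, b3 = b3, q10 = q10, t_ref = t_ref),
            class = "respiration_params")
}

#' Daily respiration rate
#'
#' `R = r_max / (1 + exp(a3 * (wc - b3))) * q10^((theta - t_ref) / 10)`.
#'
#' @param theta Daily mean temperature (deg C); vectorised.
#' @param wc Water content (g water per g dry matter); >= 0, vectorised.
#' @param rparams A [respiration_params()] object.
#' @return Respiration in mg g DM^-1 day^-1.
#' @export
respiration_rate <- function(theta, wc, rparams) {
  stopifnot(inherits(rparams, "respiration_params"))
  if (any(wc < 0)) stop("wc must be nonnegative", call. = FALSE)
  rparams$r_max / (1 + exp(rparams$a3 * (wc - rparams$b3))) *
    rparams$q10^((theta - rparams$t_ref) / 10)
}
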