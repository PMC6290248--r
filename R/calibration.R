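#' Default calibration bounds for the free parameters
#'
#' Box bounds for the 19 (simple, intermediate) or 22 (complete) free
#' parameters, anchored on the biology: optimal temperatures near 0 deg C
#' (cold hydrolysis), 15-19 deg C (mild hydrolysis) and 12-14.5 deg C
#' (re-synthesis); Q10 between 1 and 4; respiration increasing with water
#' content (a3 <= 0). Rate magnitudes are scaled per variant because the
#' units of `k_trans` differ (mg g DM^-1 day^-1, day^-1, and a
#' Michaelis-Menten maximal velocity, respectively). All bounds are
#' user-overridable by editing the returned data frame.
#'
#' @param variant One of `"simple"`, `"intermediate"`, `"complete"`.
#' @return Data frame with columns `name`, `lower`, `upper` in the canonical
#'   parameter-vector order.
#' @export
default_parameter_bounds <- function(variant = c("simple", "intermediate",
                                                 "complete")) {
  variant <- match.arg(variant)
  kmax <- switch(variant, simple = 5, intermediate = 0.2, complete = 10)
  dmax <- kmax
  reaction <- function(tag, mu_lo, mu_hi) {
    data.frame(name = paste(tag, c("k_trans", "d_endo", "d_eco", "mu",
                                   "sigma"), sep = "."),
               lower = c(0, -dmax, -dmax, mu_lo, 0.5),
               upper = c(kmax, dmax, dmax, mu_hi, 500))
  }
  out <- rbind(reaction("k1c", -5, 5),
               reaction("k1m", 10, 25),
               reaction("k2", 8, 20),
               data.frame(name = c("resp.r_max", "resp.a3", "resp.b3",
                                   "resp.q10"),
                          lower = c(0, -50, 0.3, 1),
                          upper = c(1, 0, 1.5, 4)))
  if (variant == "complete")
    out <- rbind(out,
                 data.frame(name = paste(c("k1c", "k1m", "k2"), "km",
                                         sep = "."),
                            lower = 1, upper = 1000))
  if (any(out$lower >= out$upper)) stop("degenerate bounds", call. = FALSE)
  out
}

#' Flatten model parameters to the canonical numeric vector
#'
#' @param params A [model_params()] object.
#' @return Named numeric vector of length 19 or 22, in the order used by
#'   [default_parameter_bounds()].
#' @export
params_to_vector <- function(params) {
  stopifnot(inherits(params, "model_params"))
  v <- c(unlist(lapply(c("k1c", "k1m", "k2"), function(tag) {
    rp <- params[[tag]]
    stats::setNames(c(rp$k_trans, rp$d_endo, rp$d_eco, rp$mu, rp$sigma),
                    paste(tag, c("k_trans", "d_endo", "d_eco", "mu", "sigma"),
                          sep = "."))
  })),
  stats::setNames(with(params$resp, c(r_max, a3, b3, q10)),
                  c("resp.r_max", "resp.a3", "resp.b3", "resp.q10")))
  if (params$variant == "complete")
    v <- c(v, stats::setNames(c(params$k1c$km, params$k1m$km, params$k2$km),
                              paste(c("k1c", "k1m", "k2"), "km", sep = ".")))
  v
}

#' Rebuild model parameters from the canonical vector
#'
#' Inverse of [params_to_vector()].
#'
#' @param x Numeric vector of length 19 (simple, intermediate) or 22
#'   (complete), in canonical order.
#' @param variant Model variant the vector encodes.
#' @return A [model_params()] object.
#' @export
vector_to_params <- function(x, variant = c("simple", "intermediate",
                                            "complete")) {
  variant <- match.arg(variant)
  need <- if (variant == "complete") 22L else 19L
  if (length(x) != need)
    stop("expected ", need, " parameters for the ", variant, " variant",
         call. = FALSE)
  x <- unname(x)
  rx <- function(i, km = NULL)
    reaction_params(k_trans = x[i], d_endo = x[i + 1L], d_eco = x[i + 2L],
                    mu = x[i + 3L], sigma = x[i + 4L], km = km)
  kms <- if (variant == "complete") x[20:22] else list(NULL, NULL, NULL)
  model_params(variant = variant,
               k1c = rx(1L, km = kms[[1L]]),
               k1m = rx(6L, km = kms[[2L]]),
               k2 = rx(11L, km = kms[[3L]]),
               resp = respiration_params(r_max = x[16L], a3 = x[17L],
                                         b3 = x[18L], q10 = x[19L]))
}

#' Latin hypercube sample of calibration starting points
#'
#' Draws `n_starts` points whose marginals are stratified (one point per
#' equal-probability stratum per dimension), scaled into the bound box.
#' Reproducible for a given seed; the global RNG state is left untouched.
#'
#' @param bounds Bounds data frame as from [default_parameter_bounds()].
#' @param n_starts Number of starting points (>= 1).
#' @param seed Integer seed.
#' @return Matrix `n_starts` x `nrow(bounds)` with named columns.
#' @export
lhs_starts <- function(bounds, n_starts, seed = 1L) {
  if (n_starts < 1L) stop("n_starts must be >= 1", call. = FALSE)
  if (any(bounds$lower >= bounds$upper))
    stop("degenerate bounds", call. = FALSE)
  u <- with_local_seed(seed, lhs::randomLHS(n_starts, nrow(bounds)))
  x <- sweep(u, 2L, bounds$upper - bounds$lower, "*")
  x <- sweep(x, 2L, bounds$lower, "+")
  colnames(x) <- bounds$name
  x
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Prepare one dataset for calibration
#'
#' Precomputes everything the objective needs — the phenological stage, the
#' interpolated daily water content, and the observation indices — so that
#' repeated objective evaluations only rerun the daily state loop. The
#' simulation window runs from the first observation date (whose gfs/starch
#' measurement is the initial state unless `init` is given) to budburst
#' (PS = 2) or the end of the weather, whichever comes first.
#'
#' @param weather Daily weather data frame.
#' @param observations Data frame with `date`, `gfs`, `starch`, `wc` (and
#'   optionally `fh`); as from [read_observations()] or the synthetic
#'   generator.
#' @param init Optional named initial state (`gfs`, `starch`); defaults to
#'   the first observation row.
#' @param pheno_params A [phenology_params()] object.
#' @return A `calibration_data` list used by [carbon_objective()] and
#'   [fit_carbon_model()].
#' @export
prepare_calibration_data <- function(weather, observations, init = NULL,
                                     pheno_params = phenology_params()) {
  obs <- observations[order(as.Date(observations$date)), , drop = FALSE]
  obs_dates <- as.Date(obs$date)
  if (nrow(obs) < 1L) stop("no observations", call. = FALSE)
  pheno <- accumulate_phenology(weather, pheno_params,
                                stop_at_budburst = TRUE)
  first <- obs_dates[1L]
  dates <- as.Date(pheno$date)
  keep <- dates >= first
  if (!any(keep))
    stop("observations start after the phenology window ends", call. = FALSE)
  dates <- dates[keep]
  n <- length(dates)
  state_dates <- c(dates, dates[n] + 1L)
  if (any(obs_dates < state_dates[1L] | obs_dates > state_dates[n + 1L]))
    stop("observation dates outside the simulation window", call. = FALSE)
  if (is.null(init)) init <- c(gfs = obs$gfs[1L], starch = obs$starch[1L])
  wmatch <- match(dates, as.Date(weather$date))
  structure(list(
    dates = dates,
    theta = daily_mean_temperature(weather)[wmatch],
    wc = interpolate_wc(obs_dates, obs$wc, dates),
    ps = pheno$ps[keep],
    init_gfs = unname(init[["gfs"]]),
    init_starch = unname(init[["starch"]]),
    obs_idx = match(obs_dates, state_dates),
    obs_gfs = obs$gfs,
    obs_starch = obs$starch),
    class = "calibration_data")
}

as_dataset_list <- function(datasets) {
  if (inherits(datasets, "calibration_data")) datasets <- list(datasets)
  if (!length(datasets) ||
      !all(vapply(datasets, inherits, logical(1), "calibration_data")))
    stop("datasets must be calibration_data objects", call. = FALSE)
  datasets
}

simulate_at_observations <- function(params, ds) {
  core <- simulate_core(ds$theta, ds$wc, ds$ps, ds$init_gfs, ds$init_starch,
                        params)
  list(gfs = core$gfs[ds$obs_idx], starch = core$starch[ds$obs_idx])
}

#' Residual sum of squares of a parameter set against observations
#'
#' Simulates each dataset under `params` and returns the pooled
#' `sum((GFS_sim - GFS_obs)^2) + sum((Starch_sim - Starch_obs)^2)`, the
#' quantity minimised by [fit_carbon_model()]. GFS and starch residuals are
#' weighted equally. A failed or non-finite simulation scores `+Inf`.
#'
#' @param params A [model_params()] object.
#' @param datasets One `calibration_data` object or a list of them.
#' @return Scalar sum of squares ((mg g DM^-1)^2).
#' @export
carbon_objective <- function(params, datasets) {
  datasets <- as_dataset_list(datasets)
  if (!sum(vapply(datasets, function(d) length(d$obs_idx), integer(1))))
    stop("empty observation set", call. = FALSE)
  tryCatch({
    ss <- 0
    for (ds in datasets) {
      sim <- simulate_at_observations(params, ds)
      ss <- ss + sum((sim$gfs - ds$obs_gfs)^2) +
        sum((sim$starch - ds$obs_starch)^2)
    }
    if (!is.finite(ss)) Inf else ss
  }, error = function(e) Inf)
}

# Bijection between the bound box and the real line (elementwise logit),
# so that Nelder-Mead runs unconstrained without penalty kinks.
to_unconstrained <- function(x, bounds) {
  p <- (x - bounds$lower) / (bounds$upper - bounds$lower)
  stats::qlogis(pmin(pmax(p, 1e-10), 1 - 1e-10))
}
from_unconstrained <- function(z, bounds) {
  bounds$lower + (bounds$upper - bounds$lower) * stats::plogis(z)
}

#' Fit model parameters by multistart Nelder-Mead
#'
#' Minimises [carbon_objective()] with the Nelder-Mead simplex started from
#' a Latin hypercube sample of the bound box. Bounds are enforced by a
#' smooth logit reparameterisation to the real line. Each start is polished
#' by restarting Nelder-Mead from its own endpoint until the relative
#' improvement falls below `rel_tol` or the per-start evaluation budget
#' `max_evals` is exhausted; the best endpoint across starts is returned.
#'
#' @param datasets One `calibration_data` object or a list of them
#'   (calibration datasets only; keep validation data aside for
#'   [metric_report()]).
#' @param variant Model variant to fit.
#' @param bounds Bounds data frame; defaults to
#'   [default_parameter_bounds()] for the variant.
#' @param n_starts Number of simplex starts actually optimised.
#' @param n_candidates Optional size of a Latin hypercube sample screened
#'   by a single objective evaluation before optimisation, with the
#'   `n_starts` best candidates becoming the starting points. The default
#'   (`n_starts`, no screening) preserves basin diversity, which matters
#'   more here than head starts: screened candidates tend to share basins.
#' @param max_evals Per-start objective evaluation budget.
#' @param rel_tol Relative convergence tolerance.
#' @param seed Integer seed controlling the starting sample.
#' @return A list of class `carbon_fit`: `best_params` ([model_params()]),
#'   `best_vector`, `ss_res`, per-variable `rmse` and `eff` on the
#'   calibration data, `n_starts`, `n_evals`, `converged`, `seed`, and a
#'   per-start log `starts`.
#' @export
fit_carbon_model <- function(datasets,
                             variant = c("simple", "intermediate",
                                         "complete"),
                             bounds = NULL,
                             n_starts = 100L,
                             n_candidates = NULL,
                             max_evals = 200000L,
                             rel_tol = 1e-8,
                             seed = 1L) {
  variant <- match.arg(variant)
  datasets <- as_dataset_list(datasets)
  n_obs <- sum(vapply(datasets, function(d) length(d$obs_idx), integer(1)))
  if (n_obs < 2L) stop("need at least 2 observation dates", call. = FALSE)
  if (is.null(bounds)) bounds <- default_parameter_bounds(variant)
  need <- if (variant == "complete") 22L else 19L
  if (nrow(bounds) != need)
    stop("bounds must have ", need, " rows for the ", variant, " variant",
         call. = FALSE)

  fn <- function(z) carbon_objective(
    vector_to_params(from_unconstrained(z, bounds), variant), datasets)

  if (is.null(n_candidates)) n_candidates <- n_starts
  if (n_candidates < n_starts)
    stop("n_candidates must be at least n_starts", call. = FALSE)
  cand <- lhs_starts(bounds, n_candidates, seed)
  cand_f <- vapply(seq_len(n_candidates), function(i)
    carbon_objective(vector_to_params(cand[i, ], variant), datasets),
    numeric(1))
  starts <- cand[order(cand_f)[seq_len(n_starts)], , drop = FALSE]
  total_evals <- n_candidates
  log_rows <- vector("list", n_starts)
  best_f <- Inf; best_z <- NULL
  for (s in seq_len(n_starts)) {
    z <- to_unconstrained(starts[s, ], bounds)
    f <- fn(z)
    evals <- 1L; conv <- FALSE
    if (is.finite(f)) {
      repeat {
        res <- tryCatch(
          stats::optim(z, fn, method = "Nelder-Mead",
                       control = list(maxit = 2000L, reltol = rel_tol)),
          error = function(e) NULL)
        if (is.null(res)) break
        evals <- evals + res$counts[["function"]]
        improved <- f - res$value
        z <- res$par
        if (res$value < f) f <- res$value
        if (improved <= rel_tol * (abs(f) + rel_tol)) { conv <- TRUE; break }
        if (evals >= max_evals) break
      }
    }
    total_evals <- total_evals + evals
    log_rows[[s]] <- data.frame(start = s, ss_res = f, evals = evals,
                                converged = conv)
    if (f < best_f) { best_f <- f; best_z <- z }
  }
  if (!is.finite(best_f))
    stop("all starts failed (objective not finite anywhere)", call. = FALSE)

  best_x <- from_unconstrained(best_z, bounds)
  names(best_x) <- bounds$name
  best_params <- vector_to_params(best_x, variant)
  metrics <- metric_report(best_params, datasets, role = "calibration")
  structure(list(best_params = best_params,
                 best_vector = best_x,
                 ss_res = best_f,
                 rmse = stats::setNames(metrics$rmse, metrics$variable),
                 eff = stats::setNames(metrics$eff, metrics$variable),
                 n_starts = n_starts,
                 n_evals = total_evals,
                 converged = any(vapply(log_rows, `[[`, logical(1),
                                        "converged")),
                 seed = seed,
                 starts = do.call(rbind, log_rows)),
            class = "carbon_fit")
}

#' @export
print.carbon_fit <- function(x, ...) {
  cat("Carbon-metabolism model fit (", x$best_params$variant, " variant)\n",
      sep = "")
  cat("  ss_res:", format(x$ss_res, digits = 6), "over", x$n_starts,
      "starts,", x$n_evals, "evaluations\n")
  cat(sprintf("  GFS    RMSE %6.3f  Eff %6.3f\n", x$rmse[["gfs"]],
              x$eff[["gfs"]]))
  cat(sprintf("  Starch RMSE %6.3f  Eff %6.3f\n", x$rmse[["starch"]],
              x$eff[["starch"]]))
  invisible(x)
}

#' Goodness-of-fit report for a parameter set
#'
#' Computes per-variable RMSE (labelled RMSEP on validation data) and
#' Nash-Sutcliffe efficiency of the simulated GFS and starch against the
#' observations of one or more datasets, pooled.
#'
#' @param params A [model_params()] object.
#' @param datasets One `calibration_data` object or a list of them.
#' @param role `"calibration"` or `"validation"`; controls the metric label
#'   only.
#' @return Data frame with columns `variable`, `n`, `rmse`, `eff`, `role`,
#'   `metric`.
#' @export
metric_report <- function(params, datasets,
                          role = c("calibration", "validation")) {
  role <- match.arg(role)
  datasets <- as_dataset_list(datasets)
  sims <- lapply(datasets, simulate_at_observations, params = params)
  obs_g <- unlist(lapply(datasets, `[[`, "obs_gfs"))
  obs_s <- unlist(lapply(datasets, `[[`, "obs_starch"))
  sim_g <- unlist(lapply(sims, `[[`, "gfs"))
  sim_s <- unlist(lapply(sims, `[[`, "starch"))
  data.frame(variable = c("gfs", "starch"),
             n = c(length(obs_g), length(obs_s)),
             rmse = c(rmse(obs_g, sim_g), rmse(obs_s, sim_s)),
             eff = c(efficiency(obs_g, sim_g), efficiency(obs_s, sim_s)),
             role = role,
             metric = if (role == "validation") "RMSEP" else "RMSE")
}
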