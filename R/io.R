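#' Read a daily weather file
#'
#' Delimited text with a header and columns `date` (ISO-8601), `tmin`,
#' `tmax` and optionally `tmean`. Rows are returned sorted by date;
#' duplicate dates are rejected.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return Data frame with `date` (Date) and the temperature columns.
#' @export
read_weather <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("weather file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dates <- as.Date(df$date)
  if (anyNA(dates))
    stop("unparseable date at row ", which(is.na(dates))[1L], call. = FALSE)
  if (anyDuplicated(dates))
    stop("duplicated date: ", dates[duplicated(dates)][1L], call. = FALSE)
  df$date <- dates
  df[order(df$date), , drop = FALSE]
}

#' Read a branch observation file
#'
#' Delimited text with a header and columns `date`, `gfs`, `starch`
#' (mg g DM^-1), plus either `wc` (g g^-1) directly or the fresh/dry mass
#' pair `fm`, `dm` from which `wc = (fm - dm) / dm` is computed. An optional
#' `fh` column carries measured frost hardiness (deg C, negative = hardier).
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return Data frame with `date`, `gfs`, `starch`, `wc` and `fh` (NA when
#'   absent), sorted by date.
#' @export
read_observations <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("date", "gfs", "starch"), names(df))
  if (length(miss))
    stop("observation file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dates <- as.Date(df$date)
  if (anyNA(dates))
    stop("unparseable date at row ", which(is.na(dates))[1L], call. = FALSE)
  if (is.null(df$wc)) {
    if (is.null(df$fm) || is.null(df$dm))
      stop("observation file needs either a wc column or fm and dm columns",
           call. = FALSE)
    bad <- which(df$fm < df$dm)
    if (length(bad))
      stop("fresh mass below dry mass (negative water content) at row ",
           bad[1L], call. = FALSE)
    df$wc <- (df$fm - df$dm) / df$dm
  }
  if (any(df$gfs < 0, na.rm = TRUE) || any(df$starch < 0, na.rm = TRUE))
    stop("negative carbohydrate pool in observations", call. = FALSE)
  if (is.null(df$fh)) df$fh <- NA_real_
  out <- data.frame(date = dates, gfs = df$gfs, starch = df$starch,
                    wc = df$wc, fh = df$fh)
  out[order(out$date), , drop = FALSE]
}

#' Write a daily weather series
#'
#' @param weather Weather data frame.
#' @param path Output file path.
#' @param sep Field separator.
#' @return The path, invisibly.
#' @export
write_weather <- function(weather, path, sep = ",") {
  utils::write.table(weather, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a branch observation series
#'
#' @param observations Observation data frame (`date`, `gfs`, `starch`,
#'   `wc`, optional `fh`).
#' @param path Output file path.
#' @param sep Field separator.
#' @return The path, invisibly.
#' @export
write_observations <- function(observations, path, sep = ",") {
  utils::write.table(observations, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a simulated carbon trajectory
#'
#' @param trajectory A `carbon_trajectory` data frame.
#' @param path Output file path.
#' @param sep Field separator.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(trajectory, path, sep = ",") {
  utils::write.table(trajectory, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write model parameters to a YAML configuration file
#'
#' The file holds the variant and one block per reaction (`k1c`, `k1m`,
#' `k2`) plus a `respiration` block, named per the variant's rate units to
#' prevent silent misuse across variants.
#'
#' @param params A [model_params()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_model_config <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  block <- function(rp) {
    b <- list(k_trans = rp$k_trans, d_endo = rp$d_endo, d_eco = rp$d_eco,
              mu = rp$mu, sigma = rp$sigma)
    if (!is.null(rp$km)) b$km <- rp$km
    b
  }
  cfg <- list(variant = params$variant,
              k1c = block(params$k1c),
              k1m = block(params$k1m),
              k2 = block(params$k2),
              respiration = list(r_max = params$resp$r_max,
                                 a3 = params$resp$a3, b3 = params$resp$b3,
                                 q10 = params$resp$q10,
                                 t_ref = params$resp$t_ref))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read model parameters from a YAML configuration file
#'
#' Inverse of [write_model_config()].
#'
#' @param path File path.
#' @return A [model_params()] object.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  miss <- setdiff(c("variant", "k1c", "k1m", "k2", "respiration"),
                  names(cfg))
  if (length(miss))
    stop("config lacks block(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rp <- function(b) reaction_params(k_trans = b$k_trans, d_endo = b$d_endo,
                                    d_eco = b$d_eco, mu = b$mu,
                                    sigma = b$sigma, km = b$km)
  r <- cfg$respiration
  model_params(variant = cfg$variant,
               k1c = rp(cfg$k1c), k1m = rp(cfg$k1m), k2 = rp(cfg$k2),
               resp = respiration_params(r_max = r$r_max, a3 = r$a3,
                                         b3 = r$b3, q10 = r$q10,
                                         t_ref = if (is.null(r$t_ref)) 15
                                                 else r$t_ref))
}
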