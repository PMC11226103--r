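#' Configuration of the synthetic study
#'
#' Collects every knob of the synthetic-data generator: the panel
#' dimensions, the true log-scale parameters of the production model, the
#' scales of the two random effects, the log-normal distribution of
#' first-year production, and the synthetic climate process. The defaults
#' define the package's reference simulation study: 150 municipalities
#' followed for 14 years, a covariate effect of 0.025 on the log scale
#' (about +2.5% production per covariate unit), municipality effects with
#' sd 0.3 and random-walk year innovations with sd 0.1, and initial
#' production around 5000 tons so that chains essentially never die out.
#'
#' The synthetic covariate is an *anomaly*: a deviation from each
#' municipality's climatological mean, so `covariate_mean = 0` keeps the
#' panel stable over time while still identifying the covariate effect.
#'
#' @param n_municipalities,n_years Panel dimensions; `n_years >= 2`.
#' @param crops Character vector of crop labels to simulate.
#' @param alpha_true,beta_true True intercept and covariate effect on the
#'   log-rate scale.
#' @param sigma_gamma,sigma_delta Non-negative sd of the iid municipality
#'   effects and of the RW1 year-effect innovations.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of
#'   first-year production (tons).
#' @param covariate_mean,covariate_sd,covariate_trend Mean level,
#'   municipality/month noise sd, and per-year linear trend of the
#'   monthly climate process.
#' @param seasonal_amplitude Amplitude of the within-year sinusoidal
#'   seasonal cycle of the monthly process.
#' @param variable Covariate column of the yearly climate table used in
#'   the generative linear predictor.
#' @param seed Integer seed; every simulation drawn from this config is
#'   fully reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_municipalities = 150,
                       n_years = 14,
                       crops = "rice",
                       alpha_true = 0.05,
                       beta_true = 0.025,
                       sigma_gamma = 0.3,
                       sigma_delta = 0.1,
                       baseline_log_mean = log(5000),
                       baseline_log_sd = 0.5,
                       covariate_mean = 0,
                       covariate_sd = 1.5,
                       covariate_trend = 0.02,
                       seasonal_amplitude = 3,
                       variable = "avg_temperature",
                       seed = 1L) {
  if (n_municipalities < 1 || n_years < 2) {
    stop("need `n_municipalities` >= 1 and `n_years` >= 2", call. = FALSE)
  }
  stopifnot(sigma_gamma >= 0, sigma_delta >= 0, length(crops) >= 1)
  structure(
    list(n_municipalities = as.integer(n_municipalities),
         n_years = as.integer(n_years),
         crops = as.character(crops),
         alpha_true = alpha_true, beta_true = beta_true,
         sigma_gamma = sigma_gamma, sigma_delta = sigma_delta,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         covariate_mean = covariate_mean,
         covariate_sd = covariate_sd,
         covariate_trend = covariate_trend,
         seasonal_amplitude = seasonal_amplitude,
         variable = variable,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

sim_years <- function(config) seq(2007L, length.out = config$n_years)
sim_codes <- function(config) sprintf("%05d", seq_len(config$n_municipalities))

# Poisson draws stored as doubles; means beyond integer range use the
# normal approximation (relative error is negligible at that magnitude)
rpois_large <- function(n, lambda) {
  out <- numeric(n)
  big <- lambda > 1e9
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big)) {
    out[big] <- pmax(0, round(stats::rnorm(sum(big), lambda[big],
                                           sqrt(lambda[big]))))
  }
  out
}

# TerraClimate-style source variables feeding the yearly covariates
monthly_source_variables <- function() {
  c("tmin", "tmax", "aet", "pet", "ppt", "runoff", "soil",
    "vap", "srad", "ws")
}

#' Simulate monthly climate and its yearly aggregation
#'
#' Generates a monthly climate table in the long layout used by
#' [aggregate_yearly()] and returns both the monthly table and its yearly
#' aggregation. Each variable follows
#' `mean + trend * (year - first year) + seasonal sinusoid +
#' municipality offset + monthly noise`, with the municipality offset and
#' the noise both scaled by `covariate_sd` (so a zero sd gives a
#' deterministic process). Monthly `tmin` and `tmax` are built as a
#' shared midpoint minus/plus a fixed 5-degree half-range, which keeps
#' `tmin <= tmax` and makes the midpoint the monthly average temperature.
#'
#' @param config A [sim_config()].
#' @return List with elements `monthly` (long tibble:
#'   `municipality_code`, `year`, `month`, `variable`, `value`) and
#'   `yearly` (the aggregated covariate table).
#' @export
simulate_climate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_climate_impl(config))
}

simulate_climate_impl <- function(config) {
  years <- sim_years(config)
  codes <- sim_codes(config)
  vars <- monthly_source_variables()

  grid <- tidyr::expand_grid(municipality_code = codes,
                             year = years, month = 1:12)
  season <- config$seasonal_amplitude * sinpi(2 * (grid$month - 1) / 12)
  trend <- config$covariate_trend * (grid$year - years[1])

  one_var <- function(v) {
    offs <- stats::rnorm(length(codes), 0, config$covariate_sd)
    noise <- stats::rnorm(nrow(grid), 0, config$covariate_sd)
    mid <- config$covariate_mean + trend + season +
      offs[match(grid$municipality_code, codes)] + noise
    if (v == "tmin") mid <- mid - 5
    if (v == "tmax") mid <- mid + 5
    tibble::tibble(municipality_code = grid$municipality_code,
                   year = grid$year, month = grid$month,
                   variable = v, value = mid)
  }
  # tmin/tmax share one midpoint draw so their average is the midpoint
  offs_t <- stats::rnorm(length(codes), 0, config$covariate_sd)
  noise_t <- stats::rnorm(nrow(grid), 0, config$covariate_sd)
  mid_t <- config$covariate_mean + trend + season +
    offs_t[match(grid$municipality_code, codes)] + noise_t
  temp <- dplyr::bind_rows(
    tibble::tibble(municipality_code = grid$municipality_code,
                   year = grid$year, month = grid$month,
                   variable = "tmin", value = mid_t - 5),
    tibble::tibble(municipality_code = grid$municipality_code,
                   year = grid$year, month = grid$month,
                   variable = "tmax", value = mid_t + 5))
  others <- dplyr::bind_rows(lapply(setdiff(vars, c("tmin", "tmax")), one_var))
  monthly <- dplyr::bind_rows(temp, others)
  list(monthly = monthly, yearly = aggregate_yearly(monthly))
}

#' Simulate a production panel from the generative model
#'
#' Draws ground truth and data from the package's own model: first-year
#' production is log-normal (rounded to integer tons); for later years
#' `y[i, t] ~ Poisson(y[i, t-1] * exp(alpha + gamma_i + delta_t +
#' beta * x[i, t]))`, so the previous year's production acts as the
#' offset. Municipality effects are iid Gaussian; year effects are a
#' Gaussian random walk recentred to sum to zero. A municipality whose
#' production hits zero stays at zero (the rate is undefined without a
#' positive offset); [build_design()] later drops such rows, mirroring
#' how observed data are handled. When several crops are requested they
#' share `gamma`/`delta` but have independent baselines and Poisson
#' draws.
#'
#' @param config A [sim_config()].
#' @param climate Optional pre-simulated result of [simulate_climate()];
#'   simulated from `config` when omitted.
#' @return An object of class `sim_truth`: list with `config`,
#'   `gamma_true`, `delta_true`, `panel` (long production tibble),
#'   `climate` (yearly covariates) and `monthly` climate.
#' @export
simulate_panel <- function(config, climate = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(climate)) climate <- simulate_climate(config)
  yearly <- climate$yearly
  if (!config$variable %in% names(yearly)) {
    stop("climate table lacks the generative covariate '",
         config$variable, "'", call. = FALSE)
  }
  with_seed(config$seed + 1L, simulate_panel_impl(config, climate, yearly))
}

simulate_panel_impl <- function(config, climate, yearly) {
  N <- config$n_municipalities
  Tn <- config$n_years
  years <- sim_years(config)
  codes <- sim_codes(config)

  gamma <- stats::rnorm(N, 0, config$sigma_gamma)
  walk <- cumsum(c(0, stats::rnorm(Tn - 1, 0, config$sigma_delta)))
  delta <- walk - mean(walk)

  # covariate matrix [municipality, year]
  key <- paste(yearly$municipality_code, yearly$year)
  x <- matrix(yearly[[config$variable]][match(
    paste(rep(codes, Tn), rep(years, each = N)), key)], nrow = N)
  if (anyNA(x)) stop("climate does not cover all municipality-years",
                     call. = FALSE)

  panels <- lapply(config$crops, function(crop) {
    y <- matrix(0, nrow = N, ncol = Tn)
    y[, 1] <- round(stats::rlnorm(
      N, config$baseline_log_mean, config$baseline_log_sd))
    for (t in 2:Tn) {
      lam <- y[, t - 1] * exp(config$alpha_true + gamma + delta[t] +
                                config$beta_true * x[, t])
      y[, t] <- rpois_large(N, lam)
    }
    tibble::tibble(municipality_code = rep(codes, Tn),
                   year = rep(years, each = N),
                   crop = crop,
                   production = as.vector(y))
  })
  panel <- dplyr::arrange(dplyr::bind_rows(panels),
                          .data$crop, .data$municipality_code, .data$year)

  structure(
    list(config = config, gamma_true = gamma, delta_true = delta,
         panel = panel, climate = yearly, monthly = climate$monthly),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d municipalities x %d years x %d crop(s); alpha=%.3g, beta=%.3g\n",
    x$config$n_municipalities, x$config$n_years, length(x$config$crops),
    x$config$alpha_true, x$config$beta_true))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the production panel and yearly climate as CSV and the true
#' parameter values as a flat `key=value` text file, so external harnesses
#' can consume a simulation without R.
#'
#' @param truth A `sim_truth` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("panel.csv", "climate_yearly.csv", "truth.txt"))
  utils::write.csv(truth$panel, paths[1], row.names = FALSE)
  utils::write.csv(truth$climate, paths[2], row.names = FALSE)
  cfg <- truth$config
  kv <- c(
    sprintf("alpha_true=%.17g", cfg$alpha_true),
    sprintf("beta_true=%.17g", cfg$beta_true),
    sprintf("sigma_gamma=%.17g", cfg$sigma_gamma),
    sprintf("sigma_delta=%.17g", cfg$sigma_delta),
    sprintf("n_municipalities=%d", cfg$n_municipalities),
    sprintf("n_years=%d", cfg$n_years),
    sprintf("seed=%d", cfg$seed),
    sprintf("gamma_true=%s", paste(sprintf("%.17g", truth$gamma_true),
                                   collapse = ",")),
    sprintf("delta_true=%s", paste(sprintf("%.17g", truth$delta_true),
                                   collapse = ",")))
  writeLines(kv, paths[3])
  invisible(paths)
}
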