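#' Crops and climate covariates handled by the package
#'
#' `cropclim_crops()` returns the five crop labels used throughout the
#' package; `cropclim_variables()` returns the eleven yearly climate
#' covariates (with their units as names).
#'
#' @return A character vector.
#' @export
cropclim_crops <- function() {
  c("coffee", "corn", "palm_oil", "rice", "sugarcane")
}

#' @rdname cropclim_crops
#' @export
cropclim_variables <- function() {
  c("°C"    = "min_temperature",
    "°C"    = "max_temperature",
    "°C"    = "avg_temperature",
    "mm"         = "actual_evapotranspiration",
    "mm"         = "reference_evapotranspiration",
    "mm"         = "precipitation",
    "mm"         = "runoff",
    "mm"         = "soil_moisture",
    "kPa"        = "vapor_pressure",
    "W/m^2"      = "radiation",
    "m/s"        = "wind_speed")
}

#' Prior configuration for the hierarchical Poisson model
#'
#' Gaussian priors with a common precision on the fixed effects (intercept
#' and covariate coefficient) and a conjugate Gamma(shape `a`, rate `b`)
#' hyperprior on the two random-effect precisions (iid municipality effect
#' and RW1 year effect). The default hyperprior `Gamma(1, 5e-5)` is the
#' vague log-gamma default commonly used for latent Gaussian models; the
#' default fixed-effect precision 0.001 corresponds to a prior sd of about
#' 31.6 on the log-rate scale.
#'
#' @param fixed_effect_precision Positive Gaussian precision on the
#'   intercept and the covariate coefficient.
#' @param hyper_shape,hyper_rate Positive shape and rate of the Gamma
#'   hyperprior shared by both random-effect precisions.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(fixed_effect_precision = 0.001,
                         hyper_shape = 1,
                         hyper_rate = 5e-5) {
  stopifnot(fixed_effect_precision > 0, hyper_shape > 0, hyper_rate > 0)
  structure(
    list(fixed_effect_precision = fixed_effect_precision,
         hyper_shape = hyper_shape,
         hyper_rate = hyper_rate),
    class = "prior_config"
  )
}

#' Model parameters
#'
#' Bundles one point in parameter space for the production-rate model
#' `log(rho_it) = alpha + gamma_i + delta_t + beta * x_it`: the grand
#' intercept `alpha`, covariate effect `beta`, municipality effects
#' `gamma` (length N), year effects `delta` (length T, constrained to sum
#' to zero), and the two random-effect precisions.
#'
#' @param alpha,beta Scalar fixed effects on the log scale.
#' @param gamma Numeric vector of municipality effects.
#' @param delta Numeric vector of year effects; must sum to zero
#'   (tolerance 1e-10).
#' @param tau_gamma,tau_delta Strictly positive precisions of the iid
#'   municipality effect and of the RW1 innovations.
#' @return An object of class `model_params`.
#' @export
model_params <- function(alpha, beta, gamma, delta, tau_gamma, tau_delta) {
  stopifnot(length(alpha) == 1L, length(beta) == 1L,
            is.numeric(gamma), is.numeric(delta))
  if (!(tau_gamma > 0) || !(tau_delta > 0)) {
    stop("precisions `tau_gamma` and `tau_delta` must be strictly positive",
         call. = FALSE)
  }
  if (length(delta) > 0 && abs(sum(delta)) > 1e-10) {
    stop("`delta` must sum to zero (sum-to-zero identifiability constraint)",
         call. = FALSE)
  }
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma), delta = as.numeric(delta),
         tau_gamma = as.numeric(tau_gamma), tau_delta = as.numeric(tau_delta)),
    class = "model_params"
  )
}

#' Build the single-crop, single-covariate model design
#'
#' Pairs each municipality-year production value with the previous year's
#' production (the model offset) and the current year's value of one
#' climate covariate. Only consecutive calendar years form a usable pair.
#' Rows whose offset is zero (the rate is undefined when last year's
#' production was nil) or whose covariate is missing are dropped;
#' municipalities left with no usable pair contribute nothing.
#' Municipality and year indices are densely renumbered so the model sees
#' contiguous `1..N` and `1..T` labels.
#'
#' @param panel A production panel: data frame with columns
#'   `municipality_code`, `year`, `crop`, `production`.
#' @param climate A yearly climate table with `municipality_code`, `year`
#'   and covariate columns (see [aggregate_yearly()]).
#' @param crop Single crop label to model.
#' @param variable Single covariate column name in `climate`.
#' @return An object of class `model_data`: list with vectors `y`
#'   (response), `offset_eps` (previous-year production), `x` (covariate),
#'   `muni_index`, `year_index`, scalars `N`, `T`, and the label lookups
#'   `municipalities`, `years`.
#' @export
build_design <- function(panel, climate, crop, variable) {
  stopifnot(is.character(crop) || is.factor(crop), length(crop) == 1L,
            length(variable) == 1L)
  if (!variable %in% names(climate)) {
    stop(sprintf("no estimable data for crop '%s', variable '%s': %s",
                 crop, variable,
                 "covariate column absent from the climate table"),
         call. = FALSE)
  }

  sub <- panel[panel$crop == crop, c("municipality_code", "year", "production"),
               drop = FALSE]
  sub <- sub[order(sub$municipality_code, sub$year), , drop = FALSE]
  if (any(duplicated(sub[c("municipality_code", "year")]))) {
    stop("panel has duplicated (municipality, year) rows for crop ", crop,
         call. = FALSE)
  }

  prod <- round(sub$production)
  if (any(abs(prod - sub$production) > 0)) {
    warning("fractional production values rounded to integer tons",
            call. = FALSE)
  }

  # lag within municipality; a pair is usable only across consecutive years
  same <- c(FALSE, sub$municipality_code[-1] ==
                     sub$municipality_code[-nrow(sub)])
  consecutive <- same & c(FALSE, diff(sub$year) == 1L)
  y    <- prod[consecutive]
  eps  <- prod[which(consecutive) - 1L]
  code <- sub$municipality_code[consecutive]
  yr   <- sub$year[consecutive]

  keep <- eps > 0
  y <- y[keep]; eps <- eps[keep]; code <- code[keep]; yr <- yr[keep]

  # attach the covariate for the response year
  key  <- paste(climate$municipality_code, climate$year)
  x    <- climate[[variable]][match(paste(code, yr), key)]
  keep <- is.finite(x)
  y <- y[keep]; eps <- eps[keep]; code <- code[keep]; yr <- yr[keep]
  x <- x[keep]

  if (length(y) == 0L) {
    stop(sprintf("no estimable data for crop '%s', variable '%s'",
                 crop, variable), call. = FALSE)
  }

  municipalities <- sort(unique(code))
  years <- sort(unique(yr))
  structure(
    list(y = as.numeric(y),          # integral values kept as doubles so
         offset_eps = as.numeric(eps),  # huge counts cannot overflow

         x = as.numeric(x),
         muni_index = match(code, municipalities),
         year_index = match(yr, years),
         N = length(municipalities),
         T = length(years),
         municipalities = municipalities,
         years = years,
         crop = as.character(crop),
         variable = variable),
    class = "model_data"
  )
}

#' @export
print.model_data <- function(x, ...) {
  cat(sprintf(
    "<model_data> crop '%s' ~ '%s': %d rows, %d municipalities, %d years\n",
    x$crop, x$variable, length(x$y), x$N, x$T))
  invisible(x)
}

check_params_dims <- function(data, params) {
  if (length(params$gamma) != data$N || length(params$delta) != data$T) {
    stop(sprintf(
      "parameter dimensions (gamma %d, delta %d) do not match data (N=%d, T=%d)",
      length(params$gamma), length(params$delta), data$N, data$T),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' Linear predictor, rate and Poisson mean for every observation
#'
#' Computes `eta = alpha + gamma[i] + delta[t] + beta * x`, the production
#' rate `rho = exp(eta)`, and the Poisson mean `lambda = rho * offset`.
#'
#' @param data A `model_data` object from [build_design()].
#' @param params A `model_params` object dimensioned for `data`.
#' @return List of class `fitted_rates` with vectors `eta`, `rho`, `lam`.
#' @export
compute_rates <- function(data, params) {
  check_params_dims(data, params)
  eta <- params$alpha + params$gamma[data$muni_index] +
    params$delta[data$year_index] + params$beta * data$x
  rho <- exp(eta)
  structure(list(eta = eta, rho = rho, lam = rho * data$offset_eps),
            class = "fitted_rates")
}

#' Poisson log-likelihood of the production model
#'
#' Sum over observations of the Poisson log-pmf
#' `y * log(lambda) - lambda - log(y!)` with `lambda` from
#' [compute_rates()]; the log-factorial uses `lgamma(y + 1)` so the value
#' is finite for any admissible input.
#'
#' @inheritParams compute_rates
#' @return A single finite number.
#' @export
log_likelihood <- function(data, params) {
  lam <- compute_rates(data, params)$lam
  sum(data$y * log(lam) - lam - lgamma(data$y + 1))
}

#' Joint log-prior of the model parameters
#'
#' Adds (i) mean-zero Gaussian log-densities (with normalising constants)
#' for `alpha` and `beta` at the fixed-effect precision; (ii) iid
#' mean-zero Gaussian log-densities for `gamma` at precision `tau_gamma`;
#' (iii) the improper first-order random-walk log-density for `delta`,
#' `((T-1)/2) * log(tau_delta) - (tau_delta/2) * sum(diff(delta)^2)`,
#' stated without a 2*pi constant as usual for an intrinsic prior of rank
#' T-1 under the sum-to-zero constraint; and (iv) Gamma log-densities for
#' both precisions under the hyperprior.
#'
#' @param params A `model_params` object.
#' @param prior A `prior_config` object.
#' @return A single number (log scale; finite for valid inputs).
#' @export
log_prior <- function(params, prior) {
  stopifnot(inherits(prior, "prior_config"))
  if (!(params$tau_gamma > 0) || !(params$tau_delta > 0)) {
    stop("non-positive precision in `params`", call. = FALSE)
  }
  p0 <- prior$fixed_effect_precision
  lp_fixed <- sum(stats::dnorm(c(params$alpha, params$beta),
                               sd = 1 / sqrt(p0), log = TRUE))
  lp_gamma <- sum(stats::dnorm(params$gamma,
                               sd = 1 / sqrt(params$tau_gamma), log = TRUE))
  Tn <- length(params$delta)
  lp_delta <- if (Tn >= 2) {
    (Tn - 1) / 2 * log(params$tau_delta) -
      params$tau_delta / 2 * sum(diff(params$delta)^2)
  } else 0
  lp_tau <- sum(stats::dgamma(c(params$tau_gamma, params$tau_delta),
                              shape = prior$hyper_shape,
                              rate = prior$hyper_rate, log = TRUE))
  lp_fixed + lp_gamma + lp_delta + lp_tau
}

#' Percent change in production per unit of the covariate
#'
#' Maps a log-scale coefficient to the reporting scale used for climate
#' effects: `100 * (exp(beta) - 1)`, the percent change in the production
#' rate caused by a one-unit rise in the covariate (e.g. percent per
#' degree Celsius).
#'
#' @param beta_value Numeric vector of log-scale coefficients.
#' @return Numeric vector of percent changes.
#' @examples
#' percent_change(log(2))       # a doubling: +100%
#' percent_change(log(1.0255))  # +2.55% per unit
#' @export
percent_change <- function(beta_value) {
  100 * (exp(beta_value) - 1)
}
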