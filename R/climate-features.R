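#' Aggregate monthly climate variables to yearly covariates
#'
#' Turns a long monthly climate table (TerraClimate-style source
#' variables `tmin`, `tmax`, `aet`, `pet`, `ppt`, `runoff`, `soil`,
#' `vap`, `srad`, `ws`) into the eleven yearly covariates of the
#' production model: the yearly *minimum* of monthly `tmin`, the yearly
#' *maximum* of monthly `tmax`, the yearly mean of the monthly midpoint
#' `(tmin + tmax) / 2` as average temperature, and the yearly mean per
#' month of each remaining variable. Years with fewer than twelve months
#' are aggregated over the available months and flagged via `complete`;
#' a variable entirely absent for a municipality-year yields `NA`, never
#' a silent zero.
#'
#' @param monthly Data frame with columns `municipality_code`, `year`,
#'   `month` (1-12), `variable`, `value`; at most one value per
#'   (municipality, year, month, variable).
#' @return A tibble with one row per (municipality, year): the eleven
#'   covariate columns of [cropclim_variables()], plus `n_months` (months
#'   with any data) and `complete` (all source variables present in all
#'   twelve months).
#' @export
aggregate_yearly <- function(monthly) {
  req <- c("municipality_code", "year", "month", "variable", "value")
  if (!all(req %in% names(monthly))) {
    stop("monthly climate needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(monthly$month < 1 | monthly$month > 12)) {
    stop("`month` must lie in 1..12", call. = FALSE)
  }
  if (anyDuplicated(monthly[c("municipality_code", "year", "month",
                              "variable")])) {
    stop("duplicated (municipality, year, month, variable) entries",
         call. = FALSE)
  }

  wide <- tidyr::pivot_wider(
    monthly[req], names_from = "variable", values_from = "value")
  for (v in monthly_source_variables()) {
    if (!v %in% names(wide)) wide[[v]] <- NA_real_
  }

  n_src <- length(monthly_source_variables())
  out <- dplyr::summarise(
    dplyr::group_by(wide, .data$municipality_code, .data$year),
    # completeness is computed first: later summaries reuse source
    # column names (e.g. runoff), which would shadow the monthly values
    n_months = length(unique(.data$month)),
    complete = length(unique(.data$month)) == 12L &&
      sum(!is.na(c(.data$tmin, .data$tmax, .data$aet, .data$pet, .data$ppt,
                   .data$runoff, .data$soil, .data$vap, .data$srad,
                   .data$ws))) == 12L * n_src,
    min_temperature = safe_min(.data$tmin),
    max_temperature = safe_max(.data$tmax),
    avg_temperature = safe_mean((.data$tmin + .data$tmax) / 2),
    actual_evapotranspiration = safe_mean(.data$aet),
    reference_evapotranspiration = safe_mean(.data$pet),
    precipitation = safe_mean(.data$ppt),
    runoff = safe_mean(.data$runoff),
    soil_moisture = safe_mean(.data$soil),
    vapor_pressure = safe_mean(.data$vap),
    radiation = safe_mean(.data$srad),
    wind_speed = safe_mean(.data$ws),
    .groups = "drop")
  dplyr::relocate(out, "n_months", "complete", .after = "wind_speed")
}

#' National yearly mean series of one covariate
#'
#' Unweighted mean of a yearly covariate across municipalities, per year,
#' together with the years attaining the maximum and minimum — the
#' series behind country-level descriptive time-series plots.
#'
#' @param yearly A yearly climate table (see [aggregate_yearly()]).
#' @param variable Covariate column name.
#' @return Object of class `national_series`: list with `series` (tibble
#'   `year`, `value`), `argmax_year`, `argmin_year`, `variable`.
#' @export
national_series <- function(yearly, variable) {
  stopifnot(length(variable) == 1L)
  if (!variable %in% names(yearly)) {
    stop("unknown covariate '", variable, "'", call. = FALSE)
  }
  if (nrow(yearly) == 0L) stop("empty climate table", call. = FALSE)
  ser <- dplyr::summarise(dplyr::group_by(yearly, .data$year),
                          value = safe_mean(.data[[variable]]),
                          .groups = "drop")
  ser <- dplyr::arrange(ser, .data$year)
  structure(
    list(series = ser,
         argmax_year = ser$year[which.max(ser$value)],
         argmin_year = ser$year[which.min(ser$value)],
         variable = variable),
    class = "national_series"
  )
}

#' @export
print.national_series <- function(x, ...) {
  cat(sprintf("<national_series> '%s', %d years; peak %d, trough %d\n",
              x$variable, nrow(x$series), x$argmax_year, x$argmin_year))
  invisible(x)
}

# expand coefficients of sum c_k (x - m)^k into raw powers of x
expand_centered_poly <- function(coef_centered, m) {
  d <- length(coef_centered) - 1L
  out <- numeric(d + 1L)
  for (k in 0:d) {
    # c_k * (x - m)^k = c_k * sum_j choose(k, j) x^j (-m)^(k-j)
    j <- 0:k
    out[j + 1L] <- out[j + 1L] +
      coef_centered[k + 1L] * choose(k, j) * (-m)^(k - j)
  }
  out
}

#' Polynomial trend smoother with AIC model choice
#'
#' Fits ordinary least-squares polynomials of degree 1 to 4 in year and
#' returns the one minimising `AIC = n * log(RSS / n) + 2 * (degree + 2)`
#' (the Gaussian-likelihood AIC with the error variance counted as a
#' parameter). Fitting is done on centred years for numerical stability;
#' the reported coefficients are re-expanded to the raw year scale, in
#' increasing power order (intercept first).
#'
#' @param series A data frame with columns `year` and `value`, or a
#'   [national_series()] object.
#' @return Object of class `trend_fit`: `degree`, `coefficients` (raw
#'   scale, length degree + 1), `aic` (of the chosen degree), `all_aic`
#'   and `all_rss` (named, degrees 1-4), `fitted_values`, `rss`.
#' @export
fit_trend_smoother <- function(series) {
  if (inherits(series, "national_series")) series <- series$series
  stopifnot(all(c("year", "value") %in% names(series)))
  ok <- is.finite(series$year) & is.finite(series$value)
  x <- series$year[ok]; y <- series$value[ok]
  n <- length(y)
  if (n <= 5L) {
    stop("need at least 6 points to compare trends up to degree 4",
         call. = FALSE)
  }
  m <- mean(x)
  xc <- x - m
  # degenerate exact fits leave only least-squares roundoff in the RSS;
  # flooring at the numerical noise level makes such candidates tie, so
  # the AIC penalty resolves them to the most parsimonious degree
  rss_floor <- sum(y^2) * 1e-24 + 1e-300
  fits <- lapply(1:4, function(d) {
    fit <- stats::lm.fit(outer(xc, 0:d, `^`), y)
    rss <- sum(fit$residuals^2)
    list(degree = d, coef = fit$coefficients, rss = rss,
         fitted = fit$fitted.values,
         aic = n * log(max(rss, rss_floor) / n) + 2 * (d + 2))
  })
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- fits[[which.min(aics)]]
  coefs <- expand_centered_poly(unname(best$coef), m)
  structure(
    list(degree = best$degree,
         coefficients = stats::setNames(coefs, paste0("year^", 0:best$degree)),
         aic = best$aic,
         all_aic = stats::setNames(aics, paste0("degree", 1:4)),
         all_rss = stats::setNames(vapply(fits, `[[`, numeric(1), "rss"),
                                   paste0("degree", 1:4)),
         fitted_values = best$fitted,
         rss = best$rss),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> degree %d (AIC %.2f); coefficients:\n",
              x$degree, x$aic))
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' Read and write the package's CSV formats
#'
#' Plain UTF-8 comma-separated files with a header row and `.` decimals.
#' `read_production_panel()` expects columns `municipality_code`, `year`,
#' `crop`, `production`; `read_monthly_climate()` expects
#' `municipality_code`, `year`, `month`, `variable`, `value`;
#' `read_yearly_climate()` expects the output layout of
#' [aggregate_yearly()].
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_production_panel <- function(path) {
  df <- utils::read.csv(path, colClasses = c(municipality_code = "character"))
  req <- c("municipality_code", "year", "crop", "production")
  if (!all(req %in% names(df))) {
    stop("panel CSV needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_production_panel
#' @export
read_monthly_climate <- function(path) {
  df <- utils::read.csv(path, colClasses = c(municipality_code = "character"))
  req <- c("municipality_code", "year", "month", "variable", "value")
  if (!all(req %in% names(df))) {
    stop("monthly climate CSV needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_production_panel
#' @export
read_yearly_climate <- function(path) {
  df <- utils::read.csv(path, colClasses = c(municipality_code = "character"))
  if (!all(c("municipality_code", "year") %in% names(df))) {
    stop("yearly climate CSV needs `municipality_code` and `year`",
         call. = FALSE)
  }
  tibble::as_tibble(df)
}
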