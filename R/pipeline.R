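#' Complete a production panel to a full crop x municipality x year cross
#'
#' Inserts zero-production rows for every (crop, municipality, year)
#' combination absent from the panel, so record counts are well defined:
#' the output always has exactly
#' `length(crops) * length(municipalities) * length(years)` rows. The
#' operation is idempotent.
#'
#' @param panel A production panel (possibly sparse).
#' @param municipalities,years,crops Vectors defining the full cross;
#'   default to the distinct values present in `panel`.
#' @return A tibble with the completed panel, sorted by crop,
#'   municipality and year.
#' @export
complete_panel <- function(panel,
                           municipalities = unique(panel$municipality_code),
                           years = unique(panel$year),
                           crops = unique(panel$crop)) {
  full <- tidyr::expand_grid(crop = sort(crops),
                             municipality_code = sort(municipalities),
                             year = sort(years))
  obs <- panel[panel$crop %in% crops &
                 panel$municipality_code %in% municipalities &
                 panel$year %in% years,
               c("crop", "municipality_code", "year", "production")]
  out <- dplyr::left_join(full, obs,
                          by = c("crop", "municipality_code", "year"))
  out$production[is.na(out$production)] <- 0
  tibble::as_tibble(out[c("municipality_code", "year", "crop", "production")])
}

#' Fit one crop-covariate model and report its climate effect
#'
#' Builds the design for one (crop, covariate) pair, samples the
#' posterior, and reports the covariate effect on the log scale and as
#' percent change in production per unit of the covariate, with 95%
#' credible intervals and convergence diagnostics. Per-unit percent
#' fields are the [percent_change()] transform of the corresponding
#' log-scale posterior functionals (both the mean and the interval ends
#' are transformed; the exponential is monotone, so the interval maps
#' coherently).
#'
#' @param panel Production panel.
#' @param climate Yearly climate table.
#' @param crop,variable The pair to fit.
#' @param prior A [prior_config()].
#' @param config An [mcmc_config()].
#' @param out_dir Optional directory; when given, the draws and summary
#'   of the fit are written there as CSV.
#' @return One-row tibble of class `effect_estimate` with columns `crop`,
#'   `variable`, `beta_mean`, `beta_sd`, `beta_q2.5`, `beta_q97.5`,
#'   `pct_mean`, `pct_median`, `pct_q2.5`, `pct_q97.5`, `rhat`, `ess`,
#'   `n_obs`.
#' @export
run_single <- function(panel, climate, crop, variable,
                       prior = prior_config(), config = mcmc_config(),
                       out_dir = NULL) {
  data <- build_design(panel, climate, crop, variable)
  draws <- sample_posterior(data, prior, config, store_effects = FALSE)
  summ <- summarize_draws(draws)
  b <- summ[summ$parameter == "beta", ]
  beta_pool <- unlist(lapply(draws$chains, function(m) m[, "beta"]),
                      use.names = FALSE)

  out <- tibble::tibble(
    crop = data$crop, variable = data$variable,
    beta_mean = b$mean, beta_sd = b$sd,
    beta_q2.5 = b$q2.5, beta_q97.5 = b$q97.5,
    pct_mean = mean(percent_change(beta_pool)),
    pct_median = percent_change(stats::median(beta_pool)),
    pct_q2.5 = percent_change(b$q2.5),
    pct_q97.5 = percent_change(b$q97.5),
    rhat = b$rhat, ess = b$ess,
    n_obs = length(data$y))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stem <- file.path(out_dir, paste0(crop, "_", variable))
    write_draws(draws, paste0(stem, "_draws.csv"))
    write_summary(summ, paste0(stem, "_summary.csv"))
  }
  class(out) <- c("effect_estimate", class(out))
  out
}

#' Fit every requested crop x covariate pair
#'
#' Runs [run_single()] for each pair of the requested crops and
#' covariates — one single-covariate model per pair, which avoids
#' estimation instability from correlated climate variables. A failing
#' pair (typically "no estimable data" for a sparse crop) is recorded
#' with its error message and does not abort the sweep. Each pair gets
#' its own deterministic seed derived from `config$seed` and the pair
#' index, so the sweep is reproducible and each fit is independent.
#'
#' @param panel Production panel.
#' @param climate Yearly climate table.
#' @param crops,variables Character vectors; default to all five crops
#'   and all eleven covariates.
#' @inheritParams run_single
#' @return Tibble with one row per requested pair: the
#'   [run_single()] columns plus `status` ("ok" or "failed") and
#'   `message`. Errors with class `cropclim_all_failed` if no pair
#'   succeeded.
#' @export
run_all <- function(panel, climate,
                    crops = cropclim_crops(),
                    variables = unname(cropclim_variables()),
                    prior = prior_config(), config = mcmc_config(),
                    out_dir = NULL) {
  stopifnot(length(crops) >= 1, length(variables) >= 1)
  pairs <- tidyr::expand_grid(crop = crops, variable = variables)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    res <- tryCatch(
      run_single(panel, climate, pairs$crop[k], pairs$variable[k],
                 prior = prior, config = cfg, out_dir = out_dir),
      error = function(e) e)
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      tibble::tibble(crop = pairs$crop[k], variable = pairs$variable[k],
                     beta_mean = NA_real_, beta_sd = NA_real_,
                     beta_q2.5 = NA_real_, beta_q97.5 = NA_real_,
                     pct_mean = NA_real_, pct_median = NA_real_,
                     pct_q2.5 = NA_real_, pct_q97.5 = NA_real_,
                     rhat = NA_real_, ess = NA_real_, n_obs = 0L,
                     status = "failed", message = msg)
    } else {
      dplyr::mutate(res, status = "ok", message = "")
    }
  })
  out <- dplyr::bind_rows(rows)
  if (all(out$status == "failed")) {
    stop(rlang::error_cnd(
      class = "cropclim_all_failed",
      message = paste0("every crop-variable fit failed; first error: ",
                       out$message[1])))
  }
  out
}

#' Write the consolidated effect table
#'
#' @param effects The tibble returned by [run_all()].
#' @param path Output CSV file.
#' @return Invisibly, `path`.
#' @export
write_effects <- function(effects, path) {
  utils::write.csv(as.data.frame(effects), path, row.names = FALSE)
  invisible(path)
}
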