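# split each chain column-vector into halves -> matrix [n/2, 2*chains]
split_chains <- function(cols) {
  n <- length(cols[[1]])
  half <- n %/% 2L
  mats <- lapply(cols, function(v) {
    cbind(v[seq_len(half)], v[(n - half + 1):n])
  })
  do.call(cbind, mats)
}

# potential scale reduction on split chains (draw matrix [n, m])
rhat_from_matrix <- function(sm) {
  n <- nrow(sm); m <- ncol(sm)
  if (n < 2L || m < 2L) return(NA_real_)
  means <- colMeans(sm)
  vars <- apply(sm, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# rank-normalise draws jointly across chains, preserving the layout
rank_normalize <- function(sm) {
  z <- stats::qnorm((rank(sm) - 3 / 8) / (length(sm) + 1 / 4))
  matrix(z, nrow(sm), ncol(sm))
}

# effective sample size of split chains via autocorrelations combined
# across chains, truncated by Geyer's initial monotone sequence
ess_from_matrix <- function(sm) {
  n <- nrow(sm); m <- ncol(sm)
  if (n < 4L) return(NA_real_)
  vars <- apply(sm, 2, stats::var)
  W <- mean(vars)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  B <- if (m > 1) n * stats::var(colMeans(sm)) else 0
  var_plus <- (n - 1) / n * W + B / n

  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(sm[, j], lag.max = n - 1, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus        # rho[1] is lag 0

  # Geyer: sum paired autocorrelations while positive and non-increasing
  max_pairs <- (n - 1) %/% 2L
  tau <- 1
  prev <- Inf
  for (k in seq_len(max_pairs)) {
    pair <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
  }
  max(min(m * n, m * n / tau), 1)
}

#' Summarise posterior draws
#'
#' Pools all chains for posterior means, standard deviations and central
#' 95% quantiles, and computes per-parameter convergence diagnostics:
#' split-R-hat (each chain split in half before computing the potential
#' scale reduction) and a rank-based effective sample size (autocovariance
#' of rank-normalised split chains, truncated by Geyer's initial monotone
#' sequence). With a single chain R-hat is reported as `NA`, not 1.
#'
#' @param draws A `posterior_draws` object from [sample_posterior()].
#' @return A tibble of class `posterior_summary` with columns
#'   `parameter`, `mean`, `sd`, `q2.5`, `q97.5`, `rhat`, `ess`.
#' @export
summarize_draws <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  pars <- colnames(draws$chains[[1]])
  n <- nrow(draws$chains[[1]])
  multi <- length(draws$chains) >= 2 && n >= 4

  rows <- lapply(pars, function(p) {
    cols <- lapply(draws$chains, function(m) m[, p])
    pooled <- unlist(cols, use.names = FALSE)
    if (multi) {
      sm <- split_chains(cols)
      rhat <- rhat_from_matrix(sm)
      ess <- if (stats::sd(pooled) > 0) ess_from_matrix(rank_normalize(sm))
             else NA_real_
    } else {
      rhat <- NA_real_
      ess <- NA_real_
    }
    tibble::tibble(parameter = p,
                   mean = mean(pooled),
                   sd = stats::sd(pooled),
                   q2.5 = unname(stats::quantile(pooled, 0.025)),
                   q97.5 = unname(stats::quantile(pooled, 0.975)),
                   rhat = rhat,
                   ess = ess)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("posterior_summary", class(out))
  out
}

#' Write a posterior summary as CSV
#'
#' @param summary A `posterior_summary` tibble.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}
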