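#' MCMC sampler configuration
#'
#' Settings of the Metropolis-within-Gibbs sampler. The location
#' parameters are updated by Metropolized independence proposals drawn
#' from a local Gaussian (conditional-Laplace) approximation of each
#' full conditional, so there are no proposal step sizes to tune: the
#' proposals scale themselves to the data, which matters because
#' compounding growth makes production counts span many orders of
#' magnitude across municipalities.
#'
#' @param n_chains Number of independent chains (default 4).
#' @param n_warmup,n_samples Warmup and retained iterations per chain.
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param init_jitter_sd Scale of the Gaussian jitter applied to each
#'   chain's starting values, in units of each parameter's approximate
#'   conditional posterior sd (overdispersed initialisation).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_warmup = 2000, n_samples = 2000,
                        seed = 1L, init_jitter_sd = 0.5) {
  stopifnot(n_chains >= 1, n_warmup >= 1, n_samples >= 1,
            init_jitter_sd >= 0)
  structure(
    list(n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
         n_samples = as.integer(n_samples), seed = as.integer(seed),
         init_jitter_sd = init_jitter_sd),
    class = "mcmc_config"
  )
}

#' Conjugate Gibbs draw for a random-effect precision
#'
#' The full conditional of a Gaussian random-effect precision under a
#' Gamma(a, b) prior is again Gamma. For an iid effect of length k the
#' sufficient statistic is `q = sum(effects^2)`; for a first-order random
#' walk it is the sum of squared successive differences with k equal to
#' the number of increments (length - 1). The draw comes from
#' `Gamma(a + k / 2, rate = b + q / 2)` using R's current RNG stream.
#'
#' @param effects Numeric vector of random-effect values.
#' @param kind `"iid"` or `"rw1"`.
#' @param prior A [prior_config()].
#' @return One positive draw.
#' @export
gibbs_update_precision <- function(effects, kind = c("iid", "rw1"), prior) {
  kind <- match.arg(kind)
  stopifnot(inherits(prior, "prior_config"), length(effects) >= 1)
  if (kind == "iid") {
    k <- length(effects)
    q <- sum(effects^2)
  } else {
    if (length(effects) < 2) {
      stop("a random-walk precision needs at least 2 effect values",
           call. = FALSE)
    }
    k <- length(effects) - 1L
    q <- sum(diff(effects)^2)
  }
  stats::rgamma(1, shape = prior$hyper_shape + k / 2,
                rate = prior$hyper_rate + q / 2)
}

# --- conditional-Laplace proposal machinery -------------------------------
#
# Every location update below is a Metropolized independence proposal
# drawn from a local Gaussian approximation of the parameter's full
# conditional (mode by Newton, sd from the curvature, inflated slightly
# so the proposal dominates the target's tails). Unlike tuned random
# walks, these proposals are self-scaling: the same code mixes well
# whether a cell holds fifty tons or fifty million, which matters
# because compounding growth makes synthetic (and real) production
# spans enormous.

# vectorised Newton solve of S - B*exp(g) - prec*g + lin = 0 (the score
# of a Poisson log-link conditional with a Gaussian prior); convex, so
# plain Newton with a couple of safeguards suffices
cond_mode_poisson <- function(g, S, B, prec, lin = 0) {
  for (k in 1:12) {
    Beg <- B * exp(g)
    f <- S - Beg - prec * g + lin
    fp <- Beg + prec
    step <- f / fp
    step <- pmax(pmin(step, 2), -2)
    g <- g + step
    if (max(abs(step)) < 1e-10) break
  }
  list(mode = g, sd = 1 / sqrt(B * exp(g) + prec))
}

# one full Metropolis-within-Gibbs chain; RNG state is the caller's
# responsibility
run_chain <- function(data, prior, config, store_effects = TRUE,
                      include_effects = TRUE) {
  y <- data$y; eps <- data$offset_eps; x <- data$x
  mi <- data$muni_index; yi <- data$year_index
  N <- data$N; Tn <- data$T
  n <- length(y)
  p0 <- prior$fixed_effect_precision
  a0 <- prior$hyper_shape; b0 <- prior$hyper_rate
  sumY <- sum(y)
  Sy_muni <- as.vector(rowsum(y, mi))          # ordered by index 1..N
  Sy_year <- as.vector(rowsum(y, yi))

  # conditional posterior scales, used to size the overdispersed init
  # jitter — with counts this large the posterior is far tighter than O(1)
  sc_a <- 1 / sqrt(sumY + 1)
  sc_b <- 1 / sqrt(sum(y * x^2) + 1)
  sc_g <- 1 / sqrt(Sy_muni + 1)
  sc_d <- 1 / sqrt(mean(Sy_year) + 1)

  # covariate decomposition for the ridge update: the municipality-mean
  # and year-mean components of x are absorbed by gamma and delta, so
  # only the double-centred residual identifies beta on its own
  mbar <- as.vector(rowsum(x, mi)) / tabulate(mi, N)
  xbar <- as.vector(rowsum(x, yi)) / tabulate(yi, Tn)
  mx <- mean(x)
  xt <- x - mbar[mi] - xbar[yi] + mx
  cg <- -(mbar - mx); cd <- -(xbar - mx); ca <- -mx
  dcd <- diff(cd)
  Syxt <- sum(y * xt)

  # moment-based warm start: empirical log-rates per unit, recentred,
  # plus an unweighted least-squares step for beta (on the log scale the
  # residual noise is roughly homoskedastic; count weighting would let
  # one huge municipality's idiosyncratic year pattern alias into the
  # slope)
  eps_muni <- as.vector(rowsum(eps, mi))
  eps_year <- as.vector(rowsum(eps, yi))
  alpha0 <- log((sumY + 1) / sum(eps))
  gamma0 <- log((Sy_muni + 1) / eps_muni) - alpha0
  gamma0 <- gamma0 - mean(gamma0)
  delta0 <- log((Sy_year + 1) / eps_year) - alpha0
  delta0 <- delta0 - mean(delta0)
  r0 <- log((y + 0.5) / eps) - alpha0
  if (include_effects) {
    r0 <- r0 - gamma0[mi] - delta0[yi]
    beta0 <- sum(r0 * xt) / (sum(xt^2) + 1e-12)
  } else {
    beta0 <- sum(r0 * x) / (sum(x^2) + 1e-12)
  }
  # the moment starts for gamma/delta already absorbed beta's mean
  # components; shift them out so beta0 * x is not double counted
  gamma0 <- gamma0 + beta0 * cg
  delta0 <- delta0 + beta0 * cd - mean(delta0 + beta0 * cd)
  alpha0 <- alpha0 + beta0 * ca

  jit <- 10 * config$init_jitter_sd
  for (attempt in 1:20) {
    alpha <- alpha0 + stats::rnorm(1, 0, jit * sc_a)
    beta <- beta0 + stats::rnorm(1, 0, jit * sc_b)
    gamma <- gamma0 + stats::rnorm(N, 0, jit * sc_g)
    delta <- delta0 + stats::rnorm(Tn, 0, jit * sc_d)
    delta <- delta - mean(delta)
    if (!include_effects) {
      gamma <- numeric(N); delta <- numeric(Tn)
    }
    lam <- eps * exp(alpha + gamma[mi] + delta[yi] + beta * x)
    if (all(is.finite(lam)) && all(lam > 0)) break
    if (attempt == 20) stop("could not find a finite starting point",
                            call. = FALSE)
  }
  tau_gamma <- 1
  tau_delta <- 1
  sumLam <- sum(lam)

  # proposal-sd inflation so the independence proposals dominate the
  # conditional's tails
  infl <- 1.2

  n_iter <- config$n_warmup + config$n_samples
  n_par <- 4L + if (store_effects) N + Tn else 0L
  draws <- matrix(NA_real_, config$n_samples, n_par)

  for (iter in seq_len(n_iter)) {

    # --- alpha: conditional-Laplace independence update (O(1) given the
    # cached sum of Poisson means)
    Ba <- sumLam * exp(-alpha)
    prop <- cond_mode_poisson(alpha, sumY, Ba, p0)
    s_a <- infl * prop$sd
    anew <- stats::rnorm(1, prop$mode, s_a)
    dlog <- sumY * (anew - alpha) - Ba * (exp(anew) - exp(alpha)) -
      p0 / 2 * (anew^2 - alpha^2) +
      ((anew - prop$mode)^2 - (alpha - prop$mode)^2) / (2 * s_a^2)
    if (log(stats::runif(1)) < dlog) {
      lam <- lam * exp(anew - alpha)
      sumLam <- sumLam * exp(anew - alpha)
      alpha <- anew
    }

    # --- beta: conditional Newton (a few O(n) score/curvature passes),
    # then a Metropolized independence draw from the local Gaussian
    eta_nb <- log(lam) - beta * x      # log lam with beta removed
    bmode <- beta
    for (k in 1:6) {
      lamb <- exp(eta_nb + bmode * x)
      sc <- sum((y - lamb) * x) - p0 * bmode
      cv <- sum(lamb * x^2) + p0
      step <- sc / cv
      bmode <- bmode + pmax(pmin(step, 2), -2)
      if (abs(step) < 1e-12) break
    }
    cv <- sum(exp(eta_nb + bmode * x) * x^2) + p0
    s_b <- infl / sqrt(cv)
    bnew <- stats::rnorm(1, bmode, s_b)
    lamnew <- exp(eta_nb + bnew * x)
    dlog <- (bnew - beta) * sum(y * x) - (sum(lamnew) - sumLam) -
      p0 / 2 * (bnew^2 - beta^2) +
      ((bnew - bmode)^2 - (beta - bmode)^2) / (2 * s_b^2)
    if (log(stats::runif(1)) < dlog) {
      beta <- bnew
      lam <- lamnew
      sumLam <- sum(lam)
    }

    if (include_effects) {
      # --- ridge move: shift beta along the direction the random
      # effects absorb (compensating gamma, delta, alpha so the linear
      # predictor changes only through the double-centred covariate);
      # without it beta and the year effects share a narrow ridge
      dpen <- diff(delta)
      P1 <- function(t) {                    # d/dt of the prior penalty
        p0 * (beta + t) + p0 * ca * (alpha + t * ca) +
          tau_gamma * sum(cg * (gamma + t * cg)) +
          tau_delta * sum(dcd * (dpen + t * dcd))
      }
      P2 <- p0 * (1 + ca^2) + tau_gamma * sum(cg^2) + tau_delta * sum(dcd^2)
      tmode <- 0
      for (k in 1:6) {
        lamt <- lam * exp(tmode * xt)
        sc <- sum((y - lamt) * xt) - P1(tmode)
        cv <- sum(lamt * xt^2) + P2
        step <- sc / cv
        tmode <- tmode + pmax(pmin(step, 2), -2)
        if (abs(step) < 1e-12) break
      }
      cv <- sum(lam * exp(tmode * xt) * xt^2) + P2
      s_r <- infl / sqrt(cv)
      tprop <- stats::rnorm(1, tmode, s_r)
      fac <- exp(tprop * xt)
      newSum <- sum(lam * fac)
      dlog <- tprop * Syxt - (newSum - sumLam) -
        p0 / 2 * ((beta + tprop)^2 - beta^2) -
        p0 / 2 * ((alpha + tprop * ca)^2 - alpha^2) -
        tau_gamma / 2 * (sum((gamma + tprop * cg)^2) - sum(gamma^2)) -
        tau_delta / 2 * (sum((dpen + tprop * dcd)^2) - sum(dpen^2)) +
        ((tprop - tmode)^2 - tmode^2) / (2 * s_r^2)
      if (log(stats::runif(1)) < dlog) {
        beta <- beta + tprop
        alpha <- alpha + tprop * ca
        gamma <- gamma + tprop * cg
        delta <- delta + tprop * cd
        lam <- lam * fac
        sumLam <- newSum
      }

      # --- gamma: conditionally independent across municipalities, so
      # all N conditional-Laplace updates run vectorised
      G <- as.vector(rowsum(lam, mi))
      Bg <- G * exp(-gamma)
      prop <- cond_mode_poisson(gamma, Sy_muni, Bg, tau_gamma)
      s_g <- infl * prop$sd
      gnew <- stats::rnorm(N, prop$mode, s_g)
      dlog <- Sy_muni * (gnew - gamma) - Bg * (exp(gnew) - exp(gamma)) -
        tau_gamma / 2 * (gnew^2 - gamma^2) +
        ((gnew - prop$mode)^2 - (gamma - prop$mode)^2) / (2 * s_g^2)
      acc <- log(stats::runif(N)) < dlog
      if (any(acc)) {
        dgam <- ifelse(acc, gnew - gamma, 0)
        gamma <- gamma + dgam
        lam <- lam * exp(dgam[mi])
        sumLam <- sum(lam)
      }

      # non-stochastic recentring: move mean(gamma) into alpha (the
      # linear predictor, hence lam, is unchanged)
      mg <- mean(gamma)
      gamma <- gamma - mg
      alpha <- alpha + mg

      # --- delta: checkerboard conditional-Laplace updates (years of
      # one parity are conditionally independent given the other parity
      # under the RW1 prior), then the sum-to-zero constraint is
      # re-imposed by projecting the mean into alpha
      dd_all <- numeric(Tn)
      L <- as.vector(rowsum(lam, yi))
      for (par in 0:1) {
        idx <- which(seq_len(Tn) %% 2L == par)
        nb_prec <- (idx > 1) + (idx < Tn)           # RW1 neighbour count
        nb_sum <- ifelse(idx > 1, delta[pmax(idx - 1L, 1L)], 0) +
          ifelse(idx < Tn, delta[pmin(idx + 1L, Tn)], 0)
        cur <- delta[idx]
        Bd <- L[idx] * exp(-cur)
        prop <- cond_mode_poisson(cur, Sy_year[idx], Bd,
                                  tau_delta * nb_prec,
                                  lin = tau_delta * nb_sum)
        s_d <- infl * prop$sd
        dnew <- stats::rnorm(length(idx), prop$mode, s_d)
        dlog <- Sy_year[idx] * (dnew - cur) - Bd * (exp(dnew) - exp(cur)) -
          tau_delta / 2 * (nb_prec * (dnew^2 - cur^2) -
                             2 * nb_sum * (dnew - cur)) +
          ((dnew - prop$mode)^2 - (cur - prop$mode)^2) / (2 * s_d^2)
        acc <- log(stats::runif(length(idx))) < dlog
        delta[idx[acc]] <- dnew[acc]
        dd_all[idx[acc]] <- dnew[acc] - cur[acc]
      }
      if (any(dd_all != 0)) {
        lam <- lam * exp(dd_all[yi])
        sumLam <- sum(lam)
      }
      md <- mean(delta)
      delta <- delta - md
      alpha <- alpha + md

      # --- conjugate Gibbs draws for the precisions
      tau_gamma <- stats::rgamma(1, a0 + N / 2,
                                 rate = b0 + sum(gamma^2) / 2)
      tau_delta <- stats::rgamma(1, a0 + (Tn - 1) / 2,
                                 rate = b0 + sum(diff(delta)^2) / 2)
    }

    # refresh the cached Poisson means periodically to stop fp drift
    if (iter %% 250L == 0L) {
      lam <- eps * exp(alpha + gamma[mi] + delta[yi] + beta * x)
      sumLam <- sum(lam)
    }

    if (iter > config$n_warmup) {
      row <- iter - config$n_warmup
      if (store_effects) {
        draws[row, ] <- c(alpha, beta, tau_gamma, tau_delta, gamma, delta)
      } else {
        draws[row, ] <- c(alpha, beta, tau_gamma, tau_delta)
      }
    }
  }

  colnames(draws) <- c(
    "alpha", "beta", "tau_gamma", "tau_delta",
    if (store_effects) c(paste0("gamma[", seq_len(N), "]"),
                         paste0("delta[", seq_len(Tn), "]")))
  draws
}

#' Sample the model posterior by Metropolis-within-Gibbs
#'
#' Runs independent chains of a Metropolis-within-Gibbs sampler for the
#' hierarchical Poisson production model. Per iteration: Metropolized
#' independence updates for the intercept and the covariate effect, each
#' proposed from a local Gaussian approximation of its full conditional
#' (mode by Newton, sd from the curvature); a joint "ridge" update that
#' moves the covariate effect while compensating the intercept and both
#' random effects for the covariate components they can absorb (the
#' municipality-mean and year-mean parts of x), which de-correlates the
#' otherwise nearly confounded covariate and year effects; vectorised
#' conditional-Laplace updates for the municipality effects
#' (conditionally independent given the rest); checkerboard
#' conditional-Laplace updates for the year effects (one parity at a
#' time is conditionally independent under the RW1 prior) with the
#' sum-to-zero constraint re-imposed by projecting the mean into the
#' intercept; exact conjugate Gibbs draws for the two precisions; and a
#' deterministic recentring that moves the mean of the municipality
#' effects into the intercept. Every Metropolis ratio includes the
#' proposal-density correction, so each update leaves the exact
#' posterior invariant. The run is fully deterministic given
#' `config$seed` (chains are run sequentially from a single seeded
#' stream).
#'
#' @param data A `model_data` object from [build_design()].
#' @param prior A [prior_config()].
#' @param config An [mcmc_config()].
#' @param store_effects Keep per-municipality and per-year effect draws
#'   (set `FALSE` to save memory on large designs).
#' @param include_effects If `FALSE`, fit the fixed-effects-only model
#'   (no municipality or year effects) — mainly a validation harness.
#' @return Object of class `posterior_draws`: list with `chains` (one
#'   draw matrix per chain, iterations in rows, parameters in columns),
#'   `N`, `T`, and the configs used.
#' @export
sample_posterior <- function(data, prior = prior_config(),
                             config = mcmc_config(),
                             store_effects = TRUE,
                             include_effects = TRUE) {
  stopifnot(inherits(data, "model_data"), inherits(prior, "prior_config"),
            inherits(config, "mcmc_config"))
  if (length(data$y) == 0L) stop("empty model data", call. = FALSE)
  chains <- with_seed(config$seed, {
    lapply(seq_len(config$n_chains), function(ch) {
      run_chain(data, prior, config, store_effects = store_effects,
                include_effects = include_effects)
    })
  })
  structure(
    list(chains = chains, N = data$N, T = data$T,
         include_effects = include_effects,
         prior = prior, config = config,
         crop = data$crop, variable = data$variable),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d chains x %d draws, %d parameters\n",
              length(x$chains), nrow(x$chains[[1]]), ncol(x$chains[[1]])))
  invisible(x)
}

#' Write posterior draws as CSV
#'
#' One row per retained draw with a `chain` id column and one column per
#' parameter.
#'
#' @param draws A `posterior_draws` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  tabs <- lapply(seq_along(draws$chains), function(ch) {
    cbind(chain = ch, as.data.frame(draws$chains[[ch]]))
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}
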