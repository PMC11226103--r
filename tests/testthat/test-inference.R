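test_that("precision full conditionals match the closed-form Gamma", {
  prior <- prior_config()   # shape 1, rate 5e-5
  ks_crit <- 1.628 / sqrt(10000)  # 1% critical value, n = 10,000

  cases <- list(
    list(effects = c(1, -1, 0, 0),                           kind = "iid"),
    list(effects = rnorm(50) * 0.3,                          kind = "iid"),
    list(effects = cumsum(rnorm(12, 0, 0.5)),                kind = "rw1"),
    list(effects = c(0, 0, 0, 0),                            kind = "iid"),
    list(effects = seq(0, 1, length.out = 6),                kind = "rw1"))
  set.seed(202)
  for (cs in cases) {
    if (cs$kind == "iid") {
      k <- length(cs$effects); q <- sum(cs$effects^2)
    } else {
      k <- length(cs$effects) - 1; q <- sum(diff(cs$effects)^2)
    }
    draws <- replicate(10000, gibbs_update_precision(cs$effects, cs$kind,
                                                     prior))
    ks <- suppressWarnings(ks.test(
      draws, pgamma, shape = prior$hyper_shape + k / 2,
      rate = prior$hyper_rate + q / 2))
    expect_lt(unname(ks$statistic), ks_crit)
  }
})

test_that("zero effects reduce the conditional to the prior-plus-count form", {
  prior <- prior_config(hyper_shape = 2, hyper_rate = 0.5)
  set.seed(5)
  draws <- replicate(5000, gibbs_update_precision(rep(0, 6), "iid", prior))
  ks <- suppressWarnings(ks.test(draws, pgamma, shape = 2 + 3, rate = 0.5))
  expect_lt(unname(ks$statistic), 1.628 / sqrt(5000))
  expect_error(gibbs_update_precision(1, "rw1", prior), "at least 2")
})

test_that("the sampler is deterministic given its seed", {
  sd1 <- small_sim_design(n_muni = 6, n_years = 4, seed = 2)
  cfg <- mcmc_config(n_chains = 2, n_warmup = 100, n_samples = 100, seed = 42)
  d1 <- sample_posterior(sd1$data, prior_config(), cfg)
  d2 <- sample_posterior(sd1$data, prior_config(), cfg)
  expect_identical(d1$chains, d2$chains)
  d3 <- sample_posterior(sd1$data, prior_config(),
                         mcmc_config(n_chains = 2, n_warmup = 100,
                                     n_samples = 100, seed = 43))
  expect_false(identical(d1$chains, d3$chains))
})

test_that("the intercept-only sampler agrees with the Laplace mode", {
  set.seed(17)
  n <- 40
  eps <- sample(50:500, n, TRUE)
  y <- rpois(n, eps * exp(0.08))
  d <- make_model_data(y, eps, x = rep(0, n), mi = rep(1, n), yi = rep(1, n))
  prior <- prior_config()
  dr <- sample_posterior(d, prior, mcmc_config(n_chains = 2, n_warmup = 300,
                                               n_samples = 700, seed = 9),
                         include_effects = FALSE)
  s <- summarize_draws(dr)
  a <- s[s$parameter == "alpha", ]
  lf <- laplace_fit(d, prior, include_effects = FALSE)
  mcse <- a$sd / sqrt(a$ess)
  expect_lt(abs(a$mean - lf$alpha), 2 * mcse + 0.02 * lf$sd_alpha)
  expect_equal(a$sd, lf$sd_alpha, tolerance = 0.2)
})

test_that("chains reach convergence diagnostics on a default instance", {
  sd1 <- small_sim_design(n_muni = 15, n_years = 6, seed = 31)
  dr <- sample_posterior(sd1$data, prior_config(),
                         mcmc_config(n_chains = 4, n_warmup = 400,
                                     n_samples = 400, seed = 77),
                         store_effects = FALSE)
  s <- summarize_draws(dr)
  expect_lt(s$rhat[s$parameter == "alpha"], 1.05)
  expect_lt(s$rhat[s$parameter == "beta"], 1.05)
  expect_true(all(s$q2.5 <= s$q97.5))
  # precision draws are strictly positive
  expect_true(all(sapply(dr$chains, function(m) all(m[, "tau_gamma"] > 0))))
  # every stored delta draw respects the sum-to-zero constraint
  dsum <- sapply(dr$chains, function(m) {
    max(abs(rowSums(m[, grep("^delta", colnames(m)), drop = FALSE])))
  })
  expect_lt(max(dsum), 1e-8)
})

test_that("a single-run credible interval covers the generating effect", {
  sd1 <- small_sim_design(n_muni = 40, n_years = 8, beta_true = 0.025,
                          seed = 55)
  dr <- sample_posterior(sd1$data, prior_config(),
                         mcmc_config(n_chains = 4, n_warmup = 500,
                                     n_samples = 500, seed = 56),
                         store_effects = FALSE)
  b <- summarize_draws(dr) |> dplyr::filter(parameter == "beta")
  expect_lte(b$q2.5, 0.025)
  expect_gte(b$q97.5, 0.025)
})

test_that("the Laplace engine honours its stationarity conditions", {
  # no observations: the Gaussian prior centres the mode at zero
  d0 <- make_model_data(numeric(0), numeric(0), numeric(0), integer(0),
                        integer(0))
  d0$N <- 2L; d0$T <- 3L
  lf0 <- laplace_fit(d0, prior_config())
  expect_equal(lf0$alpha, 0)
  expect_equal(lf0$beta, 0)
  expect_equal(lf0$delta, rep(0, 3))

  # single observation, intercept only: y - eps exp(a) - prec a = 0
  d1 <- make_model_data(y = round(exp(1) * 40), eps = 40, x = 0, mi = 1,
                        yi = 1)
  prior <- prior_config(fixed_effect_precision = 0.5)
  lf1 <- laplace_fit(d1, prior, include_effects = FALSE)
  resid <- d1$y - d1$offset_eps * exp(lf1$alpha) - 0.5 * lf1$alpha
  expect_lt(abs(resid), 1e-4 * d1$y)
})

test_that("MCMC and Laplace agree on a small synthetic instance", {
  sd1 <- small_sim_design(n_muni = 20, n_years = 5, seed = 71)
  dr <- sample_posterior(sd1$data, prior_config(),
                         mcmc_config(n_chains = 4, n_warmup = 500,
                                     n_samples = 500, seed = 72),
                         store_effects = FALSE)
  b <- summarize_draws(dr) |> dplyr::filter(parameter == "beta")
  lf <- laplace_fit(sd1$data, prior_config())
  expect_lt(abs(lf$beta - b$mean), 0.5 * lf$sd_beta)
})

test_that("posterior summaries follow their sort-based oracles", {
  # degenerate constant chains
  const <- structure(list(
    chains = list(matrix(3.5, 10, 1, dimnames = list(NULL, "alpha")),
                  matrix(3.5, 10, 1, dimnames = list(NULL, "alpha"))),
    N = 0L, T = 0L), class = "posterior_draws")
  s <- summarize_draws(const)
  expect_equal(s$mean, 3.5)
  expect_equal(s$sd, 0)

  # pooled quantiles are permutation invariant and match a full sort
  set.seed(88)
  v <- rnorm(1000)
  mk <- function(vec) structure(list(
    chains = list(matrix(vec[1:500], 500, 1,
                         dimnames = list(NULL, "alpha")),
                  matrix(vec[501:1000], 500, 1,
                         dimnames = list(NULL, "alpha"))),
    N = 0L, T = 0L), class = "posterior_draws")
  s1 <- summarize_draws(mk(v))
  s2 <- summarize_draws(mk(sample(v)))
  expect_equal(s1[c("mean", "sd", "q2.5", "q97.5")],
               s2[c("mean", "sd", "q2.5", "q97.5")])
  expect_equal(s1$q2.5, unname(quantile(v, 0.025)))
  expect_equal(s1$q97.5, unname(quantile(v, 0.975)))
  expect_lte(s1$ess, 1000)

  # a single chain reports R-hat as unavailable
  single <- structure(list(
    chains = list(matrix(rnorm(100), 100, 1,
                         dimnames = list(NULL, "alpha"))),
    N = 0L, T = 0L), class = "posterior_draws")
  expect_true(is.na(summarize_draws(single)$rhat))
})

test_that("draws persist to CSV with chain identifiers", {
  sd1 <- small_sim_design(n_muni = 4, n_years = 3, seed = 14)
  dr <- sample_posterior(sd1$data, prior_config(),
                         mcmc_config(n_chains = 2, n_warmup = 50,
                                     n_samples = 50, seed = 15))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(dr, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 100)
  expect_equal(sort(unique(tab$chain)), c(1, 2))
  expect_true(all(c("alpha", "beta", "tau_gamma") %in% names(tab)))
})
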