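toy_climate <- function(codes, years, temp = 20) {
  tidyr::expand_grid(municipality_code = codes, year = years) |>
    dplyr::mutate(avg_temperature = temp)
}

test_that("build_design pairs lagged offsets and drops dead rows", {
  panel <- tibble::tibble(
    municipality_code = "00001", year = 2007:2010, crop = "rice",
    production = c(100, 110, 0, 5))
  d <- build_design(panel, toy_climate("00001", 2007:2010), "rice",
                    "avg_temperature")
  expect_equal(d$y, c(110, 0))
  expect_equal(d$offset_eps, c(100, 110))
  expect_equal(length(d$y), 2L)

  single <- panel[1, ]
  expect_error(
    build_design(single, toy_climate("00001", 2007), "rice",
                 "avg_temperature"),
    "no estimable data")
})

test_that("a gap in years breaks the lag chain", {
  panel <- tibble::tibble(
    municipality_code = "00001", year = c(2007, 2009, 2010), crop = "rice",
    production = c(100, 200, 210))
  d <- build_design(panel, toy_climate("00001", 2007:2010), "rice",
                    "avg_temperature")
  # only 2009 -> 2010 is a consecutive pair
  expect_equal(d$y, 210)
  expect_equal(d$offset_eps, 200)
})

test_that("an all-positive cross consumes one year per series as offset", {
  codes <- sprintf("%05d", 1:5)
  panel <- tidyr::expand_grid(municipality_code = codes, year = 2007:2010,
                              crop = c("rice", "corn"))
  panel$production <- 100 + seq_len(nrow(panel))
  clim <- toy_climate(codes, 2007:2010)
  n_rows <- sapply(c("rice", "corn"), function(cr) {
    length(build_design(panel, clim, cr, "avg_temperature")$y)
  })
  expect_equal(unname(n_rows), c(15, 15))  # 5 municipalities x (4 - 1) years
})

test_that("missing covariate cells are dropped, missing column rejected", {
  panel <- tibble::tibble(
    municipality_code = "00001", year = 2007:2010, crop = "rice",
    production = c(100, 110, 120, 130))
  clim <- toy_climate("00001", 2007:2010)
  clim$avg_temperature[clim$year == 2009] <- NA
  d <- build_design(panel, clim, "rice", "avg_temperature")
  expect_equal(d$y, c(110, 130))
  expect_error(build_design(panel, clim, "rice", "precipitation"),
               "no estimable data.*precipitation")
})

test_that("compute_rates reproduces the linear predictor arithmetic", {
  d <- make_model_data(y = c(5, 7), eps = c(10, 20), x = c(5, 0),
                       mi = c(1, 1), yi = c(1, 2))
  p0 <- zero_params(1, 2)
  r <- compute_rates(d, p0)
  expect_equal(r$rho, c(1, 1))
  expect_equal(r$lam, c(10, 20))

  p <- model_params(alpha = 0.1, beta = 0.02, gamma = -0.05,
                    delta = c(0.03, -0.03), tau_gamma = 1, tau_delta = 1)
  r <- compute_rates(d, p)
  expect_equal(r$eta[1], 0.1 - 0.05 + 0.03 + 0.02 * 5)
  expect_equal(r$rho[1], exp(0.18))
  expect_equal(log(r$rho), r$eta)
})

test_that("eta depends on alpha, gamma, delta only through their sum", {
  set.seed(5)
  d <- make_model_data(y = rpois(20, 50), eps = rep(50, 20),
                       x = rnorm(20), mi = rep(1:4, 5), yi = rep(1:5, 4))
  p1 <- model_params(0.3, 0.1, rnorm(4), {z <- rnorm(5); z - mean(z)}, 2, 3)
  cshift <- 0.17
  p2 <- model_params(p1$alpha + cshift, p1$beta, p1$gamma - cshift,
                     p1$delta, 2, 3)
  expect_equal(compute_rates(d, p1)$eta, compute_rates(d, p2)$eta,
               tolerance = 1e-12)
})

test_that("log_likelihood equals hand-computed Poisson log-pmfs", {
  d0 <- make_model_data(y = 0, eps = 1, x = 0, mi = 1, yi = 1)
  expect_equal(log_likelihood(d0, zero_params(1, 1)), -1)

  d1 <- make_model_data(y = 2, eps = 1, x = 0, mi = 1, yi = 1)
  p1 <- model_params(log(2), 0, 0, 0, 1, 1)
  expect_equal(log_likelihood(d1, p1), log(2) - 2, tolerance = 1e-12)
})

test_that("log_likelihood matches the dpois brute-force oracle", {
  set.seed(31)
  for (k in 1:25) {
    N <- sample(2:5, 1); Tn <- sample(2:4, 1); n <- sample(5:25, 1)
    d <- make_model_data(y = rpois(n, 30), eps = sample(10:200, n, TRUE),
                         x = rnorm(n), mi = sample(1:N, n, TRUE),
                         yi = sample(1:Tn, n, TRUE))
    d$N <- N; d$T <- Tn
    p <- model_params(rnorm(1, 0, 0.2), rnorm(1, 0, 0.1), rnorm(N, 0, 0.3),
                      {z <- rnorm(Tn, 0, 0.2); z - mean(z)},
                      rexp(1) + 0.1, rexp(1) + 0.1)
    lam <- compute_rates(d, p)$lam
    expect_equal(log_likelihood(d, p), sum(dpois(d$y, lam, log = TRUE)),
                 tolerance = 1e-10)
  }
})

test_that("dimension mismatches are rejected", {
  d <- make_model_data(y = c(1, 2), eps = c(3, 4), x = c(0, 0),
                       mi = c(1, 2), yi = c(1, 1))
  expect_error(log_likelihood(d, zero_params(1, 1)), "dimensions")
})

test_that("the RW1 prior penalises exactly its quadratic increments", {
  prior <- prior_config()
  base <- model_params(0, 0, numeric(0), c(0, 0, 0), 1, 1)
  rough <- model_params(0, 0, numeric(0), c(0, 1, -1), 1, 1)
  # flat walk has zero penalty, so the difference is the stated -2.5
  expect_equal(log_prior(rough, prior) - log_prior(base, prior), -2.5,
               tolerance = 1e-12)
})

test_that("the iid effect prior matches independent normal densities", {
  set.seed(8)
  g <- rnorm(15)
  prior <- prior_config()
  with_g <- model_params(0, 0, g, c(0, 0), 1, 1)
  without <- model_params(0, 0, numeric(0), c(0, 0), 1, 1)
  expect_equal(log_prior(with_g, prior) - log_prior(without, prior),
               sum(dnorm(g, log = TRUE)), tolerance = 1e-12)
})

test_that("log_prior grows smoother walks and rejects bad precisions", {
  prior <- prior_config()
  lp <- function(step) {
    d <- c(-step, 0, step)
    log_prior(model_params(0, 0, 0, d, 1, 1), prior)
  }
  vals <- sapply(c(0.1, 0.5, 1, 2), lp)
  expect_true(all(diff(vals) < 0))
  expect_error(model_params(0, 0, 0, c(0, 0), -1, 1), "positive")
  expect_error(model_params(0, 0, 0, c(0.5, 0), 1, 1), "sum to zero")
})

test_that("percent change transforms the log scale as the field reports it", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(log(2)), 100, tolerance = 1e-12)
  expect_equal(round(percent_change(log(1.0255)), 3), 2.55)
  # strictly increasing, and asymmetric about zero
  b <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(percent_change(b)) > 0))
  expect_false(isTRUE(all.equal(percent_change(-0.3),
                                -percent_change(0.3))))
})

test_that("fractional production is rounded with a warning", {
  panel <- tibble::tibble(
    municipality_code = "00001", year = 2007:2009, crop = "rice",
    production = c(100.4, 110.6, 120))
  expect_warning(
    d <- build_design(panel, toy_climate("00001", 2007:2009), "rice",
                      "avg_temperature"),
    "rounded")
  expect_equal(d$offset_eps, c(100, 111))
})
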