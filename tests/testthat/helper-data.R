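# small construction helpers shared across test files

# a model_data object built directly, bypassing build_design
make_model_data <- function(y, eps, x, mi, yi) {
  N <- max(mi, 0L)
  Tn <- max(yi, 0L)
  structure(
    list(y = as.numeric(y), offset_eps = as.numeric(eps),
         x = as.numeric(x), muni_index = as.integer(mi),
         year_index = as.integer(yi), N = as.integer(N), T = as.integer(Tn),
         municipalities = sprintf("%05d", seq_len(N)),
         years = seq(2007L, length.out = max(Tn, 1L)),
         crop = "rice", variable = "avg_temperature"),
    class = "model_data")
}

# long monthly climate rows for one municipality-year
monthly_rows <- function(code, year, values_by_var, months = 1:12) {
  do.call(rbind, lapply(names(values_by_var), function(v) {
    data.frame(municipality_code = code, year = year, month = months,
               variable = v, value = values_by_var[[v]])
  }))
}

# parameters with everything zero except what is supplied
zero_params <- function(N, Tn, alpha = 0, beta = 0,
                        gamma = rep(0, N), delta = rep(0, Tn),
                        tau_gamma = 1, tau_delta = 1) {
  model_params(alpha, beta, gamma, delta, tau_gamma, tau_delta)
}

# a quick low-count synthetic design for sampler tests: moderate
# production so chains are cheap and posteriors are not needle-thin
small_sim_design <- function(n_muni = 20, n_years = 5, beta_true = 0.025,
                             seed = 1, baseline = log(500)) {
  cfg <- sim_config(n_municipalities = n_muni, n_years = n_years,
                    beta_true = beta_true, baseline_log_mean = baseline,
                    seed = seed)
  truth <- simulate_panel(cfg)
  list(truth = truth,
       data = build_design(truth$panel, truth$climate, "rice",
                           "avg_temperature"))
}
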