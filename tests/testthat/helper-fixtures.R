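# Shared fixtures, built once per test run (lazily, cached in an env).
.fx <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# Noise-free corpus for exact parameter-recovery checks (k spread as wide as
# the shape dimension supports).
fx_corpus_exact <- function() memo("corpus_exact", function()
  generate_corpus(corpus_config(n_tables = 200, noise_sd = 0,
                                k_range = c(-1, 1), seed = 101)))

# Noisy corpus + the three calibrated systems (the analysis conditions).
fx_corpus <- function() memo("corpus", function()
  generate_corpus(corpus_config(n_tables = 200, noise_sd = 0.01, seed = 202)))

fx_systems <- function() memo("systems", function() {
  co <- fx_corpus()
  list(logquad = fit_logquad(co$tables),
       modlogit = build_standard(co$tables),
       family = suppressWarnings(fit_families(co$tables, K = 5, seed = 202)))
})

# China-like observed series (default study conditions).
fx_series <- function() memo("series", function()
  generate_china_like_series(series_config(seed = 303)))

# Residual records over all ten cases, by sex.
fx_residuals <- function(sex = "male") memo(paste0("residuals_", sex), function() {
  s <- fx_series()$series
  run_cases(fx_systems(), s[s$sex == sex, ])
})

# Truth coefficients wrapped as a fitted-coefficients object (the generative
# system itself, usable with predict_logquad / match_k).
fx_truth_coeffs <- function() memo("truth_coeffs", function() {
  tr <- default_logquad_truth()
  structure(list(grid = tr$grid, a = tr$a, b = tr$b, c = tr$c, v = tr$v,
                 sex = NA_character_,
                 calibration_meta = list(n_tables = 0L,
                                         q5_0_range = c(0.004, 0.09))),
            class = "logquad_coefficients")
})

# A small bundle of valid random m-schedules on the default grid.
random_m_schedules <- function(n, seed = 1) {
  set.seed(seed)
  tr <- default_logquad_truth()
  lapply(seq_len(n), function(i) {
    q5 <- exp(stats::runif(1, log(0.004), log(0.09)))
    k <- stats::runif(1, -0.5, 0.5)
    truth_rates_local(tr, q5, k) * 10^stats::rnorm(tr$grid$n_groups, 0, 0.05)
  })
}

truth_rates_local <- function(tr, q5, k) {
  x <- log10(q5)
  10^(tr$a + tr$b * x + tr$c * x^2 + tr$v * k)
}
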