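# mltsys — model life table systems and estimation-bias assessment

`mltsys` is an R package for building, calibrating and stress-testing
two-parameter **model life table systems** — the tools demographers and
epidemiologists use to predict a complete age schedule of mortality from one
or two summary indicators when full vital registration is unavailable.  It is
aimed at researchers who need to ask not just *what* such a system predicts,
but *how wrong* it becomes when a population's age pattern of mortality
departs from the calibration corpus.

Three systems are implemented on a shared abridged life table backbone
(0–1, 1–4, 5-year groups, open interval at 90+ or 100+):

* a **log-quadratic system**:
  log10(mx) = aₓ + bₓ·log10(₅q₀) + cₓ·log10(₅q₀)² + vₓ·k,
  fitted per age group by least squares with the shape vector v taken from
  the SVD of the residual matrix; k is matched to an observed ₄₅q₁₅ or e₀ by
  bisection on the monotone k-map;
* a **modified-logit relational system**: the logit of survivorship,
  Y(x) = ½·ln((1−l(x)/l₀)/(l(x)/l₀)), modelled as α + β·Ys(x) around a
  calibrated standard, with age-specific child and adult correction factors
  regressed from level-only residuals;
* a **discrete-family / continuous-level system**: K = 5 mortality-pattern
  families found by model-based clustering of residual log-rate profiles,
  each with its own one-dimensional level model, plus a ₄₅q₁₅-envelope
  diagnostic for observations outside the calibrated shape range.

Around them sits the assessment pipeline: the ten shorthand estimation cases
(W1–W3, M1–M3, C1, C2(level:5q0), C2(level:45q15), C3), per-year residuals
of 1q0, 5q0, 45q15, 20q60 and e0, average relative errors (ARE),
residual-sign bias classes ("+", "−", "−+", "+−", "0"), compound
mortality-decline trend statistics, and group comparisons across sexes,
populations and countries.  Synthetic-data generators supply HMD-like
calibration corpora and China-like observed series (geometric ₅q₀ decline,
female-higher-₅q₀ yet female-higher-e₀ crossover, deflated adult/old-age
pattern), so the whole pipeline is testable without external data.

## Worked example

```r
library(mltsys)

corpus  <- generate_corpus(corpus_config(n_tables = 200, noise_sd = 0.01, seed = 1))
systems <- list(logquad  = fit_logquad(corpus$tables),
                modlogit = build_standard(corpus$tables),
                family   = fit_families(corpus$tables, K = 5, seed = 1))

series <- generate_china_like_series(series_config(seed = 1))$series
male   <- series[series$sex == "male", ]

res <- run_cases(systems, male, cases = c("W1", "W2"))
summarize_are(res)
#>    case indicator are_percent  n
#> 1    W1        e0    3.54e+00 19
#> 2    W2        e0    7.88e-01 19
#> 3    W1      q1_0    7.45e-02 19
#> 4    W2      q1_0    3.43e-01 19
#> 5    W1    q20_60    2.86e+01 19
#> 6    W2    q20_60    1.52e+01 19
#> 7    W1    q45_15    3.86e+01 19
#> 8    W2    q45_15    7.35e-07 19
#> 9    W1      q5_0    0.00e+00 19
#> 10   W2      q5_0    0.00e+00 19
```

Reading this: the series was generated with adult and old-age death rates at
0.7 of what the calibration pattern implies at the same ₅q₀.  Driven by ₅q₀
alone (case W1), the system therefore overestimates adult mortality badly
(ARE 38.6% on ₄₅q₁₅, 28.6% on ₂₀q₆₀) and underestimates e₀ (3.5%); ₅q₀
itself is an exact input (ARE 0), and once ₄₅q₁₅ is supplied as the second
input (case W2) its ARE collapses to solver tolerance while the other errors
shrink.  The residual-sign classes make the direction explicit:

```r
classify_bias(res$residual[res$case == "W1" & res$indicator == "q45_15"])  # "+"
classify_bias(res$residual[res$case == "W1" & res$indicator == "e0"])      # "-"

trend_statistics(male$q5_0, male$e0, male$year)
#> decline 9.17 % per year, e0 gain 0.432 years per year, period 1994-2012
```

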