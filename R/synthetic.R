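#' @title Synthetic calibration corpora and observed series
#' @name synthetic_data
#' @description Generators producing data with the statistical structure the
#'   assessment pipeline assumes: a calibration corpus of abridged life
#'   tables spanning a wide 5q0 range (standing in for an HMD-like
#'   collection), and China-like observed annual series with geometrically
#'   declining under-five mortality, a female-higher-5q0 /
#'   female-higher-e0 crossover, and adult/old-age pattern deviations that
#'   induce the characteristic overestimation biases.  Every generator is
#'   deterministic given its seed.
NULL

#' Default generative log-quadratic truth
#'
#' A realistic coefficient set on the default 20-group grid: log10 death
#' rates at the reference level 5q0 = 0.01 follow a modern J-shaped
#' schedule; sensitivities to log10(5q0) are highest in childhood and decay
#' with age; a mild quadratic term; and a unit-norm adult-hump shape vector
#' v with no loading on the two child groups (the 1--4 group is constrained
#' by 5q0-exactness during generation and carries no independent shape).
#'
#' @param grid An [age_grid()] with `open_start = 90` (the default).
#' @return List with per-group vectors `a`, `b`, `c`, `v`, the `grid`, and
#'   `constrained_group = 2` (the 1--4 group, whose rates are solved from
#'   5q0 rather than taken from its coefficient row).
#' @export
default_logquad_truth <- function(grid = age_grid(90)) {
  stopifnot(grid$open_start == 90)
  # log10 m at reference h0 = log10(0.01) = -2
  r <- c(-2.09, -3.35, -3.66, -3.74, -3.35, -3.15, -3.10, -3.05, -2.92,
         -2.77, -2.60, -2.40, -2.22, -1.85, -1.65, -1.42, -1.19, -0.95,
         -0.72, -0.49)
  # d log10 m / d log10 5q0 at the reference level; the infant slope is
  # pinned near 1 so 1q0 tracks a roughly constant share of 5q0, and the
  # old-age slopes are damped (old-age mortality improves more slowly than
  # child mortality), keeping life expectancy at birth in the low 70s to
  # low 80s across the calibration range
  s <- c(1.00, 1.30, 1.10, 0.95, 0.80, 0.75, 0.70, 0.65, 0.60, 0.55,
         0.50, 0.45, 0.40, 0.30, 0.26, 0.21, 0.17, 0.14, 0.10, 0.07)
  # curvature in (h - h0)^2
  t2 <- c(0.02, 0.15, 0.12, 0.10, 0.08, 0.07, 0.06, 0.05, 0.05, 0.04,
          0.04, 0.03, 0.03, 0.02, 0.02, 0.01, 0.01, 0, 0, 0)
  h0 <- -2
  v <- c(0, 0, 0.02, 0.05, 0.15, 0.25, 0.30, 0.33, 0.35, 0.35, 0.33,
         0.30, 0.26, 0.22, 0.18, 0.14, 0.10, 0.07, 0.05, 0.03)
  v <- v / sqrt(sum(v^2))
  list(grid = grid,
       a = r - s * h0 + t2 * h0^2,
       b = s - 2 * t2 * h0,
       c = t2,
       v = v,
       constrained_group = 2L)
}

truth_rates <- function(truth, q5_0, k = 0) {
  x <- log10(q5_0)
  10^(truth$a + truth$b * x + truth$c * x^2 + truth$v * k)
}

#' Configuration for a synthetic calibration corpus
#'
#' @param n_tables Number of tables.
#' @param q5_range Endpoints of the log-uniform 5q0 sampling range
#'   (proportions in (0,1)).
#' @param truth Generative coefficient set, see [default_logquad_truth()].
#' @param k_range Uniform sampling bounds for the shape parameter k.  The
#'   default spread is kept narrower than the pattern deviations the observed
#'   series applies, so that a strongly deviated population can fall outside
#'   the calibrated systems' shape range (the condition the envelope
#'   diagnostic exists to detect).
#' @param noise_sd Per-age log10-rate noise standard deviation (>= 0).
#' @param family_profiles Optional K x n_groups matrix of additive
#'   log10-rate deviation profiles defining discrete mortality-pattern
#'   families.
#' @param family_weights Mixture weights over the K families (must sum
#'   to 1); default uniform.
#' @param seed Integer seed.
#' @return List of class `corpus_config`.
#' @export
corpus_config <- function(n_tables = 200, q5_range = c(0.005, 0.08),
                          truth = default_logquad_truth(),
                          k_range = c(-0.4, 0.4), noise_sd = 0,
                          family_profiles = NULL, family_weights = NULL,
                          seed = 1) {
  stopifnot(n_tables >= 0, all(q5_range > 0), all(q5_range < 1),
            q5_range[1] < q5_range[2], noise_sd >= 0)
  if (!is.null(family_profiles)) {
    family_profiles <- as.matrix(family_profiles)
    stopifnot(ncol(family_profiles) == truth$grid$n_groups)
    if (is.null(family_weights))
      family_weights <- rep(1 / nrow(family_profiles), nrow(family_profiles))
    stopifnot(length(family_weights) == nrow(family_profiles),
              abs(sum(family_weights) - 1) < 1e-12, all(family_weights >= 0))
  }
  structure(list(n_tables = n_tables, q5_range = q5_range, truth = truth,
                 k_range = k_range, noise_sd = noise_sd,
                 family_profiles = family_profiles,
                 family_weights = family_weights, seed = seed),
            class = "corpus_config")
}

#' Generate a synthetic calibration corpus with its truth record
#'
#' Each table draws a 5q0 (log-uniform) and a shape parameter k (uniform);
#' log10 rates come from the generative coefficients plus the optional
#' family deviation profile and Gaussian noise; the table is then assembled
#' so its 5q0 equals the sampled value exactly (the 1--4 group absorbs the
#' constraint, as in the system's own prediction path).  The same seed and
#' config reproduce the corpus bit for bit.
#'
#' @param config A [corpus_config()].
#' @return List with `tables` (list of `abridged_life_table`) and `truth`
#'   (the coefficient set plus a data frame of per-table `q5_0`, `k`,
#'   `family`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(config$seed)
  n <- config$n_tables
  tr <- config$truth
  ng <- tr$grid$n_groups
  if (n == 0)
    return(list(tables = list(),
                truth = list(coefficients = tr,
                             table = data.frame(id = integer(), q5_0 = numeric(),
                                                k = numeric(), family = integer())),
                config = config))
  lr <- log(config$q5_range)
  q5 <- exp(stats::runif(n, lr[1], lr[2]))
  k <- stats::runif(n, config$k_range[1], config$k_range[2])
  fam <- if (is.null(config$family_profiles)) rep(NA_integer_, n)
         else sample.int(nrow(config$family_profiles), n, replace = TRUE,
                         prob = config$family_weights)
  eps <- if (config$noise_sd > 0)
    matrix(stats::rnorm(n * ng, 0, config$noise_sd), n, ng)
  else matrix(0, n, ng)
  tables <- vector("list", n)
  for (i in seq_len(n)) {
    dev <- if (is.na(fam[i])) 0 else config$family_profiles[fam[i], ]
    m <- truth_rates(tr, q5[i], k[i]) * 10^(dev + eps[i, ])
    tables[[i]] <- assemble_exact_q5(m, q5[i], tr$grid,
                                     label = paste0("synthetic-", i))
  }
  # Identifiable ("effective") stage-1 coefficients: the component of the
  # sampled k vector lying in the span of the regression design is absorbed
  # into the quadratic along the v direction, so the two-stage fit recovers
  # a_eff, b_eff, c_eff and the orthogonalised k_eff -- not the raw draws.
  x <- log10(q5)
  X <- cbind(1, x, x^2)
  gam <- if (length(unique(signif(x, 12))) >= 4)
    stats::lm.fit(X, k)$coefficients else c(0, 0, 0)
  effective <- list(a = tr$a + gam[1] * tr$v,
                    b = tr$b + gam[2] * tr$v,
                    c = tr$c + gam[3] * tr$v,
                    k = as.numeric(k - X %*% gam))
  list(tables = tables,
       truth = list(coefficients = tr, effective = effective,
                    table = data.frame(id = seq_len(n), q5_0 = q5, k = k,
                                       family = fam)),
       config = config)
}

#' Configuration for a China-like observed series
#'
#' Defaults reproduce the study's China conditions: a 19-year series
#' (1994--2012) with male 5q0 falling from 0.03946 to 0.00698 and female
#' from 0.05280 to 0.00514 (annual compound decline 9.17% and 12.14%), a
#' female-higher-5q0 yet female-higher-e0 crossover, and adult (15--59) and
#' old-age (60--79) death rates at 0.7 of what the calibration pattern
#' implies at the same 5q0 -- the deviation that makes 5q0-driven model
#' fits overestimate 45q15 and 20q60.
#'
#' @param n_years Number of calendar years (inclusive; >= 3).
#' @param male_q5,female_q5 Start/end 5q0 per sex (start > end).
#' @param start_year First calendar year label.
#' @param crossover If `TRUE`, the female 5q0 path is bent (minimally, in
#'   log space, endpoints untouched) so that female 5q0 exceeds male in
#'   every year but the last; female e0 exceeds male in every year via the
#'   female adult-mortality advantage.
#' @param adult_dev,old_dev Multipliers on the 15--59 and 60--79 death
#'   rates relative to the calibration pattern (1 = no deviation; < 1
#'   induces model overestimation of 45q15 / 20q60 and underestimation of
#'   e0).
#' @param female_factor Additional multiplier on female rates above age 15
#'   (the sex gap in adult mortality).
#' @param truth Generative coefficient set.
#' @param noise_sd Optional log10-rate noise (default 0: deterministic).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return List of class `series_config`.
#' @export
series_config <- function(n_years = 19,
                          male_q5 = c(0.03946, 0.00698),
                          female_q5 = c(0.05280, 0.00514),
                          start_year = 1994,
                          crossover = TRUE,
                          adult_dev = 0.7, old_dev = 0.7,
                          female_factor = 0.76,
                          truth = default_logquad_truth(),
                          noise_sd = 0, seed = 1) {
  stopifnot(n_years >= 3, male_q5[1] > male_q5[2], female_q5[1] > female_q5[2],
            all(c(male_q5, female_q5) > 0), all(c(male_q5, female_q5) < 1),
            adult_dev > 0, old_dev > 0, female_factor > 0, noise_sd >= 0)
  structure(list(n_years = n_years, male_q5 = male_q5, female_q5 = female_q5,
                 start_year = start_year, crossover = crossover,
                 adult_dev = adult_dev, old_dev = old_dev,
                 female_factor = female_factor, truth = truth,
                 noise_sd = noise_sd, seed = seed),
            class = "series_config")
}

# Log-linear path between endpoints (inclusive), base 10.
geometric_path <- function(endpoints, n) {
  10^seq(log10(endpoints[1]), log10(endpoints[2]), length.out = n)
}

# Female 5q0 path for the crossover regime: endpoints are honoured exactly
# and the female value exceeds the male one in every year but the last.
# With endpoints that start above and end below the male path, no smooth
# monotone single-rate curve can cross only in the final year, so the path
# is piecewise geometric: constant-rate decline from the female start to
# just above the male path at year n-1, then a final-year drop to the
# female end value.
bend_female_path <- function(q_m, female_q5, n) {
  margin <- 1.001
  if (female_q5[1] <= q_m[1])
    stop("infeasible crossover: female start 5q0 must exceed the male start")
  if (female_q5[2] >= q_m[n])
    stop("infeasible crossover: female end 5q0 must fall below the male end")
  knee <- q_m[n - 1] * margin
  if (knee >= female_q5[1])
    stop("infeasible crossover: male path at year n-1 exceeds the female start")
  path <- c(geometric_path(c(female_q5[1], knee), n - 1), female_q5[2])
  if (any(diff(path) >= 0))
    stop("infeasible crossover: female path is not strictly declining")
  path
}

series_table <- function(truth, q5, sex, adult_dev, old_dev, female_factor,
                         eps, label) {
  m <- truth_rates(truth, q5, 0) * 10^eps
  st <- truth$grid$starts
  m[st >= 15 & st < 60] <- m[st >= 15 & st < 60] * adult_dev
  m[st >= 60 & st < 80] <- m[st >= 60 & st < 80] * old_dev
  if (sex == "female") m[st >= 15] <- m[st >= 15] * female_factor
  assemble_exact_q5(m, q5, truth$grid, sex = sex, label = label)
}

#' Generate a China-like per-sex observed annual series
#'
#' 5q0 declines at a constant annual rate between the configured endpoints
#' (the female path minimally bent when the crossover is requested); each
#' year's underlying table applies the configured adult/old-age pattern
#' deviations, and the five assessment indicators are extracted.
#'
#' @param config A [series_config()].
#' @return List with `series` (data frame: `year`, `sex`, `q1_0`, `q5_0`,
#'   `q45_15`, `q20_60`, `e0`), `tables` (named list of per-sex lists of
#'   `abridged_life_table`) and the echoed `config`.
#' @export
generate_china_like_series <- function(config) {
  stopifnot(inherits(config, "series_config"))
  n <- config$n_years
  q_m <- geometric_path(config$male_q5, n)
  q_f <- if (config$crossover) bend_female_path(q_m, config$female_q5, n)
         else geometric_path(config$female_q5, n)
  if (config$crossover) {
    if (!all(q_f[1:(n - 1)] > q_m[1:(n - 1)]) || q_f[n] >= q_m[n])
      stop("infeasible crossover for the configured endpoints")
  }
  set.seed(config$seed)
  ng <- config$truth$grid$n_groups
  eps <- if (config$noise_sd > 0)
    matrix(stats::rnorm(2 * n * ng, 0, config$noise_sd), 2 * n, ng)
  else matrix(0, 2 * n, ng)
  years <- config$start_year + seq_len(n) - 1
  tables <- list(male = vector("list", n), female = vector("list", n))
  rows <- vector("list", 2 * n)
  r <- 0
  for (sex in c("male", "female")) {
    q_path <- if (sex == "male") q_m else q_f
    for (i in seq_len(n)) {
      r <- r + 1
      tab <- series_table(config$truth, q_path[i], sex,
                          config$adult_dev, config$old_dev,
                          config$female_factor, eps[r, ],
                          label = paste0(sex, "-", years[i]))
      tables[[sex]][[i]] <- tab
      ind <- indicators(tab)
      rows[[r]] <- data.frame(year = years[i], sex = sex,
                              q1_0 = ind$q1_0, q5_0 = ind$q5_0,
                              q45_15 = ind$q45_15, q20_60 = ind$q20_60,
                              e0 = ind$e0)
    }
  }
  series <- do.call(rbind, rows)
  if (config$crossover) {
    e_m <- series$e0[series$sex == "male"]
    e_f <- series$e0[series$sex == "female"]
    if (!all(e_f > e_m))
      stop("configured female adult advantage too weak: female e0 does not exceed male in every year")
  }
  list(series = series, tables = tables, config = config)
}

#' Observed 5q0 endpoints per country
#'
#' Start and end under-five mortality (proportions) by sex for the eleven
#' national series used for cross-country comparison, with the inclusive
#' period each covers.
#'
#' @return Data frame: `country`, `period_start`, `period_end`, `n_years`,
#'   `male_start`, `male_end`, `female_start`, `female_end`.
#' @export
country_q5_endpoints <- function() {
  d <- data.frame(
    country = c("Bulgaria", "Chile", "Poland", "China", "Japan", "Australia",
                "Canada", "Denmark", "England and Wales", "Italy", "USA"),
    period_start = c(1961, 1992, 1964, 1994, 1956, 1950, 1950, 1950, 1950,
                     1964, 1950),
    period_end = c(2010, 2005, 2009, 2012, 2012, 2009, 2009, 2011, 2011,
                   2009, 2010),
    male_start = c(0.05062, 0.01941, 0.05706, 0.03946, 0.05708, 0.03476,
                   0.05472, 0.04090, 0.03823, 0.04616, 0.04130),
    male_end = c(0.01313, 0.01070, 0.00693, 0.00698, 0.00314, 0.00568,
                 0.00588, 0.00408, 0.00578, 0.00431, 0.00789),
    female_start = c(0.04134, 0.01602, 0.04557, 0.05280, 0.05036, 0.02715,
                     0.04314, 0.03011, 0.03018, 0.03907, 0.03230),
    female_end = c(0.00981, 0.00879, 0.00693, 0.00514, 0.00293, 0.00442,
                   0.00529, 0.00388, 0.00442, 0.00364, 0.00789))
  d$n_years <- d$period_end - d$period_start + 1
  d
}

#' Generate labelled per-country indicator series
#'
#' One series per country and sex from the recorded 5q0 endpoints, with
#' geometric interpolation; only China gets the crossover bend and the
#' adult/old-age pattern deviation (other countries follow the calibration
#' pattern).  Feeds the cross-country ARE comparison.
#'
#' @param countries Subset of country names (default: all).
#' @param truth Generative coefficient set.
#' @param china_config A [series_config()] used for the China series
#'   (its endpoints are taken from the endpoint table).
#' @param seed Integer seed (noise is off by default; kept for
#'   reproducibility plumbing).
#' @return Data frame: `country`, `year`, `sex`, `q1_0`, `q5_0`, `q45_15`,
#'   `q20_60`, `e0`.
#' @export
generate_country_series <- function(countries = NULL,
                                    truth = default_logquad_truth(),
                                    china_config = series_config(truth = truth),
                                    seed = 1) {
  ep <- country_q5_endpoints()
  if (!is.null(countries)) {
    stopifnot(all(countries %in% ep$country))
    ep <- ep[ep$country %in% countries, ]
  }
  out <- vector("list", nrow(ep))
  for (i in seq_len(nrow(ep))) {
    row <- ep[i, ]
    if (row$country == "China") {
      cfg <- china_config
      cfg$truth <- truth
      cfg$n_years <- row$n_years
      cfg$male_q5 <- c(row$male_start, row$male_end)
      cfg$female_q5 <- c(row$female_start, row$female_end)
      cfg$start_year <- row$period_start
      cfg$seed <- seed
      s <- generate_china_like_series(cfg)$series
    } else {
      n <- row$n_years
      years <- row$period_start + seq_len(n) - 1
      rows <- vector("list", 2 * n)
      r <- 0
      for (sex in c("male", "female")) {
        eps0 <- numeric(truth$grid$n_groups)
        q_path <- geometric_path(
          if (sex == "male") c(row$male_start, row$male_end)
          else c(row$female_start, row$female_end), n)
        for (j in seq_len(n)) {
          r <- r + 1
          tab <- series_table(truth, q_path[j], sex, 1, 1, 1, eps0,
                              label = paste0(row$country, "-", sex))
          ind <- indicators(tab)
          rows[[r]] <- data.frame(year = years[j], sex = sex,
                                  q1_0 = ind$q1_0, q5_0 = ind$q5_0,
                                  q45_15 = ind$q45_15, q20_60 = ind$q20_60,
                                  e0 = ind$e0)
        }
      }
      s <- do.call(rbind, rows)
    }
    s$country <- row$country
    out[[i]] <- s
  }
  res <- do.call(rbind, out)
  res[, c("country", "year", "sex", "q1_0", "q5_0", "q45_15", "q20_60", "e0")]
}
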