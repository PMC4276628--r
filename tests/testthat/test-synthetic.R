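test_that("corpus generation is deterministic and honours its contract", {
  cfg <- corpus_config(n_tables = 30, noise_sd = 0.02, seed = 12)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(lapply(a$tables, `[[`, "m"), lapply(b$tables, `[[`, "m"))
  expect_identical(a$truth$table, b$truth$table)
  # sampled 5q0 is honoured exactly and every table is a valid life table
  for (i in seq_along(a$tables)) {
    tab <- a$tables[[i]]
    expect_equal(indicators(tab)$q5_0, a$truth$table$q5_0[i],
                 tolerance = 1e-12)
    expect_true(all(diff(tab$l) <= 0))
    expect_true(all(tab$q >= 0 & tab$q <= 1))
  }
  empty <- generate_corpus(corpus_config(n_tables = 0))
  expect_length(empty$tables, 0)
  expect_equal(nrow(empty$truth$table), 0)
})

test_that("the China-like series reproduces the published endpoint trends", {
  ser <- fx_series()$series
  qm <- ser$q5_0[ser$sex == "male"]
  qf <- ser$q5_0[ser$sex == "female"]
  # endpoint fidelity to the configured values
  expect_equal(qm[c(1, 19)], c(0.03946, 0.00698), tolerance = 1e-12)
  expect_equal(qf[c(1, 19)], c(0.05280, 0.00514), tolerance = 1e-12)
  # recomputed annual decline rates match the published 9.18% / 12.14%
  expect_lt(abs(annual_decrease_rate(qm[1], qm[19], 19) - 9.18), 0.006)
  expect_lt(abs(annual_decrease_rate(qf[1], qf[19], 19) - 12.14), 0.006)
  # male path is exactly geometric (constant annual decline)
  expect_lt(diff(range(diff(log(qm)))), 1e-12)
})

test_that("the sex crossover holds exactly as configured", {
  ser <- fx_series()$series
  qm <- ser$q5_0[ser$sex == "male"]
  qf <- ser$q5_0[ser$sex == "female"]
  expect_true(all(qf[1:18] > qm[1:18]))
  expect_lt(qf[19], qm[19])
  expect_true(all(diff(qf) < 0))
  # yet female e0 exceeds male e0 in every year
  expect_true(all(ser$e0[ser$sex == "female"] > ser$e0[ser$sex == "male"]))
  # infeasible endpoint configurations are signalled
  expect_error(generate_china_like_series(
    series_config(male_q5 = c(0.06, 0.007), female_q5 = c(0.05, 0.005))),
    "infeasible crossover")
})

test_that("a deflated adult pattern forces overestimation in the 5q0-only case", {
  co <- fx_corpus()
  lq <- fit_logquad(co$tables)
  ser <- fx_series()$series
  s <- ser[ser$sex == "male", ]
  res <- run_case("W1", list(logquad = lq), s)
  r45 <- res$residual[res$indicator == "q45_15"]
  expect_true(all(r45 > 0))
  expect_equal(classify_bias(r45), "+")
})

test_that("country series use the published endpoints and decline throughout", {
  cs <- generate_country_series(countries = c("Japan", "USA", "China"))
  jp <- cs[cs$country == "Japan" & cs$sex == "male", ]
  expect_equal(nrow(jp), 57)
  expect_equal(jp$q5_0[c(1, 57)], c(0.05708, 0.00314), tolerance = 1e-12)
  expect_lt(abs(annual_decrease_rate(jp$q5_0[1], jp$q5_0[57], 57) - 5.05), 0.006)
  us <- cs[cs$country == "USA" & cs$sex == "female", ]
  expect_lt(abs(annual_decrease_rate(us$q5_0[1], us$q5_0[61], 61) - 2.32), 0.006)
  # strictly declining 5q0 everywhere
  for (ctry in unique(cs$country)) for (sx in c("male", "female")) {
    q <- cs$q5_0[cs$country == ctry & cs$sex == sx]
    expect_true(all(diff(q) < 0))
  }
  # only China crosses over
  chf <- cs[cs$country == "China" & cs$sex == "female", ]
  chm <- cs[cs$country == "China" & cs$sex == "male", ]
  expect_true(all(chf$q5_0[1:18] > chm$q5_0[1:18]))
  jpf <- cs[cs$country == "Japan" & cs$sex == "female", ]
  expect_true(all(jpf$q5_0 < jp$q5_0))
})

test_that("generator truth records expose the identifiable parameterization", {
  co <- fx_corpus_exact()
  ef <- co$truth$effective
  # effective k is orthogonal to the regression design
  X <- cbind(1, log10(co$truth$table$q5_0), log10(co$truth$table$q5_0)^2)
  expect_lt(max(abs(crossprod(X, ef$k))), 1e-8 * nrow(X))
  # effective coefficients differ from the raw ones only along v
  d <- rbind(ef$a - co$truth$coefficients$a,
             ef$b - co$truth$coefficients$b)
  v <- co$truth$coefficients$v
  for (i in 1:2) {
    proj <- sum(d[i, ] * v) * v
    expect_lt(max(abs(d[i, ] - proj)), 1e-12)
  }
})
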