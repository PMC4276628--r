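test_that("the ten shorthand cases parse and unknown ones are rejected", {
  expect_equal(case_spec("W2")$system, "logquad")
  expect_equal(case_spec("M3")$inputs, "q5_0&e0")
  c2 <- case_spec("C2 (level: 45q15)")
  expect_equal(c2$name, "C2(level:45q15)")
  expect_equal(c2$level_param, "q45_15")
  expect_equal(case_spec("C1")$level_param, "q5_0")
  expect_equal(case_spec("C3")$level_param, "e0")
  expect_error(case_spec("W4"), "unknown case")
})

test_that("average relative error follows its definition", {
  expect_equal(are(c(2, 4), c(1, 5))$are_percent, 37.5)
  expect_equal(are(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))$are_percent, 0)
  # invariant to ordering
  set.seed(2)
  o <- stats::runif(10); e <- o * stats::runif(10, 0.8, 1.2)
  p <- sample(10)
  expect_equal(are(o, e)$are_percent, are(o[p], e[p])$are_percent)
  expect_warning(res <- are(c(0, 2), c(1, 1)), "observed = 0")
  expect_equal(res$n, 1)
})

test_that("bias classification distinguishes the five classes", {
  expect_equal(classify_bias(rep(0.01, 5)), "+")
  expect_equal(classify_bias(rep(-0.01, 5)), "-")
  expect_equal(classify_bias(c(-3, -2, -1, 1, 2)), "-+")
  expect_equal(classify_bias(c(3, 2, 1, -1, -2)), "+-")
  expect_equal(classify_bias(rep(1e-12, 5)), "0")
  # a linear trend crossing zero mid-series classifies as "-+"
  expect_equal(classify_bias(seq(-1, 1, length.out = 19)), "-+")
  # one outlier does not override a 90% majority
  expect_equal(classify_bias(c(rep(0.02, 18), -0.01)), "+")
})

test_that("compound decline rates reproduce the published values", {
  # n_years is the inclusive year count; compounding runs over n_years - 1
  printed <- rbind(
    c(0.03946, 0.00698, 19, 9.18),   # China males
    c(0.05280, 0.00514, 19, 12.14),  # China females
    c(0.05708, 0.00314, 57, 5.05),   # Japan males
    c(0.05036, 0.00293, 57, 4.95),   # Japan females
    c(0.04130, 0.00789, 61, 2.72),   # USA males
    c(0.03230, 0.00789, 61, 2.32),   # USA females
    c(0.05706, 0.00693, 46, 4.58),   # Poland males
    c(0.03907, 0.00364, 46, 5.14))   # Italy females
  for (i in seq_len(nrow(printed))) {
    r <- annual_decrease_rate(printed[i, 1], printed[i, 2], printed[i, 3])
    expect_lt(abs(r - printed[i, 4]), 0.006)
  }
  expect_equal(annual_decrease_rate(0.02, 0.02, 10), 0)
  expect_equal(annual_decrease_rate(0.04, 0.02, 11),
               100 * (1 - 2^(-1 / 10)), tolerance = 1e-12)
  # exact inversion
  r <- annual_decrease_rate(0.0412, 0.0071, 23)
  expect_equal(0.0412 * (1 - r / 100)^22, 0.0071, tolerance = 1e-12)
  expect_error(annual_decrease_rate(0, 0.01, 5))
})

test_that("annual e0 gains use the matching interval convention", {
  expect_equal(annual_increase_age(70, 70, 8), 0)
  expect_equal(annual_increase_age(70, 72, 11), 0.2)
  expect_equal(annual_increase_age(72, 70, 11), -0.2)
  ts <- trend_statistics(q5_0 = c(0.04, 0.03, 0.02), e0 = c(70, 71, 72),
                         years = 2000:2002)
  expect_equal(ts$e0_gain_per_year, 1)
  expect_equal(ts$period, "2000-2002")
  expect_equal(ts$decrease_rate_percent, annual_decrease_rate(0.04, 0.02, 3))
})

test_that("a series generated by the fitted system itself has zero residuals", {
  systems <- fx_systems()
  lq <- systems$logquad
  q5s <- 10^seq(log10(0.035), log10(0.008), length.out = 6)
  rows <- lapply(seq_along(q5s), function(i) {
    ind <- indicators(predict_logquad(lq, q5s[i], 0))
    data.frame(year = 2000 + i, q1_0 = ind$q1_0, q5_0 = ind$q5_0,
               q45_15 = ind$q45_15, q20_60 = ind$q20_60, e0 = ind$e0)
  })
  null_series <- do.call(rbind, rows)
  for (cs in c("W1", "W2", "W3")) {
    res <- run_case(cs, systems, null_series)
    expect_true(all(res$note == ""))
    expect_lt(max(abs(res$residual)), 1e-6)
  }
})

test_that("exact inputs yield zero residuals; free indicators generally do not", {
  res <- fx_residuals("male")
  expect_true(all(res$note == ""))
  r <- function(cases, ind) abs(res$residual[res$case %in% cases &
                                               res$indicator == ind])
  expect_lt(max(r(c("W2", "M2", "C2(level:45q15)"), "q45_15")), 1e-8)
  expect_lt(max(r(c("W3", "M3", "C3"), "e0")), 1e-6)
  q5_cases <- setdiff(unique(res$case), c("C2(level:45q15)", "C3"))
  expect_lt(max(r(q5_cases, "q5_0")), 1e-8)
  # the level-45q15 and e0-level family cases do NOT honour 5q0
  expect_gt(max(r("C2(level:45q15)", "q5_0")), 1e-4)
  expect_gt(max(r("C3", "q5_0")), 1e-4)
  # free indicators carry real error under the deviated series
  expect_gt(max(r("W1", "q45_15")), 1e-3)
})

test_that("group ARE comparison flags the larger group and keeps the layout", {
  resm <- fx_residuals("male"); resm$sex <- "male"
  resf <- fx_residuals("female"); resf$sex <- "female"
  res <- rbind(resm, resf)
  tab <- summarize_are(res, by = "sex")
  cmp <- compare_groups(tab, "sex")
  expect_equal(nrow(cmp), 10 * 5 * 2)   # cases x indicators x groups
  # at most one flag per case x indicator cell
  key <- interaction(cmp$case, cmp$indicator)
  expect_true(all(tapply(cmp$largest, key, sum) <= 1))
  # the generator gives females the larger adult-pattern deviation, so the
  # female 45q15 ARE dominates in the 5q0-only cases
  f45 <- cmp[cmp$indicator == "q45_15" & cmp$case %in% c("W1", "M1", "C1") &
               cmp$sex == "female", ]
  expect_true(all(f45$largest))
  # identical groups produce no flags
  resf2 <- resm; resf2$sex <- "female"
  cmp2 <- compare_groups(summarize_are(rbind(resm, resf2), by = "sex"), "sex")
  expect_false(any(cmp2$largest))
})
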