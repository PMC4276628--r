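# Three shape-distinct mortality patterns (child-heavy, baseline,
# old-age-heavy) used for clustering-recovery checks.
family_profiles_3 <- function() {
  rbind(c(0, 0, rep(0.15, 3), rep(-0.15, 8), rep(0.06, 7)),
        rep(0, 20),
        c(0, 0, rep(-0.15, 3), rep(0.15, 8), rep(-0.06, 7)))
}

fx_family_corpus <- function() memo("family_corpus", function()
  generate_corpus(corpus_config(n_tables = 150, noise_sd = 0.01,
                                k_range = c(-0.3, 0.3),
                                family_profiles = family_profiles_3(),
                                seed = 77)))

test_that("model-based clustering recovers well-separated generative families", {
  co <- fx_family_corpus()
  fs <- fit_families(co$tables, K = 3, seed = 7)
  ari <- mclust::adjustedRandIndex(fs$assignment_meta$classification,
                                   co$truth$table$family)
  expect_gt(ari, 0.95)
  # refitting with the same seed reproduces the assignment exactly
  fs2 <- fit_families(co$tables, K = 3, seed = 7)
  expect_identical(fs$assignment_meta$classification,
                   fs2$assignment_meta$classification)
})

test_that("K = 1 degenerates to the pooled log-quadratic system at k = 0", {
  co <- fx_corpus()
  fs1 <- fit_families(co$tables, K = 1)
  lq <- fit_logquad(co$tables)
  for (q5 in c(0.008, 0.02, 0.05)) {
    a <- predict_family(fs1, 1, "q5_0", q5)
    b <- predict_logquad(lq, q5, 0)
    expect_equal(a$m, b$m, tolerance = 1e-10)
  }
  rng <- range_45q15(fs1, 0.02)
  expect_equal(rng[["min"]], rng[["max"]])
})

test_that("family assignment identifies generative patterns and ignores the radix", {
  co <- fx_family_corpus()
  fs <- fit_families(co$tables, K = 3, seed = 7)
  # each family's own implied (5q0, 45q15) pair maps back to that family
  for (f in seq_len(fs$K)) {
    imp <- indicators(predict_family(fs, f, "q5_0", 0.02))$q45_15
    expect_identical(assign_family(fs, 0.02, imp), f)
  }
  # a generative family member's indicators map to its cluster's family
  id <- 5
  tab <- co$tables[[id]]
  ind <- indicators(tab)
  expect_identical(assign_family(fs, ind$q5_0, ind$q45_15),
                   fs$assignment_meta$classification[id])
  # indicators (hence assignment) are radix-free
  tab2 <- tab
  for (col in c("l", "L", "T")) tab2[[col]] <- tab2[[col]] / 7
  expect_equal(unlist(indicators(tab2)), unlist(indicators(tab)),
               tolerance = 1e-12)
  expect_warning(assign_family(fs, 0.2), "calibration range")
})

test_that("level matching reproduces the requested indicator", {
  fs <- fx_systems()$family
  p1 <- predict_family(fs, 1, "q5_0", 0.0213)
  expect_equal(indicators(p1)$q5_0, 0.0213, tolerance = 1e-12)
  p2 <- predict_family(fs, 2, "q45_15", 0.12)
  expect_lt(abs(indicators(p2)$q45_15 - 0.12), 1e-9)
  p3 <- predict_family(fs, 3, "e0", 74)
  expect_lt(abs(indicators(p3)$e0 - 74), 1e-7)
  expect_error(predict_family(fs, 1, "q45_15", 0.95), "attainable range")
})

test_that("the 45q15 envelope brackets every family and matches generative extremes", {
  fs <- fx_systems()$family
  for (q5 in c(0.007, 0.02, 0.05)) {
    rng <- range_45q15(fs, q5)
    vals <- vapply(seq_len(fs$K), function(f)
      indicators(predict_family(fs, f, "q5_0", q5))$q45_15, numeric(1))
    expect_true(all(vals >= rng[["min"]] - 1e-12 & vals <= rng[["max"]] + 1e-12))
  }
  # noise-free families with ordered adult mortality: envelope equals the
  # generative extremes
  prof <- rbind(c(rep(0, 4), rep(-0.12, 10), rep(0, 6)),
                rep(0, 20),
                c(rep(0, 4), rep(0.12, 10), rep(0, 6)))
  co <- generate_corpus(corpus_config(n_tables = 120, noise_sd = 0,
                                      k_range = c(0, 0),
                                      family_profiles = prof, seed = 99))
  fs0 <- fit_families(co$tables, K = 3, seed = 9)
  tr <- co$truth$coefficients
  q5 <- 0.02
  gen_ext <- range(vapply(1:3, function(f) {
    m <- truth_rates_local(tr, q5, 0) * 10^prof[f, ]
    indicators(mltsys:::assemble_exact_q5(m, q5, tr$grid))$q45_15
  }, numeric(1)))
  rng0 <- range_45q15(fs0, q5)
  expect_equal(unname(rng0), gen_ext, tolerance = 1e-6)
})

test_that("range diagnostic bookkeeping is exact", {
  fs <- fx_systems()$family
  q5s <- 10^seq(log10(0.006), log10(0.05), length.out = 19)
  env <- t(vapply(q5s, function(q) range_45q15(fs, q), numeric(2)))
  obs <- env[, 1] * 1.05          # inside (envelope min < obs < max)
  obs[1:12] <- env[1:12, 1] * 0.8 # forced below the envelope
  d <- range_diagnostic(fs, data.frame(q5_0 = q5s, q45_15 = obs))
  expect_equal(d$percent_below, 100 * 12 / 19, tolerance = 1e-12)
  expect_equal(d$percent_above, 0)
  expect_equal(d$percent_outside, d$percent_below)
  expect_equal(round(d$percent_below, 1), 63.2)
  # relative error measured against the nearer bound
  expect_equal(d$per_obs$rel_error_percent[1],
               unname(100 * (env[1, 1] - obs[1]) / obs[1]), tolerance = 1e-12)
  # additivity on random flag patterns
  set.seed(3)
  for (i in 1:5) {
    obs2 <- env[, 1] * stats::runif(19, 0.7, 1.6)
    d2 <- range_diagnostic(fs, data.frame(q5_0 = q5s, q45_15 = obs2))
    expect_equal(d2$percent_outside, d2$percent_below + d2$percent_above)
    expect_true(d2$percent_outside >= 0 && d2$percent_outside <= 100)
  }
})
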