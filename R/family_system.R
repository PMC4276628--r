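#' @title Discrete-family / continuous-level model life table system
#' @name family_system
#' @description A regional-style system: calibration tables are clustered
#'   into K mortality-pattern families by model-based clustering of their
#'   residual log-rate profiles (what remains after removing a pooled
#'   log-quadratic level fit), and each family carries its own
#'   one-dimensional level model.  A prediction picks a family and slides
#'   along that family's level dimension; because the level parameter may be
#'   45q15 or e0 rather than 5q0, the output's 5q0 need not match any
#'   observed 5q0 -- the characteristic behaviour of such systems.
NULL

#' Fit the family/level system
#'
#' Features are the per-table residual log10-rate profiles from the pooled
#' log-quadratic stage-1 fit.  They are clustered into K groups with a
#' Gaussian mixture (fixed seed; k-means fallback when the mixture fit
#' fails), and each family's level model -- a log-quadratic fit with the
#' shape parameter pinned at 0 -- is recalibrated on its members only.
#' A family left empty or too small to calibrate triggers a warned refit
#' with K - 1.
#'
#' @param corpus List of `abridged_life_table`s (>= 5 K tables).
#' @param sex Optional filter on the tables' `sex` tag.
#' @param K Number of families (default 5).
#' @param seed Integer seed making the clustering deterministic.
#' @return Object of class `family_system`: per-family level models and
#'   centroids, member 5q0 summaries used for assignment, and
#'   `assignment_meta`.
#' @export
fit_families <- function(corpus, sex = NULL, K = 5, seed = 1) {
  tabs <- filter_corpus(corpus, sex)
  stopifnot(K >= 1)
  if (length(tabs) < 5 * K)
    stop("corpus too small: need >= 5 K = ", 5 * K, " tables, got ", length(tabs))
  s1 <- logquad_stage1(tabs)
  if (K == 1) {
    cl <- rep(1L, length(tabs))
  } else {
    set.seed(seed)
    cl <- tryCatch({
      fit <- mclust::Mclust(s1$resid, G = K, verbose = FALSE)
      if (is.null(fit)) stop("Mclust returned NULL")
      as.integer(fit$classification)
    }, error = function(e) {
      set.seed(seed)
      as.integer(stats::kmeans(s1$resid, centers = K, nstart = 10)$cluster)
    })
  }
  sizes <- tabulate(cl, nbins = K)
  min_size <- max(5, round(0.05 * length(tabs)))
  distinct_q5 <- vapply(seq_len(K), function(f)
    length(unique(signif(s1$x[cl == f], 12))), integer(1))
  if (any(sizes < min_size) || any(distinct_q5 < 4)) {
    if (K == 1) stop("degenerate corpus: single family cannot be calibrated")
    warning("empty or uncalibratable family; refitting with K = ", K - 1)
    return(fit_families(tabs, sex = NULL, K = K - 1, seed = seed))
  }
  families <- lapply(seq_len(K), function(f) {
    memb <- which(cl == f)
    fs1 <- logquad_stage1(tabs[memb])
    list(coeffs = structure(
           list(grid = fs1$grid, a = fs1$a, b = fs1$b, c = fs1$c,
                v = numeric(fs1$grid$n_groups), sex = sex %||% NA_character_,
                calibration_meta = list(n_tables = length(memb),
                                        q5_0_range = range(10^fs1$x))),
           class = "logquad_coefficients"),
         centroid = colMeans(s1$resid[memb, , drop = FALSE]),
         members = memb,
         logq5_mean = mean(fs1$x),
         logq5_sd = max(stats::sd(fs1$x), 1e-6),
         q5_0_range = range(10^fs1$x))
  })
  structure(list(grid = s1$grid, K = K, families = families,
                 pooled_q5_range = range(10^s1$x),
                 sex = sex %||% NA_character_,
                 assignment_meta = list(seed = seed, sizes = tabulate(cl, K),
                                        classification = cl)),
            class = "family_system")
}

#' @export
print.family_system <- function(x, ...) {
  cat(sprintf("<family_system: K = %d, sizes %s, 5q0 in [%.4g, %.4g]>\n",
              x$K, paste(x$assignment_meta$sizes, collapse = "/"),
              x$pooled_q5_range[1], x$pooled_q5_range[2]))
  invisible(x)
}

#' Assign a family from 5q0 (and optionally 45q15)
#'
#' With 5q0 alone the family whose members' (log) 5q0 distribution gives the
#' observation the highest Gaussian density is chosen -- a
#' calibration-density proximity rule.  With both indicators the family
#' whose implied 45q15 at that 5q0 is closest (squared mismatch) to the
#' observed 45q15 wins.  Ties break to the lowest family id; inputs outside
#' the calibration 5q0 range are assigned with a warning.
#'
#' @param system A fitted `family_system`.
#' @param q5_0 Observed under-five mortality (proportion).
#' @param q45_15 Optional observed adult mortality.
#' @return Integer family id in `1:K`.
#' @export
assign_family <- function(system, q5_0, q45_15 = NULL) {
  stopifnot(is.finite(q5_0), q5_0 > 0, q5_0 < 1)
  r <- system$pooled_q5_range
  if (q5_0 < r[1] || q5_0 > r[2])
    warning(sprintf("5q0 = %.5g outside the calibration range [%.5g, %.5g]",
                    q5_0, r[1], r[2]))
  if (is.null(q45_15)) {
    dens <- vapply(system$families, function(f)
      stats::dnorm(log10(q5_0), f$logq5_mean, f$logq5_sd, log = TRUE),
      numeric(1))
    return(which.max(dens))  # which.max ties break to lowest index
  }
  mism <- vapply(system$families, function(f) {
    imp <- suppressWarnings(
      indicators(predict_logquad(f$coeffs, q5_0, 0))$q45_15)
    (imp - q45_15)^2
  }, numeric(1))
  which.min(mism)
}

#' Predict a life table from a family and a level value
#'
#' The family's one-dimensional level model is solved so that the output's
#' level indicator equals `level_value` (to 1e-9 for probabilities, 1e-7
#' years for e0).  When the level parameter is 45q15 or e0 the search runs
#' over the family's 5q0 dimension, so the output's 5q0 generally differs
#' from any observed 5q0.
#'
#' @param system A fitted `family_system`.
#' @param family Family id in `1:K`.
#' @param level_param `"q5_0"`, `"q45_15"` or `"e0"`.
#' @param level_value The level indicator's target value.
#' @param a_rule Separation-factor rule.
#' @return An `abridged_life_table`.
#' @export
predict_family <- function(system, family, level_param = c("q5_0", "q45_15", "e0"),
                           level_value, a_rule = default_a_rule) {
  level_param <- match.arg(level_param)
  stopifnot(family %in% seq_len(system$K), is.finite(level_value))
  fam <- system$families[[family]]
  if (level_param == "q5_0")
    return(suppressWarnings(predict_logquad(fam$coeffs, level_value, 0, a_rule)))
  tol <- if (level_param == "e0") 1e-7 else 1e-9
  f <- function(h)
    indicators(suppressWarnings(
      predict_logquad(fam$coeffs, 10^h, 0, a_rule)))[[level_param]] - level_value
  r <- log10(fam$q5_0_range)
  centre <- mean(r)
  g <- function(u) f(centre + u)
  g0 <- g(0)
  if (abs(g0) <= tol) return(suppressWarnings(
    predict_logquad(fam$coeffs, 10^centre, 0, a_rule)))
  half <- diff(r) / 2
  lo <- expand_arm(g, g0, -1, half, half + 1.2)
  hi <- expand_arm(g, g0, +1, half, half + 1.2)
  if (sign(lo$fk) == sign(hi$fk)) {
    rng <- sort(c(lo$fk, hi$fk) + level_value)
    stop(sprintf("level %s = %.6g outside family %d's attainable range [%.6g, %.6g]",
                 level_param, level_value, family, rng[1], rng[2]))
  }
  h <- centre + bisect_root(g, lo$k, hi$k, lo$fk, hi$fk, tol)
  suppressWarnings(predict_logquad(fam$coeffs, 10^h, 0, a_rule))
}

#' Envelope of family-implied 45q15 at a given 5q0
#'
#' @param system A fitted `family_system`.
#' @param q5_0 Under-five mortality (proportion).
#' @return Named numeric `c(min, max)` of the K families' implied 45q15
#'   when each is driven by 5q0 as the level.
#' @export
range_45q15 <- function(system, q5_0) {
  vals <- vapply(system$families, function(f)
    indicators(suppressWarnings(predict_logquad(f$coeffs, q5_0, 0)))$q45_15,
    numeric(1))
  c(min = min(vals), max = max(vals))
}

#' Flag observed (5q0, 45q15) pairs against the family envelope
#'
#' Each observation is compared with the min/max model-implied 45q15 at its
#' 5q0 ("below range" meaning the observed 45q15 is below the minimum
#' model-estimated value).  Points outside the envelope get a relative error
#' against the nearer bound, `100 |obs - bound| / obs`.
#'
#' @param system A fitted `family_system`.
#' @param observed_series Data frame with columns `q5_0` and `q45_15`.
#' @return Object of class `range_diagnostic`: `per_obs` (flags and relative
#'   errors) and aggregate percentages/AREs (`percent_below`,
#'   `percent_above`, `percent_outside`, `ARE_below`, `ARE_above`,
#'   `ARE_outside`, all in %).
#' @export
range_diagnostic <- function(system, observed_series) {
  stopifnot(is.data.frame(observed_series), nrow(observed_series) > 0,
            all(c("q5_0", "q45_15") %in% names(observed_series)))
  n <- nrow(observed_series)
  flag <- character(n); rel <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    b <- range_45q15(system, observed_series$q5_0[i])
    obs <- observed_series$q45_15[i]
    if (obs < b[[1]]) {
      flag[i] <- "below"; rel[i] <- 100 * (b[[1]] - obs) / obs
    } else if (obs > b[[2]]) {
      flag[i] <- "above"; rel[i] <- 100 * (obs - b[[2]]) / obs
    } else flag[i] <- "within"
  }
  pct <- function(fl) 100 * sum(flag == fl) / n
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  structure(list(
    per_obs = data.frame(q5_0 = observed_series$q5_0,
                         q45_15 = observed_series$q45_15,
                         flag = flag, rel_error_percent = rel),
    percent_below = pct("below"),
    percent_above = pct("above"),
    percent_outside = pct("below") + pct("above"),
    ARE_below = mean_or_na(rel[flag == "below"]),
    ARE_above = mean_or_na(rel[flag == "above"]),
    ARE_outside = mean_or_na(rel[flag != "within"])),
    class = "range_diagnostic")
}

#' @export
print.range_diagnostic <- function(x, ...) {
  cat(sprintf("<range_diagnostic: n = %d, below %.1f%%, above %.1f%%, outside %.1f%%>\n",
              nrow(x$per_obs), x$percent_below, x$percent_above,
              x$percent_outside))
  invisible(x)
}
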