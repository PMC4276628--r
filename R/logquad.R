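#' @title Log-quadratic model life table system
#' @name logquad
#' @description A two-parameter system relating the full schedule of
#'   age-specific death rates to under-five mortality:
#'   `log10(mx) = a_x + b_x log10(5q0) + c_x log10(5q0)^2 + v_x k`,
#'   where the quadratic part is fitted per age group by least squares on a
#'   calibration corpus and the shape vector v is the leading right singular
#'   vector of the residual matrix.  The scalar k tilts adult relative to
#'   child mortality; k = 0 gives the corpus-typical pattern at a given 5q0.
NULL

# Stage-1 quadratic fit + residual matrix; shared with the family system.
logquad_stage1 <- function(corpus, sex = NULL) {
  tabs <- filter_corpus(corpus, sex)
  if (length(tabs) < 2) stop("calibration corpus too small")
  grid <- tabs[[1]]$grid
  for (t in tabs)
    if (!identical(t$grid$starts, grid$starts))
      stop("all corpus tables must share one age grid")
  x <- vapply(tabs, function(t) log10(indicators(t)$q5_0), numeric(1))
  M <- t(vapply(tabs, function(t) log10(t$m), numeric(grid$n_groups)))
  n_distinct <- length(unique(signif(x, 12)))
  if (n_distinct == 1) {
    # all tables share one mortality level: intercept-only fit
    A <- colMeans(M)
    coef <- rbind(A, 0, 0)
    resid <- sweep(M, 2, A)
  } else if (n_distinct < 4) {
    stop("rank-deficient design: need at least 4 distinct 5q0 values, got ",
         n_distinct)
  } else {
    X <- cbind(1, x, x^2)
    fit <- stats::lm.fit(X, M)
    coef <- fit$coefficients
    resid <- fit$residuals
  }
  list(grid = grid, x = x, logm = M,
       a = unname(coef[1, ]), b = unname(coef[2, ]), c = unname(coef[3, ]),
       resid = resid)
}

filter_corpus <- function(corpus, sex = NULL) {
  if (inherits(corpus, "abridged_life_table")) corpus <- list(corpus)
  if (!is.null(sex)) {
    keep <- vapply(corpus, function(t) identical(t$sex, sex), logical(1))
    corpus <- corpus[keep]
  }
  corpus
}

#' Calibrate the log-quadratic system on a corpus of life tables
#'
#' Two-stage fit: (1) per age group, ordinary least squares of `log10(m)`
#' on `(1, log10(5q0), log10(5q0)^2)` across the corpus; (2) the shape
#' vector v is the leading right singular vector of the (tables x ages)
#' residual matrix, unit Euclidean norm, with its sign fixed so that
#' positive k raises adult (15--60) mortality.
#'
#' @param corpus A list of `abridged_life_table`s on one shared grid,
#'   spanning a non-degenerate range of 5q0 (at least 10 tables, at least 4
#'   distinct 5q0 values).
#' @param sex Optional filter: keep only tables with this `sex` tag.
#' @return An object of class `logquad_coefficients`: per-group vectors
#'   `a`, `b`, `c`, `v`, the `grid`, and `calibration_meta` (corpus size and
#'   5q0 range).
#' @seealso [predict_logquad()], [match_k()]
#' @export
fit_logquad <- function(corpus, sex = NULL) {
  s1 <- logquad_stage1(corpus, sex)
  if (length(s1$x) < 10)
    stop("calibration corpus too small: need >= 10 tables, got ", length(s1$x))
  sv <- La.svd(s1$resid)
  if (sv$d[1] < 1e-12)
    stop("degenerate residual matrix: shape vector v is undefined")
  v <- sv$vt[1, ]
  adult <- s1$grid$starts >= 15 & s1$grid$starts < 60
  if (sum(v[adult]) < 0) v <- -v
  structure(list(grid = s1$grid, a = s1$a, b = s1$b, c = s1$c, v = v,
                 sex = sex %||% NA_character_,
                 calibration_meta = list(n_tables = length(s1$x),
                                         q5_0_range = range(10^s1$x))),
            class = "logquad_coefficients")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.logquad_coefficients <- function(x, ...) {
  m <- x$calibration_meta
  cat(sprintf("<logquad_coefficients: %d groups, %d tables, 5q0 in [%.4g, %.4g]>\n",
              x$grid$n_groups, m$n_tables, m$q5_0_range[1], m$q5_0_range[2]))
  invisible(x)
}

logquad_rates <- function(coeffs, q5_0, k) {
  x <- log10(q5_0)
  10^(coeffs$a + coeffs$b * x + coeffs$c * x^2 + coeffs$v * k)
}

#' Predict a full life table from (5q0, k)
#'
#' Death rates for ages 5 and above (and the infant rate) come from the
#' fitted log-quadratic equation; the 1--4 probability is then solved so the
#' returned table's 5q0 equals the input exactly, which is what the system's
#' use as an indirect-estimation tool requires.
#'
#' @param coeffs A `logquad_coefficients` fit.
#' @param q5_0 Under-five mortality (proportion, in (0,1)).  Values outside
#'   the calibration range are extrapolated with a warning, never clamped.
#' @param k Shape parameter (default 0, the corpus-typical pattern).
#' @param a_rule Separation-factor rule.
#' @return An `abridged_life_table` with `indicators(.)$q5_0 == q5_0`.
#' @export
predict_logquad <- function(coeffs, q5_0, k = 0, a_rule = default_a_rule) {
  stopifnot(is.finite(q5_0), q5_0 > 0, q5_0 < 1, is.finite(k))
  r <- coeffs$calibration_meta$q5_0_range
  if (q5_0 < r[1] || q5_0 > r[2])
    warning(sprintf("5q0 = %.5g outside the calibration range [%.5g, %.5g]; extrapolating",
                    q5_0, r[1], r[2]))
  m <- logquad_rates(coeffs, q5_0, k)
  assemble_exact_q5(m, q5_0, coeffs$grid, a_rule, sex = coeffs$sex)
}

#' Solve k to reproduce an observed 45q15 or e0
#'
#' Bisection on the monotone map from k to the target indicator (45q15 is
#' increasing in k by the sign convention of v; e0 is decreasing).  The
#' initial bracket `[-8, 8]` is doubled up to `|k| = 32` before the target
#' is declared unattainable.
#'
#' @param coeffs A `logquad_coefficients` fit.
#' @param q5_0 Under-five mortality input (proportion).
#' @param target `"q45_15"` or `"e0"`.
#' @param target_value Observed value to reproduce.
#' @param tol Absolute tolerance on the matched indicator: defaults to
#'   1e-9 for probabilities and 1e-7 years for e0.
#' @param a_rule Separation-factor rule.
#' @return The matched k (scalar).
#' @export
match_k <- function(coeffs, q5_0, target = c("q45_15", "e0"), target_value,
                    tol = NULL, a_rule = default_a_rule) {
  target <- match.arg(target)
  if (is.null(tol)) tol <- if (target == "e0") 1e-7 else 1e-9
  f <- function(k)
    suppressWarnings(
      indicators(predict_logquad(coeffs, q5_0, k, a_rule)))[[target]] - target_value
  f0 <- f(0)
  if (abs(f0) <= tol) return(0)
  lo <- expand_arm(f, f0, -1, 8, 32)
  hi <- expand_arm(f, f0, +1, 8, 32)
  if (sign(lo$fk) == sign(hi$fk))
    stop(sprintf("target %s = %.6g outside the model's attainable range [%.6g, %.6g] at 5q0 = %.5g",
                 target, target_value,
                 min(lo$fk, hi$fk) + target_value,
                 max(lo$fk, hi$fk) + target_value, q5_0))
  bisect_root(f, lo$k, hi$k, lo$fk, hi$fk, tol)
}

# Grow one arm of a root bracket from `start` (doubling, up to `max_abs`)
# while f keeps the sign of f0 = f(0); back off to the feasibility boundary
# when the evaluation fails (invalid parameter region).  Returns the arm's
# endpoint and function value (the origin itself when nothing is feasible).
expand_arm <- function(f, f0, dir, start, max_abs) {
  x <- dir * start
  fx <- safe_eval(f, x)
  while (!is.na(fx) && sign(fx) == sign(f0) && abs(x) < max_abs) {
    x <- x * 2
    fx <- safe_eval(f, x)
  }
  if (is.na(fx)) {
    # refine toward the feasibility frontier between the last valid point
    # (or the origin) and the failing one
    good <- x / 2
    fg <- safe_eval(f, good)
    while (is.na(fg) && abs(good) > 1e-6) {
      x <- good
      good <- good / 2
      fg <- safe_eval(f, good)
    }
    if (is.na(fg)) return(list(k = 0, fk = f0))
    for (i in 1:40) {
      mid <- (good + x) / 2
      fm <- safe_eval(f, mid)
      if (is.na(fm)) x <- mid else { good <- mid; fg <- fm }
      if (sign(fg) != sign(f0)) break
    }
    return(list(k = good, fk = fg))
  }
  list(k = x, fk = fx)
}

# Bisection to |f| <= tol (or interval collapse); f(lo), f(hi) of opposite sign.
bisect_root <- function(f, lo, hi, flo = f(lo), fhi = f(hi), tol,
                        max_iter = 200) {
  if (abs(flo) <= tol) return(lo)
  if (abs(fhi) <= tol) return(hi)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol || (hi - lo) < 1e-14 * max(1, abs(mid))) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
  }
  (lo + hi) / 2
}
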