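#' @title Modified-logit relational model life table system
#' @name modlogit
#' @description A Brass-type relational system: the logit of survivorship,
#'   `Y(x) = 0.5 * ln((1 - l(x)/l(0)) / (l(x)/l(0)))`, of any schedule is modelled
#'   as a linear function `alpha + beta * Ys(x)` of a standard schedule's
#'   logits, plus age-specific child and adult correction factors that absorb
#'   the systematic bias of the plain two-parameter transform when mortality
#'   at young or adult ages departs from the standard.
NULL

logit_surv <- function(s) 0.5 * log((1 - s) / s)
inv_logit_surv <- function(Y) 1 / (1 + exp(2 * Y))

#' Build a modified-logit standard from a calibration corpus
#'
#' The standard logit schedule `Ys(x)` is the corpus mean of
#' `0.5 ln((1-l)/l)` at each interior boundary age.  Each corpus table is
#' then given a level-only fit `Y ~ alpha + Ys` (a pure logit shift), so the
#' residual profiles retain all of the corpus's age-pattern variation
#' relative to the shifted standard; these residuals are regressed (per
#' boundary, jointly, no intercept) on the child deviation
#' `z_c = 1 - Y(5)/Ys(5)` and the adult deviation `z_a = 1 - Y(60)/Ys(60)`,
#' giving the correction vectors gamma and theta, which thereby encode how
#' child and adult mortality levels relative to the standard reshape the
#' whole schedule.  Both are normalised to 0 at their own anchor boundary
#' (a constant shift, preserving smoothness).
#'
#' @param corpus List of `abridged_life_table`s on one grid.
#' @param sex Optional filter on the tables' `sex` tag.
#' @param anchor_ages Boundary ages defining the child and adult deviations
#'   (default `c(5, 60)`).
#' @return An object of class `modlogit_standard`: `boundaries`, `Ys`,
#'   `gamma`, `theta`, `anchor_ages`, the corpus-mean open-group expectation
#'   `open_e`, and `calibration_meta`.
#' @seealso [predict_modlogit()], [match_modlogit()]
#' @export
build_standard <- function(corpus, sex = NULL, anchor_ages = c(5, 60)) {
  tabs <- filter_corpus(corpus, sex)
  if (length(tabs) < 2) stop("calibration corpus too small")
  grid <- tabs[[1]]$grid
  bnd <- grid_boundaries(grid)
  i_c <- match(anchor_ages[1], bnd)
  i_a <- match(anchor_ages[2], bnd)
  if (is.na(i_c) || is.na(i_a)) stop("anchor ages must be grid boundaries")
  S <- t(vapply(tabs, function(t) survivorship(t), numeric(length(bnd))))
  if (any(S <= 0) || any(S >= 1))
    stop("survivorship must lie strictly in (0,1) at every interior boundary; logit undefined")
  Y <- logit_surv(S)
  Ys <- unname(colMeans(Y))
  E <- matrix(0, nrow(Y), ncol(Y))
  z_c <- numeric(nrow(Y)); z_a <- numeric(nrow(Y))
  for (t in seq_len(nrow(Y))) {
    alpha_t <- mean(Y[t, ] - Ys)
    E[t, ] <- Y[t, ] - (alpha_t + Ys)
    z_c[t] <- 1 - Y[t, i_c] / Ys[i_c]
    z_a[t] <- 1 - Y[t, i_a] / Ys[i_a]
  }
  if (max(abs(z_c)) < 1e-12 && max(abs(z_a)) < 1e-12) {
    gamma <- theta <- numeric(length(bnd))
    adult_from_child <- c(0, 0)
  } else {
    adult_from_child <- unname(stats::lm.fit(cbind(1, z_c), z_a)$coefficients)
    adult_from_child[is.na(adult_from_child)] <- 0
    # intercept absorbs any constant profile offset so it cannot leak into
    # the (nearly collinear) deviation slopes
    Z <- cbind(1, z_c, z_a)
    cf <- stats::lm.fit(Z, E)$coefficients
    cf[is.na(cf)] <- 0
    gamma <- unname(cf[2, ]); theta <- unname(cf[3, ])
    # At the anchor boundaries the response is identically a linear function
    # of the deviations (they are defined from Y at those ages), so the
    # regression rows there are structurally degenerate; replace them by
    # neighbour interpolation of the smooth profile.
    interp <- function(v, j) {
      if (j == 1) v[2]
      else if (j == length(v)) v[j - 1]
      else (v[j - 1] + v[j + 1]) / 2
    }
    g0 <- gamma; t0 <- theta
    for (j in c(i_c, i_a)) {
      gamma[j] <- interp(g0, j)
      theta[j] <- interp(t0, j)
    }
    # normalise each correction profile to 0 at its own anchor boundary
    # (a constant shift, so the profile stays smooth)
    gamma <- gamma - gamma[i_c]
    theta <- theta - theta[i_a]
  }
  structure(list(grid = grid, boundaries = bnd, Ys = Ys,
                 gamma = gamma, theta = theta,
                 adult_from_child = adult_from_child,
                 anchor_ages = anchor_ages, anchor_idx = c(i_c, i_a),
                 open_e = mean(vapply(tabs, function(t) t$e[grid$n_groups],
                                      numeric(1))),
                 sex = sex %||% NA_character_,
                 calibration_meta = list(n_tables = length(tabs))),
            class = "modlogit_standard")
}

#' @export
print.modlogit_standard <- function(x, ...) {
  cat(sprintf("<modlogit_standard: %d boundaries, anchors (%d, %d), %d tables>\n",
              length(x$boundaries), x$anchor_ages[1], x$anchor_ages[2],
              x$calibration_meta$n_tables))
  invisible(x)
}

#' Predict a life table from the modified-logit system
#'
#' First pass `Y0(x) = alpha + beta Ys(x)`; the corrections are then applied
#' as `Y(x) = Y0(x) + gamma_x z_c + theta_x z_a`.  The child deviation is
#' self-consistent with the returned schedule -- `z_c = 1 - Y(5)/Ys(5)`
#' evaluated at the corrected curve -- and the adult deviation follows the
#' corpus-calibrated child-to-adult relation `z_a = p0 + p1 z_c`.  Because
#' the corrections are linear in the deviations and gamma vanishes at the
#' child anchor, the self-consistency condition has a closed-form solution
#' (no iteration).  At `(alpha, beta) = (0, 1)` both deviations are 0 and
#' the standard is reproduced exactly.
#'
#' @param std A `modlogit_standard`.
#' @param alpha,beta Level and slope of the logit transform; `beta > 0`.
#' @param a_rule Separation-factor rule for the rebuilt table.
#' @param open_group_e Expectation of life at the open-interval start;
#'   defaults to the standard's corpus mean.
#' @return An `abridged_life_table`.
#' @export
predict_modlogit <- function(std, alpha, beta, a_rule = default_a_rule,
                             open_group_e = NULL) {
  stopifnot(is.finite(alpha), is.finite(beta), beta > 0)
  i_c <- std$anchor_idx[1]
  p <- std$adult_from_child %||% c(0, 0)
  Ys5 <- std$Ys[i_c]
  th5 <- std$theta[i_c]
  den <- 1 + th5 * p[2] / Ys5
  if (abs(den) < 1e-10)
    stop("degenerate correction geometry: child deviation not identifiable")
  z_c <- (1 - (alpha + beta * Ys5 + th5 * p[1]) / Ys5) / den
  z_a <- p[1] + p[2] * z_c
  Y <- alpha + beta * std$Ys + std$gamma * z_c + std$theta * z_a
  s <- inv_logit_surv(Y)
  if (any(diff(s) >= 0))
    stop("transformed survivorship is not strictly decreasing; (alpha, beta) = (",
         signif(alpha, 4), ", ", signif(beta, 4), ") outside the usable range")
  n <- std$grid$n_groups
  s_full <- c(1, s)            # survivorship at ages 0, 1, 5, ..., open start
  q <- numeric(n)
  q[1:(n - 1)] <- 1 - s_full[-1] / s_full[-n]
  q[n] <- 1
  table_from_q(q, std$grid, a_rule,
               open_group_e = open_group_e %||% std$open_e, sex = std$sex)
}

#' Solve (alpha, beta) to reproduce observed indicators
#'
#' Case `"q5_0"`: beta fixed at 1, alpha solved so the output 5q0 matches.
#' Case `"q5_0&q45_15"` / `"q5_0&e0"`: nested solve -- for each trial beta,
#' alpha is solved to match 5q0 exactly, and beta is then bisected on the
#' second indicator.
#'
#' @param std A `modlogit_standard`.
#' @param case One of `"q5_0"`, `"q5_0&q45_15"`, `"q5_0&e0"`.
#' @param values Named list/vector of observed targets: `q5_0` always, plus
#'   `q45_15` or `e0` for the two-indicator cases.
#' @param tol_q,tol_e Matching tolerances (absolute): probabilities 1e-9,
#'   e0 1e-7 years.
#' @param a_rule Separation-factor rule.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
match_modlogit <- function(std, case = c("q5_0", "q5_0&q45_15", "q5_0&e0"),
                           values, tol_q = 1e-9, tol_e = 1e-7,
                           a_rule = default_a_rule) {
  case <- match.arg(case)
  values <- as.list(values)
  q5 <- values$q5_0
  stopifnot(is.finite(q5), q5 > 0, q5 < 1)

  ind_at <- function(alpha, beta)
    indicators(predict_modlogit(std, alpha, beta, a_rule))

  solve_alpha <- function(beta) {
    # 5q0 is increasing in alpha
    f <- function(alpha) ind_at(alpha, beta)$q5_0 - q5
    f0 <- f(0)
    if (abs(f0) <= tol_q) return(0)
    lo <- expand_arm(f, f0, -1, 0.5, 12)
    hi <- expand_arm(f, f0, +1, 0.5, 12)
    if (sign(lo$fk) == sign(hi$fk))
      stop("target 5q0 = ", signif(q5, 6), " unattainable for beta = ",
           signif(beta, 4))
    bisect_root(f, lo$k, hi$k, lo$fk, hi$fk, tol_q)
  }

  if (case == "q5_0") return(c(alpha = solve_alpha(1), beta = 1))

  second <- if (case == "q5_0&q45_15") "q45_15" else "e0"
  target2 <- values[[second]]
  tol2 <- if (second == "e0") tol_e else tol_q
  stopifnot(is.finite(target2))
  g <- function(beta) {
    a <- solve_alpha(beta)
    ind_at(a, beta)[[second]] - target2
  }
  # bracket a sign change of g over a beta grid
  betas <- exp(seq(log(0.1), log(10), length.out = 25))
  gv <- vapply(betas, function(b) safe_eval(g, b), numeric(1))
  ok <- which(!is.na(gv))
  ic <- NULL
  for (j in seq_len(length(ok) - 1)) {
    if (sign(gv[ok[j]]) != sign(gv[ok[j + 1]])) { ic <- c(ok[j], ok[j + 1]); break }
  }
  if (is.null(ic)) {
    rng <- range(gv[ok] + target2)
    stop(sprintf("target %s = %.6g unattainable; attainable range about [%.6g, %.6g] at this 5q0",
                 second, target2, rng[1], rng[2]))
  }
  beta <- bisect_root(g, betas[ic[1]], betas[ic[2]], gv[ic[1]], gv[ic[2]], tol2)
  c(alpha = solve_alpha(beta), beta = beta)
}

safe_eval <- function(f, x)
  tryCatch(f(x), error = function(e) NA_real_)
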