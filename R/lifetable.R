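#' @title Abridged life table construction
#' @name lifetable
#' @description Build abridged period life tables from central death rates
#'   or from death probabilities, on the package's abridged [age_grid()].
NULL

LT_RADIX <- 100000

new_life_table <- function(grid, m, q, a, l, L, T, e,
                           sex = NA_character_, label = "") {
  structure(list(grid = grid, m = m, q = q, a = a, l = l, L = L, T = T,
                 e = e, sex = sex, label = label),
            class = "abridged_life_table")
}

#' @export
print.abridged_life_table <- function(x, ...) {
  cat(sprintf("<abridged_life_table%s%s: open at %d+>\n",
              if (is.na(x$sex)) "" else paste0(", ", x$sex),
              if (nzchar(x$label)) paste0(", ", x$label) else "",
              x$grid$open_start))
  print(as.data.frame(x), digits = 6)
  invisible(x)
}

#' @export
as.data.frame.abridged_life_table <- function(x, ...) {
  data.frame(age_start = x$grid$starts,
             age_width = ifelse(is.finite(x$grid$widths), x$grid$widths, -1),
             m = x$m, q = x$q, a = x$a, l = x$l, L = x$L, T = x$T, e = x$e)
}

#' Build an abridged life table from central death rates
#'
#' Converts a schedule of central death rates m into death probabilities
#' via `q = n m / (1 + (n - a) m)` in each closed group (with separation
#' factors a from `a_rule`), sets `q = 1` in the open group with
#' `L = l / m`, and chains the survivorship, person-years and expectation
#' columns with radix 100000.
#'
#' @param m Per-group central death rates (deaths per person-year);
#'   non-negative in closed groups, strictly positive in the open group.
#' @param grid An [age_grid()]; `length(m)` must equal `grid$n_groups`.
#' @param a_rule Separation-factor rule, a `function(m, grid)`;
#'   see [default_a_rule()].
#' @param sex Optional `"male"`/`"female"` tag.
#' @param label Optional free-text label (year / population).
#' @return An `abridged_life_table`.
#' @examples
#' g <- age_grid()
#' m <- c(0.02, 0.002, rep(0.001, 10), 0.002, 0.004, 0.008,
#'        0.016, 0.03, 0.06, 0.11, 0.2)
#' lt <- build_life_table(m, g)
#' indicators(lt)$e0
#' @export
build_life_table <- function(m, grid, a_rule = default_a_rule,
                             sex = NA_character_, label = "") {
  n <- grid$n_groups
  if (length(m) != n)
    stop("m has length ", length(m), " but the grid has ", n, " groups")
  if (any(!is.finite(m)) || any(m[-n] < 0) || m[n] <= 0)
    stop("m must be finite, non-negative in closed groups and positive in the open group")
  w <- grid$widths
  a <- a_rule(m, grid)
  q <- numeric(n)
  cl <- seq_len(n - 1)
  q[cl] <- w[cl] * m[cl] / (1 + (w[cl] - a[cl]) * m[cl])
  q[n] <- 1
  if (any(q[cl] < 0) || any(q[cl] >= 1))
    stop("computed q outside [0, 1): inconsistent m / separation factors")
  l <- LT_RADIX * cumprod(c(1, 1 - q[cl]))
  d <- l * q
  L <- numeric(n)
  L[cl] <- w[cl] * (l[cl] - d[cl]) + a[cl] * d[cl]
  L[n] <- l[n] / m[n]
  T <- rev(cumsum(rev(L)))
  new_life_table(grid, m, q, a, l, L, T, T / l, sex, label)
}

#' Build an abridged life table from death probabilities
#'
#' Inverse companion of [build_life_table()]: recovers the central death
#' rates `m = q / (n - (n - a) q)` consistent with the same separation-factor
#' rule (iterating where the rule itself depends on m, as the default infant
#' rule does), takes the open-group rate from the expectation of life at the
#' open interval start (`m = 1 / e_open`), and chains the remaining columns.
#' Extracting `q` from the result reproduces the input exactly.
#'
#' @param q Per-group death probabilities, in `[0, 1)` for closed groups
#'   (the open-group entry is ignored and forced to 1).
#' @param grid,a_rule,sex,label As in [build_life_table()].
#' @param open_group_e Expectation of life (years) at the start of the open
#'   interval; must be positive.
#' @return An `abridged_life_table`.
#' @export
table_from_q <- function(q, grid, a_rule = default_a_rule, open_group_e,
                         sex = NA_character_, label = "") {
  n <- grid$n_groups
  if (length(q) != n)
    stop("q has length ", length(q), " but the grid has ", n, " groups")
  if (any(!is.finite(q[-n])) || any(q[-n] < 0) || any(q[-n] >= 1))
    stop("closed-group q must lie in [0, 1)")
  stopifnot(is.finite(open_group_e), open_group_e > 0)
  w <- grid$widths
  # m and a are mutually dependent through a_rule(m, ...); a short fixed-point
  # iteration converges because only the infant factor varies, mildly, with m.
  m <- q / pmax(w - (w / 2) * q, .Machine$double.eps)
  m[n] <- 1 / open_group_e
  for (it in 1:50) {
    a <- a_rule(m, grid)
    m_new <- q / (w - (w - a) * q)
    m_new[n] <- 1 / open_group_e
    if (max(abs(m_new - m), na.rm = TRUE) < 1e-15) { m <- m_new; break }
    m <- m_new
  }
  build_life_table(m, grid, a_rule, sex = sex, label = label)
}

#' Survivorship at the grid's age boundaries
#'
#' Radix-normalised probabilities of surviving from birth to each interior
#' boundary age (1, 5, ..., open interval start).
#'
#' @param table An `abridged_life_table`.
#' @return Named numeric vector `l(x)/l(0)` at ages `grid$starts[-1]`.
#' @export
survivorship <- function(table) {
  s <- c(table$l[-1] / table$l[1])
  names(s) <- grid_boundaries(table$grid)
  s
}

#' Key mortality indicators of a life table
#'
#' Extracts the summary indicators used for model life table matching and
#' assessment: infant mortality 1q0, under-five mortality 5q0, adult
#' mortality 45q15 (`1 - l(60)/l(15)`), old-age mortality 20q60
#' (`1 - l(80)/l(60)`) and life expectancy at birth `e0 = T(0)/l(0)`.
#'
#' @param table An `abridged_life_table`.
#' @return A list of class `mortality_indicators` with elements `q1_0`,
#'   `q5_0`, `q45_15`, `q20_60`, `e0`.
#' @export
indicators <- function(table) {
  g <- table$grid
  l <- table$l
  at <- function(age) l[grid_index(g, age)]
  structure(list(q1_0  = 1 - at(1) / l[1],
                 q5_0  = 1 - at(5) / l[1],
                 q45_15 = 1 - at(60) / at(15),
                 q20_60 = 1 - at(80) / at(60),
                 e0 = table$T[1] / l[1]),
            class = "mortality_indicators")
}

#' @export
print.mortality_indicators <- function(x, ...) {
  cat(sprintf("1q0 %.5f  5q0 %.5f  45q15 %.5f  20q60 %.5f  e0 %.2f\n",
              x$q1_0, x$q5_0, x$q45_15, x$q20_60, x$e0))
  invisible(x)
}

# Assemble a table that honours an exact 5q0: the infant rate is given,
# the 1-4 probability is solved so 1 - (1-q1_0)(1-q4_1) == q5_0, ages 5+
# come from the supplied rates.  Shared by the model systems' predictors
# and the synthetic series generator.
assemble_exact_q5 <- function(m, q5_0, grid, a_rule = default_a_rule,
                              sex = NA_character_, label = "") {
  n <- grid$n_groups
  a <- a_rule(m, grid)
  q1_0 <- m[1] / (1 + (1 - a[1]) * m[1])
  q4_1 <- 1 - (1 - q5_0) / (1 - q1_0)
  if (!is.finite(q4_1) || q4_1 < 0 || q4_1 >= 1)
    stop("input 5q0 (", signif(q5_0, 6),
         ") is incompatible with the predicted infant rate (implied 4q1 = ",
         signif(q4_1, 6), ")")
  w <- grid$widths
  q <- numeric(n)
  q[1] <- q1_0
  q[2] <- q4_1
  mid <- 3:(n - 1)
  q[mid] <- w[mid] * m[mid] / (1 + (w[mid] - a[mid]) * m[mid])
  q[n] <- 1
  table_from_q(q, grid, a_rule, open_group_e = 1 / m[n],
               sex = sex, label = label)
}
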