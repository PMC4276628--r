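#' Abridged age grid
#'
#' Defines the standard abridged age grouping used throughout the package:
#' an infant group (0--1), a childhood group (1--4), then 5-year groups up
#' to a single open-ended terminal interval.  With the default
#' `open_start = 90` this yields the 20-group grid (0-1, 1-4, 5-9, ...,
#' 85-89, 90+); `open_start = 100` gives the 22-group variant used by
#' census-year tables.
#'
#' Groups are contiguous half-open intervals `[x, x + n)`; ages are exact
#' years.
#'
#' @param open_start Exact age (years) at which the open interval begins.
#'   Must be a multiple of 5, at least 30.
#' @return An object of class `age_grid`: a list with `starts` (exact start
#'   ages), `widths` (group widths in years, `Inf` for the open group),
#'   `open_start` and `n_groups`.
#' @examples
#' g <- age_grid()
#' g$n_groups   # 20
#' @export
age_grid <- function(open_start = 90) {
  stopifnot(length(open_start) == 1, is.finite(open_start),
            open_start %% 5 == 0, open_start >= 30)
  starts <- c(0, 1, seq(5, open_start, by = 5))
  widths <- c(1, 4, rep(5, (open_start - 5) / 5), Inf)
  structure(list(starts = starts, widths = widths,
                 open_start = open_start, n_groups = length(starts)),
            class = "age_grid")
}

#' @export
print.age_grid <- function(x, ...) {
  cat(sprintf("<age_grid: %d groups, 0-1, 1-4, 5-year groups, open at %d+>\n",
              x$n_groups, x$open_start))
  invisible(x)
}

# Interior age boundaries of the grid: 1, 5, 10, ..., open_start.
grid_boundaries <- function(grid) grid$starts[-1]

# Index of the group whose start age is `age` (exact match required).
grid_index <- function(grid, age) {
  i <- match(age, grid$starts)
  if (is.na(i)) stop("age ", age, " is not a group start of this grid")
  i
}

#' Default separation-factor (nax) rule
#'
#' Average person-years lived within each age group by those dying in it:
#' a smooth low-mortality adjustment for the infant group
#' (`a0 = 0.3` when `m0 >= 0.01`, else `0.1 + 20 m0`), `1.5` years for the
#' 1--4 group, and half the group width for the remaining closed groups.
#' The open group needs no separation factor (its person-years follow from
#' `L = l/m`) and is returned as `NA`.
#'
#' @param m Per-group central death rates (per person-year).
#' @param grid An [age_grid()].
#' @return Numeric vector of separation factors, `NA` in the open group.
#' @export
default_a_rule <- function(m, grid) {
  a <- grid$widths / 2
  a[1] <- if (m[1] >= 0.01) 0.3 else 0.1 + 20 * m[1]
  a[2] <- 1.5
  a[grid$n_groups] <- NA_real_
  a
}
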