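#' @title Assessment pipeline: residuals, ARE, bias classes, trends
#' @name assessment
#' @description Runs the model life table systems over an observed annual
#'   indicator series under the ten shorthand input cases (W1--W3, M1--M3,
#'   C1, C2(level:5q0), C2(level:45q15), C3), and summarises estimation
#'   error as residuals, average relative errors (ARE), residual-sign bias
#'   classes, and compound mortality-decline trend statistics.
NULL

CASE_NAMES <- c("W1", "W2", "W3", "M1", "M2", "M3",
                "C1", "C2(level:5q0)", "C2(level:45q15)", "C3")

#' Specify an estimation case
#'
#' Translates a shorthand case name into its system, input set and (for the
#' family system) level parameter.  Case 1 uses 5q0 only; case 2 uses
#' 5q0 & 45q15; case 3 uses 5q0 & e0.  The family system distinguishes
#' which indicator drives its continuous level.
#'
#' @param name One of `"W1"`, `"W2"`, `"W3"`, `"M1"`, `"M2"`, `"M3"`,
#'   `"C1"`, `"C2(level:5q0)"`, `"C2(level:45q15)"`, `"C3"` (spaces
#'   ignored).
#' @return A list of class `case_spec` with `name`, `system`
#'   (`"logquad"`/`"modlogit"`/`"family"`), `inputs`, and `level_param`
#'   (family system only).
#' @export
case_spec <- function(name) {
  key <- gsub("[[:space:]]", "", name)
  canon <- CASE_NAMES[match(tolower(key), tolower(gsub("[[:space:]]", "", CASE_NAMES)))]
  if (is.na(canon)) stop("unknown case shorthand: ", name)
  sys <- switch(substr(canon, 1, 1), W = "logquad", M = "modlogit", C = "family")
  case_no <- as.integer(substr(canon, 2, 2))
  inputs <- switch(case_no, "q5_0", "q5_0&q45_15", "q5_0&e0")
  level <- if (sys == "family")
    switch(canon, "C1" = "q5_0", "C2(level:5q0)" = "q5_0",
           "C2(level:45q15)" = "q45_15", "C3" = "e0")
  else NA_character_
  structure(list(name = canon, system = sys, inputs = inputs,
                 level_param = level), class = "case_spec")
}

estimate_table_for_case <- function(case, systems, obs, a_rule = default_a_rule) {
  q5 <- obs$q5_0
  switch(case$system,
    logquad = {
      lq <- systems$logquad
      k <- switch(case$inputs,
        "q5_0" = 0,
        "q5_0&q45_15" = match_k(lq, q5, "q45_15", obs$q45_15, a_rule = a_rule),
        "q5_0&e0" = match_k(lq, q5, "e0", obs$e0, a_rule = a_rule))
      suppressWarnings(predict_logquad(lq, q5, k, a_rule))
    },
    modlogit = {
      std <- systems$modlogit
      ab <- match_modlogit(std, case$inputs,
                           values = obs[c("q5_0", "q45_15", "e0")],
                           a_rule = a_rule)
      predict_modlogit(std, ab[["alpha"]], ab[["beta"]], a_rule)
    },
    family = {
      fs <- systems$family
      fam <- if (case$inputs == "q5_0&q45_15")
        suppressWarnings(assign_family(fs, q5, obs$q45_15))
      else suppressWarnings(assign_family(fs, q5))
      lv <- case$level_param
      predict_family(fs, fam, lv, obs[[lv]], a_rule)
    })
}

#' Run one estimation case over an observed series
#'
#' For each year, a full life table is estimated from the case's inputs and
#' the five indicators are compared with the observed ones.  Residuals are
#' `estimated - observed`, so positive means overestimation.  Years whose
#' targets are unattainable for the calibrated system are recorded with NA
#' residuals and a note rather than aborting the run.
#'
#' @param case A [case_spec()] (or a shorthand name).
#' @param systems Named list of calibrated systems: `logquad`
#'   (`logquad_coefficients`), `modlogit` (`modlogit_standard`), `family`
#'   (`family_system`); only the one the case needs is required.
#' @param observed_series Data frame with columns `year`, `q1_0`, `q5_0`,
#'   `q45_15`, `q20_60`, `e0` (one row per year).
#' @param a_rule Separation-factor rule.
#' @return Data frame of residual records: `year`, `case`, `indicator`,
#'   `observed`, `estimated`, `residual`, `note`.
#' @export
run_case <- function(case, systems, observed_series, a_rule = default_a_rule) {
  if (is.character(case)) case <- case_spec(case)
  inds <- c("q1_0", "q5_0", "q45_15", "q20_60", "e0")
  stopifnot(all(c("year", inds) %in% names(observed_series)))
  out <- vector("list", nrow(observed_series))
  for (i in seq_len(nrow(observed_series))) {
    obs <- as.list(observed_series[i, ])
    est <- tryCatch(
      indicators(estimate_table_for_case(case, systems, obs, a_rule)),
      error = function(e) e)
    if (inherits(est, "error")) {
      out[[i]] <- data.frame(year = obs$year, case = case$name,
                             indicator = inds,
                             observed = unlist(obs[inds], use.names = FALSE),
                             estimated = NA_real_, residual = NA_real_,
                             note = conditionMessage(est))
    } else {
      ev <- unlist(est[inds], use.names = FALSE)
      ov <- unlist(obs[inds], use.names = FALSE)
      out[[i]] <- data.frame(year = obs$year, case = case$name,
                             indicator = inds, observed = ov, estimated = ev,
                             residual = ev - ov, note = "")
    }
  }
  do.call(rbind, out)
}

#' Run several cases over a series
#'
#' @param cases Character vector of case shorthands (default: all ten).
#' @inheritParams run_case
#' @return Row-bound residual records from [run_case()].
#' @export
run_cases <- function(systems, observed_series, cases = CASE_NAMES,
                      a_rule = default_a_rule) {
  do.call(rbind, lapply(cases, run_case, systems = systems,
                        observed_series = observed_series, a_rule = a_rule))
}

#' Average relative error (ARE)
#'
#' `100 * mean(|estimated - observed| / observed)`, the scale-free error
#' summary appropriate when the mortality level changes strongly over the
#' series.  Observations equal to 0 are excluded with a warning.
#'
#' @param observed,estimated Numeric vectors of equal length.
#' @return List of class `are_result`: `are_percent` and `n` (observations
#'   used).
#' @export
are <- function(observed, estimated) {
  stopifnot(length(observed) == length(estimated))
  keep <- is.finite(observed) & is.finite(estimated)
  if (any(observed[keep] == 0)) {
    warning("excluding ", sum(observed[keep] == 0), " observation(s) with observed = 0")
    keep <- keep & observed != 0
  }
  structure(list(are_percent = 100 * mean(abs(estimated[keep] - observed[keep]) /
                                            abs(observed[keep])),
                 n = sum(keep)),
            class = "are_result")
}

#' Summarise AREs of a residual table
#'
#' @param residuals A residual record data frame from [run_case()], possibly
#'   with extra grouping columns (e.g. `sex`, `population`, `country`).
#' @param by Character vector of grouping columns (always includes `case`
#'   and `indicator`).
#' @return Data frame with one row per group: grouping columns,
#'   `are_percent`, `n`.
#' @export
summarize_are <- function(residuals, by = character()) {
  by <- unique(c("case", "indicator", by))
  keys <- residuals[by]
  split_idx <- split(seq_len(nrow(residuals)), keys, drop = TRUE)
  rows <- lapply(split_idx, function(idx) {
    a <- suppressWarnings(are(residuals$observed[idx], residuals$estimated[idx]))
    cbind(residuals[idx[1], by, drop = FALSE],
          data.frame(are_percent = a$are_percent, n = a$n))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the systematic sign of a residual series
#'
#' Rules: all residuals within `tol` of 0 -> `"0"`; at least 90% of the
#' non-negligible residuals positive -> `"+"` (overestimation), negative ->
#' `"-"`; otherwise, if the sign sequence after 3-point running-median
#' smoothing changes exactly once, `"-+"` (negative turning positive over
#' the series) or `"+-"`; failing that, the majority sign.
#'
#' @param residuals Numeric residual series in year order (length >= 3).
#' @param tol Absolute tolerance below which a residual counts as zero.
#' @return One of `"+"`, `"-"`, `"-+"`, `"+-"`, `"0"`.
#' @export
classify_bias <- function(residuals, tol = 1e-8) {
  residuals <- residuals[is.finite(residuals)]
  stopifnot(length(residuals) >= 3)
  big <- residuals[abs(residuals) > tol]
  if (length(big) == 0) return("0")
  p_pos <- mean(big > 0)
  if (p_pos >= 0.9) return("+")
  if (p_pos <= 0.1) return("-")
  sm <- stats::runmed(residuals, 3)
  s <- sign(sm)
  s <- s[s != 0]
  runs <- rle(s)$values
  if (length(runs) == 2) return(if (runs[1] < 0) "-+" else "+-")
  if (p_pos >= 0.5) "+" else "-"
}

#' Annual compound decrease rate of a probability
#'
#' The rate r (% per year) such that the start value compounded over the
#' period's year-to-year intervals reproduces the end value:
#' `q1 (1 - r/100)^(n_years - 1) = q2`.  `n_years` is the inclusive count
#' of calendar years in the period (so a 1994--2012 series has
#' `n_years = 19` and 18 compounding intervals).  The returned r is
#' positive when mortality falls.
#'
#' @param q1,q2 Start and end probabilities (both > 0).
#' @param n_years Inclusive number of calendar years (>= 2).
#' @return Decrease rate in % per year.
#' @examples
#' annual_decrease_rate(0.03946, 0.00698, 19)  # ~9.17
#' @export
annual_decrease_rate <- function(q1, q2, n_years) {
  stopifnot(q1 > 0, q2 > 0, n_years >= 2)
  100 * (1 - (q2 / q1)^(1 / (n_years - 1)))
}

#' Annual gain in life expectancy at birth
#'
#' `(e02 - e01) / (n_years - 1)`, using the same interval convention as
#' [annual_decrease_rate()].
#'
#' @param e01,e02 Start and end life expectancies (years).
#' @param n_years Inclusive number of calendar years (>= 2).
#' @return Gain in years per year (negative if e0 fell).
#' @export
annual_increase_age <- function(e01, e02, n_years) {
  stopifnot(n_years >= 2)
  (e02 - e01) / (n_years - 1)
}

#' Trend statistics of an indicator series
#'
#' @param q5_0 Series of 5q0 values in year order (first/last used).
#' @param e0 Series of e0 values in year order (first/last used).
#' @param years Optional year labels (first/last used for the period label).
#' @return List of class `trend_result`: `decrease_rate_percent`,
#'   `e0_gain_per_year`, `n_years`, `period`.
#' @export
trend_statistics <- function(q5_0, e0 = NULL, years = NULL) {
  n <- length(q5_0)
  structure(list(
    decrease_rate_percent = annual_decrease_rate(q5_0[1], q5_0[n], n),
    e0_gain_per_year = if (is.null(e0)) NA_real_
                       else annual_increase_age(e0[1], e0[length(e0)], n),
    n_years = n,
    period = if (is.null(years)) NA_character_
             else paste0(years[1], "-", years[length(years)])),
    class = "trend_result")
}

#' Compare AREs across groups
#'
#' Takes a long ARE table (as from [summarize_are()] with a grouping
#' column) and flags, within every case x indicator cell, the group with
#' the strictly largest ARE; exact ties get no flag.  Missing cells are
#' kept and flagged absent rather than dropped.
#'
#' @param are_table Data frame with columns `case`, `indicator`, a grouping
#'   column, `are_percent`.
#' @param group Name of the grouping column (e.g. `"sex"`, `"population"`,
#'   `"country"`).
#' @return The input with logical `largest` and `absent` columns added.
#' @export
compare_groups <- function(are_table, group) {
  stopifnot(all(c("case", "indicator", group, "are_percent") %in% names(are_table)))
  groups <- unique(are_table[[group]])
  cells <- unique(are_table[c("case", "indicator")])
  full <- merge(cells, data.frame(g = groups))
  names(full)[names(full) == "g"] <- group
  out <- merge(full, are_table, by = c("case", "indicator", group),
               all.x = TRUE, sort = FALSE)
  out$absent <- !is.finite(out$are_percent)
  out$largest <- FALSE
  key <- interaction(out$case, out$indicator, drop = TRUE)
  for (cell in levels(key)) {
    idx <- which(key == cell & !out$absent)
    if (length(idx) < 2) next
    v <- out$are_percent[idx]
    if (sum(v == max(v)) == 1) out$largest[idx[which.max(v)]] <- TRUE
  }
  out[order(out$case, out$indicator, out[[group]]), ]
}
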