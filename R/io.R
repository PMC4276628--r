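#' @title Readers and writers
#' @name io
#' @description Plain-text serialisation: the package's life table CSV
#'   schema, an HMD-style period life table reader with aggregation onto the
#'   abridged grid, and coefficient/standard/system files with JSON metadata
#'   sidecars.
NULL

fmt_num <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "" else sprintf("%.17g", v), character(1))
  out
}

#' Write / read a life table CSV
#'
#' Schema: columns `age_start`, `age_width` (-1 for the open interval),
#' `m`, `q`, `a`, `l`, `L`, `T`, `e`; UTF-8, dot decimal, full double
#' precision so a write/read round trip is lossless to 1e-12.
#'
#' @param table An `abridged_life_table`.
#' @param path File path.
#' @return `read_life_table_csv` returns an `abridged_life_table`;
#'   `write_life_table_csv` returns `path` invisibly.
#' @export
write_life_table_csv <- function(table, path) {
  df <- as.data.frame(table)
  out <- data.frame(lapply(df, fmt_num))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param sex,label Optional tags attached to the table on read.
#' @rdname write_life_table_csv
#' @export
read_life_table_csv <- function(path, sex = NA_character_, label = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_start", "age_width", "m", "q", "a", "l", "L", "T", "e")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (any(diff(df$age_start) <= 0))
    stop("schema error in ", path, ": age_start not strictly increasing (row ",
         which(diff(df$age_start) <= 0)[1] + 1, ")")
  open <- which(df$age_width < 0)
  if (length(open) != 1 || open != nrow(df))
    stop("schema error in ", path, ": exactly the last row must be the open interval")
  closed <- seq_len(nrow(df) - 1)
  bad_q <- c(closed[df$q[closed] < 0 | df$q[closed] >= 1],
             if (df$q[nrow(df)] < 0 || df$q[nrow(df)] > 1) nrow(df))
  if (length(bad_q))
    stop("invalid q in ", path, " at row ", bad_q[1], ": ", df$q[bad_q[1]])
  grid <- age_grid(open_start = df$age_start[nrow(df)])
  if (!identical(as.numeric(grid$starts), as.numeric(df$age_start)))
    stop("schema error in ", path, ": ages do not form the abridged grid")
  new_life_table(grid, df$m, df$q, ifelse(is.na(df$a), NA_real_, df$a),
                 df$l, df$L, df$T, df$e, sex = sex, label = label)
}

#' Read an HMD-style period life table and aggregate onto the abridged grid
#'
#' Expects the whitespace-delimited layout of Human Mortality Database
#' period life table files: a header line with columns `Age`, `mx`, `qx`,
#' `ax`, `lx`, `dx`, `Lx`, `Tx`, `ex` (plus an optional leading `Year`),
#' ages written as `0`, `1-4`, `5-9`, ... with a terminal `110+` style open
#' age.  Rows are aggregated onto the target grid by summing deaths and
#' person-years within each group and taking survivorship at the group
#' start, which conserves total person-years exactly.
#'
#' @param path File path.
#' @param grid Target [age_grid()].
#' @param sex,label Optional tags.
#' @return An `abridged_life_table`.
#' @export
read_hmd_lifetable <- function(path, grid = age_grid(90),
                               sex = NA_character_, label = "") {
  lines <- readLines(path)
  hdr <- grep("\\bAge\\b", lines)[1]
  if (is.na(hdr)) stop("no header line containing 'Age' found in ", path)
  df <- utils::read.table(text = lines[hdr:length(lines)], header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("Age", "mx", "lx", "dx", "Lx", "Tx", "ex")
  if (!all(need %in% names(df)))
    stop("HMD schema error in ", path, ": need columns ",
         paste(need, collapse = ", "))
  age_start <- as.numeric(sub("[+]$", "", sub("-.*$", "", df$Age)))
  if (any(is.na(age_start))) stop("unparseable Age values in ", path)
  n <- grid$n_groups
  gidx <- findInterval(age_start, grid$starts)
  if (any(gidx < 1)) stop("ages below 0 in ", path)
  if (!all(grid$starts %in% age_start))
    stop("input ages do not cover every grid boundary; cannot aggregate")
  l <- df$lx[match(grid$starts, age_start)]
  L <- as.numeric(tapply(df$Lx, gidx, sum))
  d <- c(-diff(l), l[n])
  T <- rev(cumsum(rev(L)))
  m <- d / L
  q <- d / l
  q[n] <- 1
  a <- (L - grid$widths * (l - d)) / d
  a[n] <- NA_real_
  radix <- df$lx[1]
  sc <- LT_RADIX / radix
  new_life_table(grid, m, q, a, l * sc, L * sc, T * sc, T / l,
                 sex = sex, label = label)
}

#' Save / load log-quadratic coefficients
#'
#' CSV with columns `age_start`, `a`, `b`, `c`, `v` plus a JSON sidecar
#' (`<path>.meta.json`) holding the calibration metadata.
#'
#' @param coeffs A `logquad_coefficients`.
#' @param path CSV path.
#' @export
write_logquad_csv <- function(coeffs, path) {
  df <- data.frame(age_start = coeffs$grid$starts, a = coeffs$a,
                   b = coeffs$b, c = coeffs$c, v = coeffs$v)
  utils::write.csv(data.frame(lapply(df, fmt_num)), path,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(sex = coeffs$sex,
                            open_start = coeffs$grid$open_start,
                            calibration_meta = coeffs$calibration_meta),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_logquad_csv
#' @export
read_logquad_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  grid <- age_grid(meta$open_start)
  stopifnot(nrow(df) == grid$n_groups)
  structure(list(grid = grid, a = df$a, b = df$b, c = df$c, v = df$v,
                 sex = meta$sex %||% NA_character_,
                 calibration_meta = meta$calibration_meta),
            class = "logquad_coefficients")
}

#' Save / load a modified-logit standard
#'
#' CSV with columns `age_boundary`, `Ys`, `gamma`, `theta` plus a JSON
#' metadata sidecar.
#'
#' @param std A `modlogit_standard`.
#' @param path CSV path.
#' @export
write_standard_csv <- function(std, path) {
  df <- data.frame(age_boundary = std$boundaries, Ys = std$Ys,
                   gamma = std$gamma, theta = std$theta)
  utils::write.csv(data.frame(lapply(df, fmt_num)), path,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(sex = std$sex, open_start = std$grid$open_start,
                            anchor_ages = std$anchor_ages,
                            adult_from_child = std$adult_from_child,
                            open_e = std$open_e,
                            calibration_meta = std$calibration_meta),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_standard_csv
#' @export
read_standard_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  grid <- age_grid(meta$open_start)
  bnd <- grid_boundaries(grid)
  stopifnot(identical(as.numeric(df$age_boundary), as.numeric(bnd)))
  anchors <- as.numeric(meta$anchor_ages)
  structure(list(grid = grid, boundaries = bnd, Ys = df$Ys,
                 gamma = df$gamma, theta = df$theta,
                 adult_from_child = as.numeric(meta$adult_from_child),
                 anchor_ages = anchors,
                 anchor_idx = match(anchors, bnd),
                 open_e = meta$open_e, sex = meta$sex %||% NA_character_,
                 calibration_meta = meta$calibration_meta),
            class = "modlogit_standard")
}

#' Save / load a family system
#'
#' A directory holding one coefficient CSV per family
#' (`family-<k>.csv`, written with [write_logquad_csv()]) and a
#' `manifest.json` with K, the clustering seed, member 5q0 summaries and
#' centroids.
#'
#' @param system A `family_system`.
#' @param dir Directory path (created if needed).
#' @export
write_family_system <- function(system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_len(system$K))
    write_logquad_csv(system$families[[f]]$coeffs,
                      file.path(dir, sprintf("family-%d.csv", f)))
  jsonlite::write_json(
    list(K = system$K, sex = system$sex,
         open_start = system$grid$open_start,
         pooled_q5_range = system$pooled_q5_range,
         assignment_meta = system$assignment_meta[c("seed", "sizes")],
         families = lapply(system$families, function(f)
           list(centroid = f$centroid, logq5_mean = f$logq5_mean,
                logq5_sd = f$logq5_sd, q5_0_range = f$q5_0_range))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_family_system
#' @export
read_family_system <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = FALSE)
  K <- meta$K
  families <- lapply(seq_len(K), function(f) {
    co <- read_logquad_csv(file.path(dir, sprintf("family-%d.csv", f)))
    fm <- meta$families[[f]]
    list(coeffs = co, centroid = as.numeric(unlist(fm$centroid)),
         members = integer(),
         logq5_mean = fm$logq5_mean, logq5_sd = fm$logq5_sd,
         q5_0_range = as.numeric(unlist(fm$q5_0_range)))
  })
  structure(list(grid = age_grid(meta$open_start), K = K,
                 families = families,
                 pooled_q5_range = as.numeric(unlist(meta$pooled_q5_range)),
                 sex = if (is.null(meta$sex)) NA_character_ else meta$sex,
                 assignment_meta = list(seed = meta$assignment_meta$seed,
                                        sizes = as.integer(unlist(meta$assignment_meta$sizes)))),
            class = "family_system")
}

#' Write residual records and ARE summaries as tidy CSVs
#'
#' @param residuals Residual records from [run_case()] / [run_cases()].
#' @param dir Output directory (created if needed).
#' @param are_by Extra grouping columns for the ARE summary.
#' @return Invisibly, the paths written.
#' @export
write_assessment_csv <- function(residuals, dir, are_by = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "residuals.csv")
  p2 <- file.path(dir, "are_summary.csv")
  utils::write.csv(residuals, p1, row.names = FALSE)
  utils::write.csv(summarize_are(residuals, by = are_by), p2,
                   row.names = FALSE)
  invisible(c(p1, p2))
}
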