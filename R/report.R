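# Aggregation of grid results into the summary-table layouts, lossless
# CSV/JSON output, and a flat key-value config reader.

GRID_COLUMNS <- c("family", "skewness", "sd_ratio", "n_per_group", "alpha",
                  "replications", "seed", "reject_rate_t", "reject_rate_wmw",
                  "prop_wmw_smaller", "mc_se_t", "mc_se_wmw", "mc_se_prop",
                  "n_degenerate")

as_grid_table <- function(df) {
  missing <- setdiff(GRID_COLUMNS, names(df))
  if (length(missing)) {
    stop("not a grid table; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[GRID_COLUMNS]
  df$family <- as.character(df$family)
  for (cn in c("n_per_group", "replications", "seed", "n_degenerate")) {
    df[[cn]] <- as.integer(df[[cn]])
  }
  for (cn in setdiff(GRID_COLUMNS, c("family", "n_per_group", "replications",
                                     "seed", "n_degenerate"))) {
    df[[cn]] <- as.numeric(df[[cn]])
  }
  class(df) <- c("grid_table", "data.frame")
  df
}

check_full_slice <- function(grid, family, skewness = skew_grid(),
                             sd_ratios = sd_ratio_grid()) {
  sub <- grid[grid$family == family, , drop = FALSE]
  if (!nrow(sub)) stop("grid has no cells for family ", family, call. = FALSE)
  wanted <- expand.grid(skewness = skewness, sd_ratio = sd_ratios,
                        n_per_group = sort(unique(sub$n_per_group)))
  have <- paste(sub$skewness, sub$sd_ratio, sub$n_per_group)
  need <- paste(wanted$skewness, wanted$sd_ratio, wanted$n_per_group)
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop(sprintf("incomplete %s grid; missing (skewness sd_ratio n): %s",
                 family, paste(missing, collapse = "; ")), call. = FALSE)
  }
  sub
}

#' Mean rejection rate by sample size
#'
#' For each per-group sample size present in the grid, the unweighted mean
#' (in percent) of the rejection rates over the 32 skewness-by-SD-ratio
#' combinations of one family, for one of the two tests — the layout of the
#' mean-rejection summary table.
#'
#' @param grid A `grid_table` containing all 32 (skewness, sd_ratio) cells
#'   of `family` for every sample size it covers.
#' @param family `"gamma"` or `"lognormal"`.
#' @param test `"t"` or `"wmw"`.
#' @return An `aggregate_row`: a named numeric vector (percentages, names =
#'   sample sizes) with a `label` attribute.
#' @export
mean_rejection_by_n <- function(grid, family, test = c("t", "wmw")) {
  test <- match.arg(test)
  check_family(family)
  sub <- check_full_slice(grid, family)
  col <- if (test == "t") "reject_rate_t" else "reject_rate_wmw"
  agg <- tapply(sub[[col]], sub$n_per_group, mean)
  structure(100 * agg[order(as.numeric(names(agg)))],
            label = sprintf("%s / %s test", family,
                            if (test == "t") "t" else "WMW"),
            class = "aggregate_row")
}

#' Mean probability that the WMW p-value is the smaller one, by sample size
#'
#' As [mean_rejection_by_n()] but averaging the per-cell proportion of
#' replicates in which the WMW p-value was strictly smaller than the Welch
#' t p-value.
#'
#' @inheritParams mean_rejection_by_n
#' @return An `aggregate_row` of percentages.
#' @export
mean_prop_wmw_smaller_by_n <- function(grid, family) {
  check_family(family)
  sub <- check_full_slice(grid, family)
  agg <- tapply(sub$prop_wmw_smaller, sub$n_per_group, mean)
  structure(100 * agg[order(as.numeric(names(agg)))],
            label = sprintf("%s / P(WMW p < t p)", family),
            class = "aggregate_row")
}

#' @export
print.aggregate_row <- function(x, ...) {
  cat(attr(x, "label"), "\n")
  v <- as.numeric(x)
  print(stats::setNames(signif(v, 3), names(x)))
  invisible(x)
}

#' True P(X < Y) over a scenario grid
#'
#' Evaluates [prob_x_less_y()] for every (family, skewness, sd_ratio)
#' combination.  Values are kept at full precision; the print method rounds
#' to 2 decimals, matching the usual display convention.
#'
#' @param families Character vector of families.
#' @param skewness,sd_ratios Numeric grid axes.
#' @return A `prob_table`: data frame with columns `family`, `skewness`,
#'   `sd_ratio`, `prob`.
#' @export
prob_table <- function(families = c("gamma", "lognormal"),
                       skewness = skew_grid(), sd_ratios = sd_ratio_grid()) {
  cells <- expand.grid(family = families, skewness = skewness,
                       sd_ratio = sd_ratios, stringsAsFactors = FALSE)
  cells <- cells[order(cells$family, cells$skewness, cells$sd_ratio), ]
  cells$prob <- mapply(function(f, s, r) prob_x_less_y(make_pair(f, s, r)),
                       cells$family, cells$skewness, cells$sd_ratio)
  rownames(cells) <- NULL
  class(cells) <- c("prob_table", "data.frame")
  cells
}

#' @export
print.prob_table <- function(x, digits = 2, ...) {
  for (f in unique(x$family)) {
    cat(f, "distributions: P(X<Y) by SD ratio (rows) and skewness (columns)\n")
    sub <- x[x$family == f, ]
    wide <- tapply(round(sub$prob, digits), list(sub$sd_ratio, sub$skewness),
                   identity)
    print(wide)
  }
  invisible(x)
}

fmt_full <- function(v) {
  ifelse(is.na(v), "", sprintf("%.17g", v))
}

#' Write and read simulation results losslessly
#'
#' CSV files carry one header row and one row per scenario cell, numeric
#' values printed with 17 significant digits so a read-back reproduces the
#' doubles exactly.  JSON files carry the same rows (including the full
#' spec with its seed) via `jsonlite`.
#'
#' @param grid A `grid_table` (or any data frame with its columns).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; `read_results()` infers it from the
#'   file extension when not given.
#' @return `write_results()` returns `path` invisibly; `read_results()` a
#'   `grid_table`.
#' @export
write_results <- function(grid, path, format = c("csv", "json")) {
  format <- match.arg(format)
  grid <- as.data.frame(grid)
  ok <- tryCatch(suppressWarnings({
    if (format == "csv") {
      cols <- if (nrow(grid)) grid[GRID_COLUMNS] else grid[intersect(GRID_COLUMNS, names(grid))]
      lines <- paste(GRID_COLUMNS, collapse = ",")
      if (nrow(grid)) {
        body <- vapply(seq_len(nrow(grid)), function(i) {
          row <- lapply(GRID_COLUMNS, function(cn) {
            v <- grid[[cn]][i]
            if (is.numeric(v)) fmt_full(v) else as.character(v)
          })
          paste(unlist(row), collapse = ",")
        }, character(1))
        lines <- c(lines, body)
      }
      writeLines(lines, path)
    } else {
      jsonlite::write_json(grid, path, digits = I(17), dataframe = "rows",
                           auto_unbox = FALSE)
    }
    TRUE
  }), error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("failed to write results to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such results file: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!nrow(df)) {
    df <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(GRID_COLUMNS)), GRID_COLUMNS))
    df$family <- character(0)
  }
  as_grid_table(df)
}

#' Read a flat key-value configuration file
#'
#' One `key: value` pair per line (a YAML-compatible flat mapping); `#`
#' starts a comment.  Values are parsed as numbers where possible and
#' comma-separated values become vectors.  Keys mirror the CLI flags
#' (`family`, `skewness`, `sd_ratio`, `n`, `reps`, `alpha`, `seed`, `out`,
#' `format`).
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) {
      stop("malformed config line (expected 'key: value'): ", ln, call. = FALSE)
    }
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else parts
  }
  out
}
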