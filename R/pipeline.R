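# Measurement-table I/O, treatment comparison and pipeline orchestration.

MEASUREMENT_COLUMNS <- c("water_band", "si_dose_mg_per_L", "replicate",
                         "time_h", "response_kind", "value", "units")

validate_measurements <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("measurement table must be a nonempty data frame", call. = FALSE)
  }
  missing <- setdiff(MEASUREMENT_COLUMNS, names(table))
  if (length(missing)) {
    stop("measurement table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(table$time_h)) || any(table$time_h <= 0)) {
    bad <- which(!is.finite(table$time_h) | table$time_h <= 0)[1L]
    stop(sprintf("row %d: time_h must be a positive clock hour", bad),
         call. = FALSE)
  }
  u <- unique(table[, c("response_kind", "units")])
  if (anyDuplicated(u$response_kind)) {
    stop("units are not consistent within response_kind", call. = FALSE)
  }
  key <- interaction(table$water_band, table$si_dose_mg_per_L,
                     table$response_kind, table$time_h, table$replicate,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicate replicate identifiers within a treatment cell and time",
         call. = FALSE)
  }
  invisible(table)
}

#' Read a long-format gas-exchange measurement table
#'
#' Reads a CSV with the exact header
#' `water_band,si_dose_mg_per_L,replicate,time_h,response_kind,value,units`
#' and validates it: numeric dose, time and value; positive times;
#' consistent units per response kind; unique replicate labels within
#' each cell. Errors name the offending row of the file.
#'
#' @param path Path to a CSV file.
#' @return A validated measurement data frame.
#' @seealso [write_measurements()], [generate_gas_exchange()]
#' @export
read_measurements <- function(path) {
  header <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  if (!identical(header, MEASUREMENT_COLUMNS)) {
    stop("bad measurement header; expected exactly: ",
         paste(MEASUREMENT_COLUMNS, collapse = ","), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  parse_num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad)) {
      stop(sprintf("row %d: cannot parse %s value '%s' as a number",
                   bad[1L], col, raw[[col]][bad[1L]]), call. = FALSE)
    }
    x
  }
  out <- data.frame(
    water_band = raw$water_band,
    si_dose_mg_per_L = parse_num("si_dose_mg_per_L"),
    replicate = utils::type.convert(raw$replicate, as.is = TRUE),
    time_h = parse_num("time_h"),
    response_kind = raw$response_kind,
    value = parse_num("value"),
    units = raw$units,
    stringsAsFactors = FALSE)
  validate_measurements(out)
  out
}

#' @rdname read_measurements
#' @param table A measurement data frame.
#' @export
write_measurements <- function(table, path) {
  validate_measurements(table)
  utils::write.csv(table[, MEASUREMENT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Percentage gain of a treated value over its control
#'
#' `100 * (treated - control) / control`; losses come out negative.
#' Vectorised; the control must be nonzero.
#'
#' @param treated,control Numeric vectors (recycled to a common
#'   length).
#' @return Percent gain.
#' @export
percent_gain <- function(treated, control) {
  if (any(control == 0)) {
    stop("undefined gain: control value is zero", call. = FALSE)
  }
  100 * (treated - control) / control
}

#' Classical one-way analysis of variance
#'
#' Between-group mean square over within-group mean square, with the
#' upper-tail probability from the F distribution -- the screening
#' test applied at each measurement time to ask whether silicon doses
#' differ. Requires at least two groups of at least two values and
#' nonzero within-group variance.
#'
#' @param groups List of numeric vectors, one per treatment group.
#' @return List with `F`, `p`, and `df` (numerator, denominator).
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))$F # 3
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(lengths(groups) < 2L)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  within_ss <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  if (within_ss == 0) {
    stop("degenerate groups: zero within-group variance, F is unbounded",
         call. = FALSE)
  }
  res <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter))
}

#' Per-time-point ANOVA screen across silicon doses
#'
#' For every water band x response kind x measurement time, tests
#' whether the Si doses differ by [anova_oneway()] on the replicate
#' values. Cells where the test is undefined (too few replicates, zero
#' within-group variance) get `NA` statistics and the reason in
#' `note`.
#'
#' @param table A measurement data frame.
#' @param alpha Significance level for the `significant` flag
#'   (default 0.05, uncorrected -- see `p_adjust`).
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()] across the whole table; default `"none"`.
#' @return Data frame: `water_band`, `response_kind`, `time_h`, `F`,
#'   `p`, `significant`, `note`.
#' @export
anova_table <- function(table, alpha = 0.05, p_adjust = "none") {
  validate_measurements(table)
  cells <- unique(table[, c("water_band", "response_kind", "time_h")])
  cells <- cells[order(match(cells$water_band, unique(table$water_band)),
                       cells$response_kind, cells$time_h), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- table[table$water_band == cell$water_band &
                   table$response_kind == cell$response_kind &
                   table$time_h == cell$time_h, , drop = FALSE]
    groups <- split(sub$value, sub$si_dose_mg_per_L)
    res <- tryCatch(anova_oneway(groups), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(cell, F = NA_real_, p = NA_real_,
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(cell, F = res$F, p = res$p, note = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out[, c("water_band", "response_kind", "time_h", "F", "p",
          "significant", "note")]
}

#' Run the full diurnal-analysis pipeline
#'
#' Orchestrates every stage on one dataset: obtain measurements
#' (either a supplied table/CSV or a fresh synthetic experiment), fit
#' the diurnal curve to every treatment cell, integrate each fitted
#' curve for cumulative courses, daily totals and the fraction
#' achieved by the cutoff hour, compute per-time percent gains of each
#' Si dose against the 0-Si control of its band and of each band
#' against the well-watered band, and screen Si effects by per-time
#' one-way ANOVA. All tables are returned and, if `out_dir` is given,
#' written as CSV (plus a JSON run manifest); rerunning with the same
#' inputs and seed reproduces the files byte for byte. Excluded cells
#' are reported via `message()` and in the exclusions table.
#'
#' @param measurements A measurement data frame, a path to a
#'   measurement CSV, or `NULL` to simulate from `config`/`design`.
#' @param config [synthetic_config()] used when simulating.
#' @param design [treatment_design()] used when simulating.
#' @param out_dir Output directory for the report bundle, or `NULL`
#'   to skip writing.
#' @param window Integration window in hours, default `c(7, 17)`.
#' @param cutoff Cutoff hour for the fraction-achieved column
#'   (default 12, i.e. noon).
#' @param step,rule Quadrature settings, see [integrate_response()].
#' @param grid_by Spacing (hours) of the cumulative-curve grid.
#' @param refine Passed to [fit_all()].
#' @param alpha,p_adjust Passed to [anova_table()].
#' @return (Invisibly) a list with `measurements`, `climate` (if
#'   simulated), `constants`, `exclusions`, `cumulative`,
#'   `percent_gain`, `anova`, `manifest`.
#' @export
run_pipeline <- function(measurements = NULL,
                         config = synthetic_config(),
                         design = treatment_design(),
                         out_dir = NULL,
                         window = c(7, 17), cutoff = 12,
                         step = 0.1, rule = "simpson", grid_by = 1,
                         refine = FALSE,
                         alpha = 0.05, p_adjust = "none") {
  simulated <- is.null(measurements)
  climate <- NULL
  if (simulated) {
    measurements <- generate_gas_exchange(design, config)
    climate <- generate_climate()
  } else if (is.character(measurements)) {
    measurements <- read_measurements(measurements)
  } else {
    validate_measurements(measurements)
  }

  constants <- fit_all(measurements, refine = refine)
  excluded <- constants[!is.na(constants$note) | is.na(constants$omega), ,
                        drop = FALSE]
  for (i in seq_len(nrow(excluded))) {
    message(sprintf("pipeline[fit]: cell %s / %s / %s: %s",
                    excluded$water_band[i], excluded$si_dose_mg_per_L[i],
                    excluded$response_kind[i], excluded$note[i]))
  }
  fitted_ok <- constants[!is.na(constants$omega), , drop = FALSE]

  grid <- seq(window[1], window[2], by = grid_by)
  if (grid[length(grid)] < window[2]) grid <- c(grid, window[2])
  cumulative <- do.call(rbind, lapply(seq_len(nrow(fitted_ok)), function(i) {
    row <- fitted_ok[i, ]
    p <- model_params(row$omega, row$eta, row$psi)
    cc <- cumulative_curve(p, grid, step = step, rule = rule)
    data.frame(water_band = row$water_band,
               si_dose_mg_per_L = row$si_dose_mg_per_L,
               response_kind = row$response_kind,
               t = cc$grid,
               cumulative = cc$cumulative,
               daily_total = cc$daily_total,
               fraction_by_cutoff = fraction_achieved_by(
                 p, cutoff, window = window, step = step, rule = rule),
               stringsAsFactors = FALSE)
  }))

  gains <- percent_gain_table(fitted_ok, times = sort(unique(measurements$time_h)))
  anova <- anova_table(measurements, alpha = alpha, p_adjust = p_adjust)

  manifest <- list(
    package = "photodiurnal",
    version = as.character(utils::packageVersion("photodiurnal")),
    simulated = simulated,
    seed = if (simulated) config$seed else NA,
    noise_sigma_ln = if (simulated) config$noise_sigma_ln else NA,
    window = window, cutoff = cutoff, step = step, rule = rule,
    refine = refine, alpha = alpha, p_adjust = p_adjust,
    n_measurements = nrow(measurements),
    n_cells_fitted = nrow(fitted_ok),
    n_cells_excluded = sum(is.na(constants$omega)))

  result <- list(measurements = measurements, climate = climate,
                 constants = constants, exclusions = excluded,
                 cumulative = cumulative, percent_gain = gains,
                 anova = anova, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
    if (simulated) {
      write_measurements(measurements, file.path(out_dir, "measurements.csv"))
      wr(climate, "climate.csv")
    }
    wr(constants[, c("water_band", "si_dose_mg_per_L", "response_kind",
                     "omega", "eta", "psi", "n", "r", "S")],
       "constants.csv")
    wr(excluded, "exclusions.csv")
    wr(cumulative, "cumulative.csv")
    wr(gains, "percent_gain.csv")
    wr(anova, "anova.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(result)
}

# per-time fitted values and percent gains vs the 0-Si control of the
# band and vs the well-watered band at the same dose
percent_gain_table <- function(constants, times) {
  fitted_at <- function(row, t) {
    evaluate_response(model_params(row$omega, row$eta, row$psi), t)
  }
  rows <- lapply(seq_len(nrow(constants)), function(i) {
    row <- constants[i, ]
    data.frame(water_band = row$water_band,
               si_dose_mg_per_L = row$si_dose_mg_per_L,
               response_kind = row$response_kind,
               time_h = times,
               fitted = fitted_at(row, times),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  lookup <- function(band, dose, kind) {
    sel <- out$water_band == band & out$si_dose_mg_per_L == dose &
      out$response_kind == kind
    if (!any(sel)) return(rep(NA_real_, length(times)))
    out$fitted[sel][match(times, out$time_h[sel])]
  }
  out$gain_vs_si0_pct <- NA_real_
  out$gain_vs_control_band_pct <- NA_real_
  for (band in unique(out$water_band)) {
    for (dose in unique(out$si_dose_mg_per_L)) {
      for (kind in unique(out$response_kind)) {
        sel <- out$water_band == band & out$si_dose_mg_per_L == dose &
          out$response_kind == kind
        if (!any(sel)) next
        ctrl_si <- lookup(band, 0, kind)
        if (!anyNA(ctrl_si)) {
          out$gain_vs_si0_pct[sel] <- percent_gain(out$fitted[sel], ctrl_si)
        }
        ctrl_band <- lookup(water_bands()[1], dose, kind)
        if (!anyNA(ctrl_band)) {
          out$gain_vs_control_band_pct[sel] <-
            percent_gain(out$fitted[sel], ctrl_band)
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}
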