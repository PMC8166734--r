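# Grid sweep: evaluate every catalog size against every calibration error
# and collect the deviations into the matrix behind the color-coded tables.

# round half away from zero to `digits` decimals (table display convention;
# base round() is half-to-even)
round_half_away <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Construct a symmetric calibration-error grid
#'
#' The sweep of signed calibration errors, `-max_abs_pct` to `+max_abs_pct`
#' inclusive in steps of `step_pct`. Always contains 0 and is symmetric
#' about it. Calibration errors up to +/- 12% are common in digital
#' templating; errors up to about 24% bound what has been observed.
#'
#' @param max_abs_pct largest absolute error in percent (positive).
#' @param step_pct grid step in percent (default 1); must divide
#'   `max_abs_pct` exactly.
#' @return An object of class `error_grid`: list with `max_abs_pct`,
#'   `step_pct` and the ordered `values`.
#' @export
#' @examples
#' error_grid(12)       # 25 values, -12..+12
#' error_grid(24, 1)    # 49 values
error_grid <- function(max_abs_pct, step_pct = 1) {
  stopifnot(is.numeric(max_abs_pct), length(max_abs_pct) == 1L,
            is.numeric(step_pct), length(step_pct) == 1L)
  if (max_abs_pct < 0) stop("max_abs_pct must be >= 0", call. = FALSE)
  if (step_pct <= 0) stop("step_pct must be positive", call. = FALSE)
  k <- max_abs_pct / step_pct
  if (abs(k - round(k)) > 1e-9) {
    stop("step_pct = ", step_pct, " does not divide max_abs_pct = ",
         max_abs_pct, " exactly", call. = FALSE)
  }
  structure(
    list(max_abs_pct = max_abs_pct, step_pct = step_pct,
         values = step_pct * seq(-round(k), round(k))),
    class = "error_grid"
  )
}

#' Bundle a catalog, error grid and display options into a scenario
#'
#' @param catalog an [implant_catalog()].
#' @param grid an [error_grid()].
#' @param tie_rule midpoint rule for [snap()].
#' @param report_side `"positive_only"` reports only errors >= 0 (the
#'   published tables do this because the snapped deviations are symmetric
#'   in the error sign); `"both"` keeps the full signed grid.
#' @return An object of class `scenario_config`.
#' @export
scenario <- function(catalog, grid,
                     tie_rule = c("toward_true", "down", "up"),
                     report_side = c("positive_only", "both")) {
  stopifnot(inherits(catalog, "implant_catalog"), inherits(grid, "error_grid"))
  structure(
    list(catalog = catalog, grid = grid,
         tie_rule = match.arg(tie_rule),
         report_side = match.arg(report_side)),
    class = "scenario_config"
  )
}

#' Preset scenarios for the two study samples
#'
#' `"group1"`: common cup sizes 44-66 mm against common errors +/- 12%.
#' `"group2"`: all plausible sizes 38-72 mm against extreme errors +/- 24%.
#' Both use 2 mm size increments, 1% error steps, `toward_true` ties and
#' positive-side reporting.
#'
#' @param name `"group1"` or `"group2"`.
#' @param report_side overrides the preset's reporting side.
#' @return A `scenario_config`.
#' @export
#' @examples
#' scenario_preset("group1")
scenario_preset <- function(name = c("group1", "group2"),
                            report_side = c("positive_only", "both")) {
  name <- match.arg(name)
  scenario(
    catalog_preset(name),
    error_grid(switch(name, group1 = 12, group2 = 24), 1),
    report_side = match.arg(report_side)
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Templating scenario\n")
  cat("  catalog:   ", length(x$catalog$sizes), " sizes, ",
      min(x$catalog$sizes), "-", max(x$catalog$sizes), " mm\n", sep = "")
  cat("  errors:    +/-", x$grid$max_abs_pct, "% in ", x$grid$step_pct,
      "% steps\n", sep = "")
  cat("  tie rule:  ", x$tie_rule, "; reporting: ", x$report_side, "\n",
      sep = "")
  invisible(x)
}

#' Bin a deviation in component sizes into a table label
#'
#' Deviations of up to eight component sizes keep their own label;
#' anything larger is combined into one `">8"` group. With
#' `signed = FALSE` (the positive-side table convention) the magnitude is
#' labelled; with `signed = TRUE` the sign is preserved, large negative
#' deviations becoming `"<-8"`.
#'
#' @param steps integer vector of deviations in component sizes.
#' @param signed preserve the sign in the label?
#' @return character vector of bin labels.
#' @export
#' @examples
#' bin_label(c(0, 5, 9))          # "0" "5" ">8"
#' bin_label(-9, signed = TRUE)   # "<-8"
bin_label <- function(steps, signed = FALSE) {
  steps <- as.integer(steps)
  if (signed) {
    ifelse(steps > 8L, ">8",
           ifelse(steps < -8L, "<-8", as.character(steps)))
  } else {
    ifelse(abs(steps) > 8L, ">8", as.character(abs(steps)))
  }
}

#' Build the deviation matrix for a scenario
#'
#' Sweeps every catalog size (rows) against every calibration error on the
#' reported side of the grid (columns) through [evaluate_case()], collecting
#' the pre-snap projections, the deviations in mm and in component-size
#' steps, and the bin label of each cell. This is the object behind the
#' color-coded tables and the summary figures.
#'
#' @param config a [scenario()] or [scenario_preset()].
#' @return An object of class `deviation_matrix`: a list with numeric
#'   matrices `projected_mm`, `deviation_mm`, integer matrix
#'   `deviation_steps`, character matrix `bins` (all sizes x errors,
#'   dimnames = size / error), the row `sizes`, column `errors`, and the
#'   originating `config`.
#' @export
#' @examples
#' m <- build_matrix(scenario_preset("group1"))
#' m$deviation_mm["52", "8"]   # +4 mm
build_matrix <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  sizes <- config$catalog$sizes
  errors <- config$grid$values
  if (config$report_side == "positive_only") errors <- errors[errors >= 0]
  cases <- expand.grid(size = sizes, err = errors, KEEP.OUT.ATTRS = FALSE)
  res <- evaluate_case(cases$size, cases$err, config$catalog,
                       tie_rule = config$tie_rule)
  dn <- list(size = format(sizes, trim = TRUE),
             error_pct = format(errors, trim = TRUE))
  shape <- function(v) matrix(v, nrow = length(sizes), ncol = length(errors),
                              dimnames = dn)
  steps <- shape(res$deviation_steps)
  structure(
    list(
      sizes = sizes,
      errors = errors,
      projected_mm = shape(res$projected_size),
      deviation_mm = shape(res$deviation_mm),
      deviation_steps = steps,
      bins = matrix(bin_label(steps, signed = config$report_side == "both"),
                    nrow = length(sizes), dimnames = dn),
      config = config
    ),
    class = "deviation_matrix"
  )
}

#' @export
print.deviation_matrix <- function(x, ...) {
  cat("Deviation matrix: ", length(x$sizes), " sizes x ", length(x$errors),
      " errors (", x$config$report_side, ")\n", sep = "")
  cat("Cell deviations in mm (one decimal):\n")
  print(noquote(format(round_half_away(x$deviation_mm, 1L), nsmall = 1L)))
  invisible(x)
}

#' Summarize a deviation matrix
#'
#' Reports the worst-case templating error of the scenario:
#' `max_abs_presnap_mm` is the largest continuous deviation
#' `|size x error / 100|` before catalog snapping, rounded to one decimal;
#' `max_abs_snapped_mm` and `max_abs_steps` are the largest deviations after
#' snapping, in mm and component sizes.
#'
#' @param object a `deviation_matrix`.
#' @param ... unused.
#' @return list of class `deviation_summary` with the three maxima.
#' @export
#' @examples
#' summary(build_matrix(scenario_preset("group1")))  # 7.9 mm, 4 sizes
summary.deviation_matrix <- function(object, ...) {
  presnap <- abs(object$projected_mm -
                   matrix(object$sizes, nrow = length(object$sizes),
                          ncol = length(object$errors)))
  structure(
    list(
      max_abs_presnap_mm = round_half_away(max(presnap), 1L),
      max_abs_snapped_mm = max(abs(object$deviation_mm)),
      max_abs_steps = max(abs(object$deviation_steps))
    ),
    class = "deviation_summary"
  )
}

#' @export
print.deviation_summary <- function(x, ...) {
  cat("Maximum templating error: ", format(x$max_abs_presnap_mm, nsmall = 1L),
      " mm pre-snap; ", x$max_abs_snapped_mm, " mm / ", x$max_abs_steps,
      " component size(s) after catalog selection\n", sep = "")
  invisible(x)
}

#' Pre-snap projection curves for plotting
#'
#' One straight line per catalog size: projected size (mm) as a function of
#' calibration error (%), evaluated on the full signed error grid
#' (figures show both sides regardless of the table's `report_side`).
#'
#' @param config a [scenario()] or [scenario_preset()].
#' @return data.frame with columns `size_mm`, `error_pct`, `projected_mm`,
#'   ordered by size then error.
#' @export
#' @examples
#' head(figure_series(scenario_preset("group1")))
figure_series <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cases <- expand.grid(error_pct = config$grid$values,
                       size_mm = config$catalog$sizes,
                       KEEP.OUT.ATTRS = FALSE)
  data.frame(
    size_mm = cases$size_mm,
    error_pct = cases$error_pct,
    projected_mm = project_size(cases$size_mm, cases$error_pct)
  )
}
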