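# Core projection model: a calibration error of e percent scales every
# templated object linearly, so a true component of size s appears as
# s * (100 + e) / 100 on the miscalibrated radiograph.

#' Project a true component size through a calibration error
#'
#' The magnified (projected) size of a component under a percent
#' calibration error: `true_mm * (100 + error_pct) / 100`. Linear and
#' strictly increasing in both arguments.
#'
#' @param true_mm true component diameter in mm (positive).
#' @param error_pct signed calibration error in percent; must exceed -100
#'   (an error of -100% would collapse the projection to zero size).
#' @return projected diameter in mm (continuous, not yet snapped to a
#'   catalog).
#' @export
#' @examples
#' project_size(52, 8)    # 56.16
#' project_size(66, 12)   # 73.92
project_size <- function(true_mm, error_pct) {
  stopifnot(is.numeric(true_mm), is.numeric(error_pct))
  if (any(true_mm <= 0)) stop("true_mm must be positive", call. = FALSE)
  if (any(error_pct <= -100)) {
    stop("error_pct must be greater than -100 (non-physical projection)",
         call. = FALSE)
  }
  true_mm * (100 + error_pct) / 100
}

#' Evaluate the templating outcome for one or more (size, error) pairs
#'
#' Composes the full forward model: project the true size through the
#' calibration error, snap the projection to the catalog, and express the
#' resulting deviation both in mm and in component-size steps. This is the
#' quantity a surgeon cares about: by how much does a miscalibrated
#' radiograph shift the templated cup away from the optimal one?
#'
#' @param true_mm true component diameter(s) in mm; must lie on the catalog
#'   lattice. Recycled against `error_pct`.
#' @param error_pct signed calibration error(s) in percent.
#' @param catalog an [implant_catalog()].
#' @param tie_rule midpoint rule passed to [snap()]; the default
#'   `"toward_true"` resolves exact midpoints toward the true size.
#' @return a data.frame of class `projection_result` with columns
#'   `true_size`, `error_pct`, `projected_size` (continuous mm),
#'   `snapped_size` (lattice mm), `deviation_mm` (snapped - true) and
#'   `deviation_steps` (signed component sizes).
#' @export
#' @examples
#' evaluate_case(52, 8, catalog_preset("group1"))  # +4 mm, +2 sizes
evaluate_case <- function(true_mm, error_pct, catalog,
                          tie_rule = c("toward_true", "down", "up")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(inherits(catalog, "implant_catalog"))
  n <- max(length(true_mm), length(error_pct))
  true_mm <- rep_len(as.numeric(true_mm), n)
  error_pct <- rep_len(as.numeric(error_pct), n)
  if (!all(.on_lattice(true_mm, catalog))) {
    stop("true_mm must lie on the catalog lattice", call. = FALSE)
  }
  projected <- project_size(true_mm, error_pct)
  snapped <- snap(projected, catalog, tie_rule = tie_rule, true_mm = true_mm)
  res <- data.frame(
    true_size = true_mm,
    error_pct = error_pct,
    projected_size = projected,
    snapped_size = snapped,
    deviation_mm = snapped - true_mm,
    deviation_steps = steps_between(true_mm, snapped, catalog)
  )
  class(res) <- c("projection_result", class(res))
  res
}

#' Recover the optimal component size from a templated size
#'
#' The inverse view of [evaluate_case()]: given the size that was templated
#' on a radiograph suspected of carrying a calibration error, which size
#' should have been chosen? Because the relationship between calibration
#' error and component magnification is inverse, a positive error (template
#' magnified too much) means the optimal component is *smaller* than the
#' templated one. Computed as `snap(templated_mm * 100 / (100 + error_pct))`;
#' midpoint ties under `"toward_true"` resolve toward the templated size.
#'
#' @param templated_mm templated diameter(s) in mm, on the catalog lattice.
#' @param error_pct suspected signed calibration error in percent (> -100).
#' @param catalog an [implant_catalog()].
#' @param tie_rule midpoint rule passed to [snap()].
#' @return optimal diameter(s) in mm on the catalog lattice.
#' @export
#' @examples
#' optimal_from_templated(56, 8, catalog_preset("group1"))  # 52
optimal_from_templated <- function(templated_mm, error_pct, catalog,
                                   tie_rule = c("toward_true", "down", "up")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(inherits(catalog, "implant_catalog"))
  n <- max(length(templated_mm), length(error_pct))
  templated_mm <- rep_len(as.numeric(templated_mm), n)
  error_pct <- rep_len(as.numeric(error_pct), n)
  if (!all(.on_lattice(templated_mm, catalog))) {
    stop("templated_mm must lie on the catalog lattice", call. = FALSE)
  }
  if (any(error_pct <= -100)) {
    stop("error_pct must be greater than -100", call. = FALSE)
  }
  snap(templated_mm * 100 / (100 + error_pct), catalog,
       tie_rule = tie_rule, true_mm = templated_mm)
}

#' Forward lookup: the size templated under a calibration error
#'
#' Convenience wrapper returning only the snapped size of
#' [evaluate_case()]: starting from the optimal component, which size does
#' a miscalibrated radiograph make the planner select?
#'
#' @inheritParams evaluate_case
#' @return templated diameter(s) in mm on the catalog lattice.
#' @export
#' @examples
#' templated_from_optimal(52, 8, catalog_preset("group1"))  # 56
templated_from_optimal <- function(true_mm, error_pct, catalog,
                                   tie_rule = c("toward_true", "down", "up")) {
  evaluate_case(true_mm, error_pct, catalog,
                tie_rule = match.arg(tie_rule))$snapped_size
}
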