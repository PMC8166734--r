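# Implant catalogs: the discrete set of component diameters a surgeon can
# actually order, and the rule mapping a continuous projected diameter to a
# selectable size.

# absolute tolerance (mm) for lattice membership and midpoint detection
.lattice_tol <- 1e-9

#' Construct an implant catalog from an explicit size list
#'
#' An implant catalog is the ordered set of component diameters available
#' from a manufacturer. Hemispherical acetabular cups are typically offered
#' in 2 mm diameter increments; [make_catalog()] builds such uniform
#' catalogs from (min, max, increment). This constructor also accepts
#' non-uniform size lists.
#'
#' @param sizes numeric vector of component diameters in mm, strictly
#'   increasing, all positive.
#' @param clamped logical; if `TRUE`, [snap()] is restricted to
#'   `[min(sizes), max(sizes)]`. If `FALSE` (default) and the catalog is
#'   uniform, snapping extends the increment lattice beyond both ends so
#'   that projections larger than the largest real size still map to a
#'   hypothetical lattice diameter. Non-uniform catalogs are always
#'   effectively clamped because no lattice extension is defined.
#' @return An object of class `implant_catalog`: a list with elements
#'   `sizes`, `increment` (`NA` when spacing is non-uniform) and `clamped`.
#' @seealso [make_catalog()], [catalog_preset()], [snap()]
#' @export
#' @examples
#' implant_catalog(c(44, 46, 48, 50))
implant_catalog <- function(sizes, clamped = FALSE) {
  sizes <- as.numeric(sizes)
  if (length(sizes) < 1L || anyNA(sizes)) {
    stop("'sizes' must be a non-empty numeric vector without NA", call. = FALSE)
  }
  if (any(sizes <= 0)) {
    stop("all catalog sizes must be positive (mm)", call. = FALSE)
  }
  if (is.unsorted(sizes, strictly = TRUE)) {
    stop("catalog sizes must be strictly increasing", call. = FALSE)
  }
  increment <- NA_real_
  if (length(sizes) >= 2L) {
    d <- diff(sizes)
    # round to the lattice tolerance so 33.2 - 31.2 yields exactly 2
    if (max(d) - min(d) <= .lattice_tol) increment <- round(d[[1L]], 9L)
  }
  structure(
    list(sizes = sizes, increment = increment, clamped = isTRUE(clamped)),
    class = "implant_catalog"
  )
}

#' Construct a uniform implant catalog
#'
#' Enumerates the arithmetic progression `min_mm, min_mm + increment_mm,
#' ..., max_mm`. The increment must divide the range exactly (within
#' 1e-9 mm), mirroring how manufacturers list cup diameters.
#'
#' @param min_mm,max_mm smallest and largest diameter in mm; `0 < min < max`.
#' @param increment_mm spacing between consecutive sizes in mm; positive.
#' @param clamped see [implant_catalog()].
#' @return An `implant_catalog`.
#' @export
#' @examples
#' make_catalog(44, 66, 2)   # 12 sizes: the common acetabular cup range
#' make_catalog(38, 72, 2)   # 18 sizes: extended range incl. revision cups
make_catalog <- function(min_mm, max_mm, increment_mm, clamped = FALSE) {
  stopifnot(is.numeric(min_mm), is.numeric(max_mm), is.numeric(increment_mm),
            length(min_mm) == 1L, length(max_mm) == 1L, length(increment_mm) == 1L)
  if (!(min_mm > 0 && max_mm > min_mm)) {
    stop("require 0 < min_mm < max_mm (got min = ", min_mm,
         ", max = ", max_mm, ")", call. = FALSE)
  }
  if (increment_mm <= 0) {
    stop("increment_mm must be positive (got ", increment_mm, ")", call. = FALSE)
  }
  n_steps <- (max_mm - min_mm) / increment_mm
  if (abs(n_steps - round(n_steps)) > .lattice_tol) {
    stop("increment ", increment_mm, " mm does not divide the range [",
         min_mm, ", ", max_mm, "] mm exactly", call. = FALSE)
  }
  implant_catalog(min_mm + increment_mm * seq(0L, round(n_steps)),
                  clamped = clamped)
}

#' Preset catalogs for the two study samples
#'
#' `"group1"` is the convenient sample of common acetabular cup sizes,
#' 44-66 mm in 2 mm increments (12 sizes). `"group2"` is the large sample
#' covering all plausible sizes including revision cups, 38-72 mm in 2 mm
#' increments (18 sizes). Both are unclamped so that strongly magnified
#' projections snap onto the extended 2 mm lattice.
#'
#' @param name `"group1"` or `"group2"`.
#' @return An `implant_catalog`.
#' @export
#' @examples
#' catalog_preset("group1")
catalog_preset <- function(name = c("group1", "group2")) {
  name <- match.arg(name)
  switch(name,
    group1 = make_catalog(44, 66, 2),
    group2 = make_catalog(38, 72, 2)
  )
}

#' @export
print.implant_catalog <- function(x, ...) {
  cat("Implant catalog: ", length(x$sizes), " sizes, ",
      x$sizes[[1L]], "-", x$sizes[[length(x$sizes)]], " mm",
      if (!is.na(x$increment)) paste0(" (", x$increment, " mm increments)"),
      if (x$clamped) " [clamped]" else " [unclamped]", "\n", sep = "")
  invisible(x)
}

# is x (scalar or vector) on the catalog lattice?
.on_lattice <- function(x, catalog) {
  if (!catalog$clamped && !is.na(catalog$increment)) {
    k <- (x - catalog$sizes[[1L]]) / catalog$increment
    abs(k - round(k)) <= .lattice_tol
  } else {
    vapply(x, function(xi) any(abs(catalog$sizes - xi) <= .lattice_tol),
           logical(1L))
  }
}

# candidate diameters bracketing a projection (2 for uniform lattices,
# the whole size list otherwise)
.snap_candidates <- function(projected_mm, catalog) {
  if (!is.na(catalog$increment) && !catalog$clamped) {
    inc <- catalog$increment
    k <- floor((projected_mm - catalog$sizes[[1L]]) / inc + .lattice_tol)
    lo <- catalog$sizes[[1L]] + k * inc
    c(lo, lo + inc)
  } else if (!is.na(catalog$increment)) {
    inc <- catalog$increment
    lo_mm <- catalog$sizes[[1L]]
    hi_mm <- catalog$sizes[[length(catalog$sizes)]]
    k <- floor((projected_mm - lo_mm) / inc + .lattice_tol)
    cand <- lo_mm + c(k, k + 1) * inc
    unique(pmin(pmax(cand, lo_mm), hi_mm))
  } else {
    catalog$sizes
  }
}

#' Snap a projected diameter to the nearest catalog size
#'
#' Implements the component selection rule: of the selectable diameters, the
#' one closest to the projected (magnified) size is chosen. For unclamped
#' uniform catalogs the candidate grid is the increment lattice extended
#' beyond the catalog ends, since large calibration errors project beyond
#' any real catalog. For clamped catalogs, projections outside the range
#' return the nearer endpoint.
#'
#' Exact midpoints between two candidates (e.g. 55.0 mm between 54 and 56)
#' are resolved by `tie_rule`:
#' \describe{
#'   \item{`"toward_true"`}{pick the candidate nearer `true_mm`, i.e.
#'     minimize the final deviation from the optimal size (default).}
#'   \item{`"down"`}{pick the smaller candidate.}
#'   \item{`"up"`}{pick the larger candidate.}
#' }
#'
#' @param projected_mm positive numeric vector of projected diameters (mm).
#' @param catalog an [implant_catalog()].
#' @param tie_rule midpoint resolution rule; see Details.
#' @param true_mm true (optimal) component size in mm; required when
#'   `tie_rule = "toward_true"`. Recycled against `projected_mm`.
#' @return numeric vector of snapped diameters (mm).
#' @export
#' @examples
#' g2 <- catalog_preset("group2")
#' snap(56.16, g2, true_mm = 52)  # 52 mm cup seen under +8% error -> 56
#' snap(55, g2, tie_rule = "down")
snap <- function(projected_mm, catalog,
                 tie_rule = c("toward_true", "down", "up"), true_mm = NULL) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(inherits(catalog, "implant_catalog"), is.numeric(projected_mm))
  if (any(projected_mm <= 0)) {
    stop("projected_mm must be positive", call. = FALSE)
  }
  if (tie_rule == "toward_true") {
    if (is.null(true_mm)) {
      stop("tie_rule = \"toward_true\" requires 'true_mm'", call. = FALSE)
    }
    true_mm <- rep_len(as.numeric(true_mm), length(projected_mm))
  }
  vapply(seq_along(projected_mm), function(i) {
    p <- projected_mm[[i]]
    cand <- .snap_candidates(p, catalog)
    d <- abs(cand - p)
    best <- cand[d <= min(d) + .lattice_tol]
    if (length(best) == 1L) return(best)
    switch(tie_rule,
      down = min(best),
      up   = max(best),
      toward_true = {
        dt <- abs(best - true_mm[[i]])
        # a midpoint equidistant from the true size too: take the smaller
        min(best[dt <= min(dt) + .lattice_tol])
      }
    )
  }, numeric(1L))
}

#' Signed distance between two catalog sizes, in component-size steps
#'
#' Converts a deviation in mm into the clinical unit of "component sizes":
#' how many catalog increments separate two lattice diameters. For uniform
#' catalogs this is `(b - a) / increment` (both sizes may lie on the
#' extended lattice of an unclamped catalog); for non-uniform catalogs it is
#' the difference of the positions in the size list.
#'
#' @param a_mm,b_mm diameters in mm, on the catalog lattice.
#' @param catalog an [implant_catalog()].
#' @return integer vector: positive when `b_mm > a_mm`.
#' @export
#' @examples
#' g1 <- catalog_preset("group1")
#' steps_between(52, 56, g1)  # +2 sizes (4 mm)
steps_between <- function(a_mm, b_mm, catalog) {
  stopifnot(inherits(catalog, "implant_catalog"))
  n <- max(length(a_mm), length(b_mm))
  a_mm <- rep_len(as.numeric(a_mm), n)
  b_mm <- rep_len(as.numeric(b_mm), n)
  off <- !(.on_lattice(a_mm, catalog) & .on_lattice(b_mm, catalog))
  if (any(off)) {
    bad <- unique(c(a_mm[off], b_mm[off]))
    stop("sizes not on the catalog lattice: ",
         paste(format(bad), collapse = ", "), call. = FALSE)
  }
  if (!is.na(catalog$increment)) {
    as.integer(round((b_mm - a_mm) / catalog$increment))
  } else {
    idx <- function(x) vapply(x, function(xi)
      which(abs(catalog$sizes - xi) <= .lattice_tol)[[1L]], integer(1L))
    idx(b_mm) - idx(a_mm)
  }
}
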