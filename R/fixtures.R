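# Randomized fixtures for property-based testing: catalogs and case lists
# drawn under a single integer seed, with no effect on the caller's RNG.

# run expr with a private RNG seeded by `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit(if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random uniform implant catalog
#'
#' Draws a minimum diameter, a size count and an increment uniformly within
#' the given bounds and builds the corresponding catalog. Identical seeds
#' give identical catalogs; the global RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param min_bounds numeric length-2: bounds for the smallest diameter (mm).
#' @param count_bounds integer length-2: bounds for the number of sizes
#'   (both >= 2).
#' @param increments numeric vector of admissible increments (mm) to draw
#'   from.
#' @param clamped passed through to [make_catalog()].
#' @return An [implant_catalog()].
#' @export
#' @examples
#' random_catalog(1)
random_catalog <- function(seed, min_bounds = c(30, 50),
                           count_bounds = c(2L, 20L),
                           increments = c(1, 2, 2.5, 4),
                           clamped = FALSE) {
  stopifnot(length(min_bounds) == 2L, diff(min_bounds) >= 0,
            min_bounds[[1L]] > 0,
            length(count_bounds) == 2L, count_bounds[[1L]] >= 2L,
            count_bounds[[2L]] >= count_bounds[[1L]],
            length(increments) >= 1L, all(increments > 0))
  .with_seed(seed, {
    inc <- sample(rep(increments, 2L), 1L)  # rep: sample() scalar quirk
    n <- sample(seq(count_bounds[[1L]], count_bounds[[2L]]), 1L)
    lo <- round(stats::runif(1L, min_bounds[[1L]], min_bounds[[2L]]), 1L)
    make_catalog(lo, lo + inc * (n - 1L), inc, clamped = clamped)
  })
}

#' Generate a random case list for a catalog
#'
#' Draws `n` (templated size, suspected error) pairs: sizes uniformly from
#' the catalog members, errors uniformly in `[-error_bound, +error_bound]`
#' percent. Reproducible under `seed`; global RNG state untouched.
#'
#' @param n number of cases (0 allowed).
#' @param catalog an [implant_catalog()].
#' @param error_bound largest absolute error in percent.
#' @param seed integer seed.
#' @return data.frame with columns `templated_mm`, `error_pct`.
#' @export
#' @examples
#' random_cases(3, catalog_preset("group1"), seed = 1)
random_cases <- function(n, catalog, error_bound = 24, seed = 1L) {
  stopifnot(inherits(catalog, "implant_catalog"), n >= 0, error_bound >= 0)
  if (n == 0L) {
    return(data.frame(templated_mm = numeric(0L), error_pct = numeric(0L)))
  }
  .with_seed(seed, data.frame(
    templated_mm = sample(rep(catalog$sizes, 2L), n, replace = TRUE),
    error_pct = stats::runif(n, -error_bound, error_bound)
  ))
}
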