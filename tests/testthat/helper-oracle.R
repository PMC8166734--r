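# Brute-force nearest-lattice oracle, independent of snap()'s bracketing
# arithmetic: enumerate an explicit candidate grid and take the argmin.

oracle_snap <- function(projected_mm, catalog,
                        tie_rule = c("toward_true", "down", "up"),
                        true_mm = NULL) {
  tie_rule <- match.arg(tie_rule)
  if (!catalog$clamped && !is.na(catalog$increment)) {
    inc <- catalog$increment
    span <- max(abs(projected_mm - catalog$sizes[[1L]]), 0) / inc + 2
    grid <- catalog$sizes[[1L]] + inc * seq(-ceiling(span), ceiling(span))
  } else {
    grid <- catalog$sizes
  }
  d <- abs(grid - projected_mm)
  best <- grid[d <= min(d) + 1e-9]
  if (length(best) == 1L) return(best)
  switch(tie_rule,
    down = min(best),
    up = max(best),
    toward_true = {
      dt <- abs(best - true_mm)
      min(best[dt <= min(dt) + 1e-9])
    })
}
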