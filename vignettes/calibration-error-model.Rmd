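---
title: "Modelling calibration-error propagation in digital templating for THA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling calibration-error propagation in digital templating for THA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(templacal)
```

## The problem

Preoperative digital templating for total hip arthroplasty (THA) overlays
CAD outlines of prosthetic components on a digital radiograph that has been
scaled by a magnification (calibration) factor, usually estimated from a
radio-opaque marker placed at the level of the hip. If the marker is
malpositioned — for example, too close to the X-ray source — the estimated
factor is wrong by some percent, and every templated component is wrong by
the same percent of its diameter. Because implants come in discrete sizes
(hemispherical acetabular cups typically in 2 mm diameter increments), a
continuous percent error turns into a discrete selection error: the planner
templates a cup one, two or more catalog sizes away from the optimal one.

`templacal` models this propagation deterministically. There is no noise and
no fitted parameter anywhere in the model; every number the package prints
is an exact consequence of three ingredients: a linear projection formula, a
discrete catalog, and a nearest-size selection rule.

## The model

For a true (optimal) component diameter $s$ in mm and a signed calibration
error $e$ in percent, the projected (magnified) diameter is

$$ s' = s \cdot \frac{100 + e}{100}. $$

The pre-snap templating deviation is therefore $s' - s = s\,e/100$: linear
in both arguments, odd in the sign of $e$, and growing with component size —
the same calibration error hurts more for larger cups. The planner then
selects the catalog diameter closest to the projection,
$\hat{s} = \operatorname{snap}(s')$, and the clinically relevant outcome is
the deviation $\hat{s} - s$ in mm, or divided by the catalog increment, in
component sizes.

The inverse lookup answers the complementary question: a cup of size $t$ was
templated on a radiograph suspected of an error $e$ — which size should have
been chosen? Since the relationship between calibration error and component
magnification is inverse (an over-magnified template makes the planner pick
a cup that is too large), the answer is
$\operatorname{snap}(t \cdot 100/(100+e))$. With an 8 % error, a templated
56 mm cup corrects to 52 mm, and conversely the optimal 52 mm cup templates
as 56 mm — two component sizes or 4 mm.

```{r example}
g1 <- catalog_preset("group1")
evaluate_case(52, 8, g1)
optimal_from_templated(56, 8, g1)
```

## The two scenarios

Two preset scenarios sweep the model over a full size-by-error grid:

* **group1** — the *convenient* sample: common cup sizes 44–66 mm (12 sizes,
  2 mm increments) against common calibration errors ±12 % in 1 % steps.
* **group2** — the *large* sample: all plausible sizes 38–72 mm (18 sizes),
  including revision cups, against extreme errors ±24 %.

The ±12 % bound reflects what is commonly observed in clinical templating;
errors above 20 % have been reported but are rare, so ±24 % bounds the
worst case. The deviation matrix tabulates every cell:

```{r matrices}
m1 <- build_matrix(scenario_preset("group1"))
summary(m1)
summary(build_matrix(scenario_preset("group2")))
```

The group-1 maximum is $66 \times 12\,\% = 7.92 \approx 7.9$ mm before
snapping, i.e. 4 component sizes after selection. For group 2 the stated
formula gives $72 \times 24\,\% = 17.28$ mm, which snaps to 90 mm on the
extended lattice — 18 mm or 9 component sizes. A figure of about 21 mm / 10
sizes is sometimes quoted for the large sample; no combination of this grid
and this formula produces it, so the package reports the formula-derived
maximum and notes the discrepancy here rather than reproducing an
unreachable number.

## Numerical and design choices

**Snapping beyond the catalog.** Large positive errors project diameters
beyond any real catalog (66 mm at +12 % projects to 73.92 mm, past the
66 mm catalog end). The deviation tables clearly report such cells, so the
default catalog is *unclamped*: the nearest-size search runs on the 2 mm
increment lattice extended beyond both catalog ends. A `clamped = TRUE`
catalog instead returns the nearer endpoint, which is what a surgeon
constrained to a real catalog would experience; it is available but not the
default because it truncates exactly the cells the tables exist to show.

**Tie-breaking at exact midpoints.** A projection can land exactly halfway
between two catalog sizes (55.00 mm between 54 and 56). The selection rule
"closest to the true size" is read literally: the default `toward_true` rule
picks the candidate nearer the true component, i.e. minimizes the final
deviation. Deterministic `down` and `up` alternatives are provided for users
who prefer a size-independent convention. Midpoint detection, and all other
lattice comparisons, use an absolute tolerance of 1e-9 mm — far below
any physically meaningful scale, large enough to absorb binary floating
point representation of decimal sizes.

**Forward vs. inverse convention.** The forward model applies the printed
formula literally: a positive error inflates the projection. The inverse
("what should have been chosen") is exposed only through
`optimal_from_templated()`, never by silently negating errors, so both
reading directions of the worked example reproduce without sign ambiguity.

**Selection-rule reading.** The phrase "the calculated size closest to the
true size" is grammatically ambiguous; snapping the *projected* size to the
lattice is the only reading consistent with the worked example
(52 × 1.08 = 56.16 → 56), and is the one implemented.

**Display rounding.** Table cells show the deviation in mm to one decimal,
rounded half away from zero (so 7.92 prints as 7.9, and a hypothetical
0.05 as 0.1); full precision is kept internally. Deviations beyond eight
component sizes are combined into a single `">8"` bin (signed variants
`"<-8"`/`">8"` when both error signs are reported); this bin occurs only in
the group-2 grid. Published tables report only the positive error side
because the snapped deviation is symmetric in the error sign away from
midpoints; `report_side = "both"` keeps the full signed grid.

**Errors as reals.** The model accepts any real error above −100 % (at
−100 % the projection collapses to zero, which is rejected as
non-physical); the preset grids sweep integer percents because that is how
the scenarios are defined, and each grid validates that its step divides
its bound exactly.

## What the random fixtures emulate — and what they do not

`random_catalog()` and `random_cases()` exist for property-based testing:
they draw uniform catalogs (random minimum diameter, size count and
increment) and case lists (catalog sizes with errors uniform in ±24 %)
under a single integer seed, without touching the caller's RNG. They
emulate the *structure* of real implant catalogs and suspected-error
queries, not their clinical distribution: real cup sizes concentrate around
48–58 mm and real calibration errors are small and left-skewed. A green
property test therefore establishes that the selection rule, the inverse
lookup and the matrix agree with a brute-force oracle everywhere on the
lattice — not that any particular clinical error rate is likely.

## Limitations

The model is deliberately minimal. It does not estimate the calibration
error from marker geometry (the spherical-marker projection problem and
dual-marker schemes are out of scope), does not process radiographs, and
covers acetabular cups only — femoral stem templating involves non-spherical
geometry and different catalog structures. All results are worst-case
deterministic statements about size selection, not probabilistic statements
about any patient population.
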