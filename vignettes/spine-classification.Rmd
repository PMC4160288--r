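---
title: "Geometric classification of dendritic spines: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric classification of dendritic spines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemorph)
```

## The measurement model

A tracing session reduces each dendritic spine to two calibrated
measurements. The **head width** `w` is a straight 2D line drawn across
the widest part of the spine head, perpendicular to the spine's long
axis, on the optical section where the head is in focus; its length in
micrometres is the pixel distance times the pixel size. The **spine
length** `l` is a 3D Z-trace clicked from the base of the neck to the
tip of the head while scrolling through the image stack; its length is
the sum of per-segment 3D norms, where the axial component of a segment
is the section-index difference times the nominal optical-section
thickness (0.5 µm by default). The same Z-trace construction, applied
along the dendritic shaft between a start and stop position, gives the
segment's contour length; a straight 2D reference line of roughly 10 µm
marks those positions but is not itself a measurement.

Two modelling choices are worth making explicit. First, the axial step
uses the *nominal* section thickness with no refractive-index
correction: the imaging protocol assigns every section one thickness,
and correcting it is a calibration concern upstream of this package.
Second, Z-trace lengths are raw polyline lengths — no smoothing or
resampling — which matches how serial-section tracing software reports
them. Consequently `ztrace_length()` is never below the 3D chord
between its endpoints, and inserting a collinear vertex changes nothing;
both properties are tested.

## The classification rule

With `LWR = l / w`, each spine receives exactly one of six types by the
first matching rule, in this order:

| order | type        | rule                         |
|-------|-------------|------------------------------|
| 1     | `branch`    | flagged in the trace name    |
| 2     | `filo`      | `l > 2` µm                   |
| 3     | `mush`      | `w > 0.6` µm                 |
| 4     | `long_thin` | `l > 1` µm                   |
| 5     | `thin`      | `LWR > 1`                    |
| 6     | `stub`      | `LWR ≤ 1`                    |

The operators are part of the method: rules 2–5 are strict (`>`), rule 6
is inclusive (`≤`), so a spine sitting exactly on a cutoff falls through
to the next rule. Rules 5 and 6 partition whatever reaches them, making
the rule set total: the suite verifies totality exhaustively on a
0.01 µm grid over widths 0.01–2 µm and lengths 0–4 µm, and verifies
agreement with a literal left-to-right nested-conditional
re-implementation (the way a spreadsheet cell would evaluate it) on
10⁵ random inputs.

Branch status is *not* geometric: multi-headed spines are recognised by
the analyst and flagged by appending `branch` to the trace name. The
classifier only consumes the flag. A branch-flagged spine still needs a
positive width because the LWR is computed for every row; the recorded
width is whatever the analyst measured (the method does not specify
which head).

The thresholds live in `spine_thresholds()` and can be overridden
(e.g. for species with different spine geometry), but every output
table then carries a `(non-default)` marker in its metadata header so
analyses remain comparable between users — inter-analyst consistency is
the method's main selling point.

## Pairing widths with lengths

Widths arrive in one Trace List per dendrite, lengths in one Z-Trace
List per series. `assemble_dendrites()` pairs them by the explicit spine
indices in the names when the index sets match, and otherwise by rank
order within the dendrite — the protocol requires measuring spines in
the same order for both passes — but only under a mandatory count
check: a width/length count mismatch is an error that names the
dendrite and both counts, never a silent drop. A dendrite contour
shorter than its straight reference line is geometrically impossible,
so it is an error by default and a warning with `strict = FALSE`
(hand-traced real data can violate it by a hair).

## Per-dendrite summaries and statistics

The dendrite is the statistical unit. For each segment the package
reports the spine count, protrusion density, unweighted means of width,
length and LWR, and per-type counts, fractions and densities. The
density denominator is the **Z-trace contour length** by default: the
contour is the accurate length of the dendrite, while the straight line
only marks start/stop. `denominator = "straight"` is available for
comparison with 2D-only workflows and will report systematically higher
densities (the chord is shorter than the contour). Branched spines count
toward density and fractions always, and toward the means by default
(`include_branch_in_means = FALSE` excludes them). Empty dendrites have
density 0 and *missing* means — never zero, which would bias group
averages.

Two-group comparisons use the classical pooled-variance two-tailed
Student's t-test on a chosen per-dendrite metric. Pooled rather than
Welch variance is the package's reading of an unqualified "Student's
t-test"; with near-equal group sizes and variances the two agree
closely. Swapping the groups flips the sign of t and preserves p.

## What the synthetic generator emulates

`generate_dataset()` emits exactly the file structure a real session
produces: one Trace List CSV per dendrite (straight reference line plus
spine widths, with occasional manual `branch` suffixes) and one Z-Trace
List CSV per series, plus ground truth and optional 3D polylines whose
calibrated lengths equal the exported Z-lengths to 10⁻⁶ µm.

Study conditions, chosen once: segments are 10 µm straight length (the
protocol asks for at least 10 µm), with a contour 2–12% longer
(uniform tortuosity factor); default density is 1 protrusion/µm with a
mixed, mature-leaning type composition; the spine count per dendrite is
`round(density × contour length)`. Within a type, width and length are
drawn **uniformly from a box** that keeps a margin (0.05 µm, 0.05 LWR
by default) away from every threshold, so at zero measurement noise the
classifier recovers 100% of generated labels — this is what makes the
end-to-end acceptance check deterministic. Gaussian measurement noise
can be added; misclassifications then occur only for spines within
noise-reach of a cutoff, which the suite checks.

What the generator does *not* emulate: real within-type width/length
distributions (uniform boxes are a documented simplification — real
spines cluster near the thresholds, so real-data accuracy is bounded by
measurement quality, not by this pipeline), optical blur and focus
ambiguity, analyst ordering mistakes, and any pixel-level imagery.
Passing the recovery tests therefore demonstrates that the *bookkeeping*
(file round-trips, pairing, formula evaluation, densities) is exact; it
says nothing about how well a human measures spines.

Randomness is one explicit stream: each dendrite draws from a sub-seed
derived deterministically from the config seed and the dendrite number,
so enlarging a dataset never reshuffles earlier dendrites.

The `maturation_scenario()` preset encodes two groups of segments
(immature-like: 0.6 protrusions/µm, filopodia-heavy; mature-like: 1.0
protrusions/µm, mushroom-heavy) to demonstrate the direction of a
developmental contrast — higher density, higher mushroom fraction and
lower mean LWR in the mature-like group. The magnitudes are generator
conventions, not empirical claims.

## Numerical choices and edge cases

* A zero or negative head width is a domain error, never a silent
  infinite LWR.
* Zero length is legal (LWR 0, a `stub` unless flagged or wide).
* Tie-breaks at thresholds are exactly the printed operators; there is
  no epsilon fuzzing anywhere in the classifier.
* CSV round-trips are exact: doubles are written at full precision and
  names verbatim, and re-running any command on the same inputs yields
  byte-identical output (output metadata contains the package version
  and settings, no timestamps).
* Validation sizes: the classifier grid (2 × 160k points) and the 10⁵
  oracle comparison run in seconds; the end-to-end recovery check uses
  500 dendrites at 2 protrusions/µm (≈10⁴ spines), a size chosen to
  exercise file I/O at scale while keeping the default test run fast.

## Known limitations

Measurement happens upstream, by a human: the package inherits
calibration mistakes (units are micrometres throughout; no unit column
exists in the exports to check against) and ordering mistakes that
happen to preserve counts (index-based pairing catches most, rank-based
pairing cannot). Only two-group comparisons are provided — multi-group
designs need ANOVA or mixed models outside this package — and no
multiple-testing correction is applied, matching the single planned
comparisons the method was designed for.
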