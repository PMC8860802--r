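---
title: "Multipoint hemodynamic analysis of aneurysm surfaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipoint hemodynamic analysis of aneurysm surfaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blebpoint)
```

## The problem

De novo bleb formation — the appearance of a secondary protrusion on a
previously smooth aneurysm dome — is rare enough that hemodynamic studies of
it typically have one or two subjects. Comparing "aneurysms that formed a
bleb" against "aneurysms that did not" is then statistically hopeless. The
multipoint method shifts the unit of analysis from the aneurysm to the
surface point: points are distributed evenly at a fixed spacing over the sac
of a CFD model, per-point hemodynamic parameters are measured, and the
points inside the (clinically delineated) bleb-formation region are compared
with those outside it. `blebpoint` implements that pipeline: mesh and field
I/O, point distribution, index computation, detection of divergent-WSS
centers, and the region statistics.

The bleb/non-bleb delineation is always an *input* (a vertex labelling, in
the original work a neurosurgeon consensus); the package never infers it.

## Hemodynamic indices

All instantaneous quantities are evaluated at the **peak systole of the
second simulated cycle** — the time of maximum inlet flow rate within that
cycle, ties broken to the earliest sample (`select_peak_systole()`). The
first simulated cycle is conventionally discarded as solver transient;
cycle choice is a parameter (`cycle_index`).

Pressure and WSS are **normalized to the parent vessel**: each value is
divided by the average of the same quantity over an inlet cross-section
1 mm proximal to the aneurysm,

> normalized pressure = P / P_ave(inlet), normalized WSS = |tau| / WSS_ave(inlet),

which removes dependence on the inflow boundary conditions. The inlet plane
is user-specified (origin, normal, slab thickness); its averages are
area-weighted by default (per-vertex areas, one third of incident face
area), with `weighted = FALSE` available because a vertex-count mean is the
other defensible reading. A non-positive inlet average is an error, not
silently re-gauged: the analysis convention is zero pressure at the outlets,
so a negative inlet mean indicates a gauge the normalization was not meant
for.

TAWSS and OSI use the standard cycle-integral definitions

- TAWSS = (1/T) &int;<sub>0</sub><sup>T</sup> |tau(t)| dt
- OSI = 0.5 (1 − |&int; tau dt| / &int; |tau| dt)

integrated by the trapezoidal rule on the supplied (possibly non-uniform)
time grid. OSI is 0 for a unidirectional WSS history, 0.5 for perfect
reversal, and undefined for an identically zero history — such points
return `NA` and are excluded from the statistics with their count reported.
Refining the grid of a smooth field converges at second order (tested).

## Point distribution

The study condition is "points evenly distributed with a 0.5-mm distance".
The original tooling (a commercial point-cloud function) documents no
algorithm, so the package defines one explicitly: Poisson-disk sampling by
greedy dart throwing over a dense area-weighted candidate set drawn on the
triangle faces, with acceptance radius `spacing * (1 - spacing_tolerance)`
and `spacing_tolerance = 0.05`. This guarantees the minimum pairwise
distance and, at the default candidate density (40 per spacing² of area),
saturates the surface, so no further point could be added at the nominal
spacing (checked stochastically in the tests). Distances are Euclidean 3D
chords, not geodesics: at 0.5 mm on a millimetre-scale sac the difference
is far below the spacing tolerance. The result is deterministic given the
seed.

Fields are measured at a point by barycentric interpolation on its anchor
face — exact for fields linear in position per face. Points inherit the
majority region label of their anchor face's vertices; ties resolve toward
`bleb`, the conservative direction when characterising the bleb region.

## Centers of divergent WSS vectors

The original analysis identified "centers of radically divergent WSS
vectors" visually, as arrowhead annotations on vector maps. The package
replaces inspection with an explicit operator on the peak-systole field:

1. project the WSS vectors into the vertex tangent planes (WSS is
   tangential by definition; the projection removes numerical normal
   components);
2. compute the discrete surface divergence: per-face constant divergence
   from linear shape functions, area-averaged to vertices;
3. flag vertices that are one-ring local maxima of divergence above the
   `min_divergence_percentile` (default 95) of the searched domain, whose
   one-ring edges carry outward-pointing flow on at least
   `outflow_fraction_threshold` (default 0.8) of edges, and that are at
   least `min_separation_mm` (default 1.0 mm) from stronger centers.

The outflow test evaluates the field at the *ring* vertices: the field at
the candidate itself is near zero at a genuine source and would contribute
only noise. Boundary (neck-ring) vertices are excluded to avoid spurious
rim maxima. The defaults were chosen on, and are only validated against,
the synthetic generator — there is no quantitative definition of "radically
divergent" to inherit. Detection is scale-invariant in the field magnitude
(percentile threshold, sign tests). Each detected center is assigned to its
nearest sample point (`is_center = TRUE`, ties to the lower point id); two
centers landing on one point is an error instructing the caller to sample
more densely, not a silent merge.

## Region statistics

Continuous parameters are compared with a two-sided Mann-Whitney U test.
`exact` mode computes the full permutation distribution of U over all
C(n, n_a) group assignments by dynamic programming over midranks — ties are
handled exactly, unlike the usual exact routines that fall back to the
normal approximation — and is the default when the smaller group has at
most 12 points, the situation the method was designed for (8-11 bleb
points). Larger groups use the normal approximation with continuity and
tie corrections. Both modes are validated against brute-force enumeration
and against `wilcox.test`.

Center prevalence is compared with a two-sided Fisher exact test
(conditional-probability criterion: the sum of probabilities of all
equally-or-less-likely tables with the observed margins), validated against
exhaustive hypergeometric enumeration and `fisher.test`. Two contingency
constructions are provided. `as_printed` (default) uses columns
(center count, total point count) per region; `conventional` uses
(center count, non-center count). The published per-case and pooled
p-values (0.156, 0.114, 0.025) are reproduced exactly by the `as_printed`
construction applied to the published counts — the arithmetic implies that
is how the original tables were fed to the statistics package, though no
text states it — so that is the default, with the statistically standard
construction available and documented. The original results section prints
the pooled value once as 0.25 where its table and abstract print 0.025;
the package follows the table and flags the discrepancy rather than
reconciling it silently. Significance is reported at p < 0.05 with no
multiple-testing correction, matching the original analysis. Summaries are
mean ± sample SD (n − 1), per case and pooled.

Points on a surface are spatially correlated; treating them as independent
observations is an inherited assumption of the method, not a claim of this
package. The null calibration below quantifies its consequences under the
generator's noise model only.

## The synthetic generator

No CFD fields are deposited with the original study, so the generator
stands in for them with known ground truth. It emulates, at Case 1's scale:

- **Geometry** — a sac of radius 1.75 mm (3.5 mm diameter) built as an
  icosphere cap cut at a 135° half-angle (a beyond-hemisphere sac with a
  narrowed neck, ~33 mm², giving ~90-100 sample points at 0.5-mm spacing —
  the order of the published 146/152 per aneurysm), over an open parent
  tube of radius 1.5 mm; the inlet ring sits 1 mm proximal to the sac. The
  bleb patch is a geodesic disc of radius 0.9 mm (~8% of the sac, the order
  of the published bleb-point fractions).
- **Pressure** — a uniform level (1500 Pa) with a small axial drop, plus a
  Gaussian bump centred on the bleb patch and scaled so the dome maximum
  divided by the inlet average equals the target (default 1.04, the
  published Case 1 maximum). The scaling solves for the bump amplitude
  against the same area-weighted inlet average the pipeline computes, so
  the target is exact before noise.
- **WSS** — a unit tangential base-flow direction of uniform magnitude
  (6 Pa on the sac, 7 Pa on the tube), attenuated inside a low-WSS patch
  co-located with the bleb patch (residual factor 0.3); one planted radial
  source per region (strength 3 Pa, width 0.5 mm), with the base flow
  suppressed in a slightly wider window so each source is a true
  stagnation-like divergence center of the total field; an orthogonal
  oscillatory component (2 Pa, zero-mean over the cycle) inside the bleb
  patch that raises OSI locally.
- **Waveform** — a positive two-harmonic pulse of period 1.80 s peaking at
  0.36 s into each cycle; fields cover the second cycle in 21 steps.
- **Noise** — i.i.d. Gaussian (1 Pa pressure, 0.05 Pa per WSS component).

A geometric note: the base direction field is the normalized pushforward of
a constant planar field under the inverse stereographic map from the sac's
excluded pole. A spherical cap admits such a nowhere-zero tangent field;
naive constructions (projecting a constant 3D vector and normalizing)
necessarily carry direction defects whose spurious divergence rivals the
planted sources.

`make_null_fields()` removes every region-dependent ingredient (bump,
patches, sources, oscillation, axial gradient) for type-I-error
calibration. The generator is bit-reproducible given (spec, seed) and does
not disturb the session RNG.

What the generator does **not** emulate: real intra-aneurysmal flow
structure (impingement jets, secondary vortices), spatially correlated
solver error, wall compliance, inter-aneurysm variability, or the morphology
of real sacs. Passing the recovery tests therefore shows the pipeline
measures what it claims on fields with known structure — not that the
biological conclusions transfer.

## Numerical choices and degenerate inputs

- Trapezoidal integration on the supplied grid; the analysis accepts any
  strictly increasing time grid spanning at most one period.
- Zero-area faces are excluded from divergence with a warning; isolated
  vertices are rejected at mesh construction.
- OSI is clamped to [0, 0.5] against floating-point leakage; identically
  zero WSS histories yield `NA`.
- STL input merges coincident corners on a 1e-6-mm grid; meshes round-trip
  through PLY/VTK to 1e-5 mm with exact topology.
- Field containers on disk are plain text (a CSV + JSON directory layout,
  or a legacy-VTK file sequence); units are fixed (mm, Pa, s) with no
  inference.

## Problem sizes in the tests

The test suite regenerates everything it uses: the default synthetic case
(~1350 vertices, 21 time steps), 20 seeds for planted-pattern recovery,
200 null seeds for calibration (Mann-Whitney rejection rate at the 0.05
level within [0.01, 0.10]; Fisher rejection rate below 0.10), 1000 random
tables for the Fisher oracle and every two-group partition of n ≤ 10 for
the Mann-Whitney oracle. These sizes keep a full run to a few minutes on
one CPU while leaving the binomial noise on the calibration rates small
against the tested bands.

## Known limitations

- Point-level inference ignores spatial autocorrelation (inherited from
  the method; see above).
- Detection defaults for "radically divergent" are generator-calibrated;
  on real CFD output they are starting values, not validated thresholds.
- Euclidean (chord) spacing, not geodesic; negligible at 0.5 mm on
  millimetre-scale sacs, not for coarse spacings on highly curved patches.
- The synthetic sac has no real-data realism (see generator notes); the
  published group means are not reproducible without the original CFD
  fields, and the package does not attempt them — only the published
  contingency counts are re-analysed exactly.
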