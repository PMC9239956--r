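---
title: "Methods behind mrlqa: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind mrlqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrlqa)
```

mrlqa implements the machine-QA computations a physics team runs when
commissioning a ring-gantry MR-linac: locating ballbearing projections on
megavoltage portal images, fitting the MV radiation isocentre, comparing
planar dose maps with the gamma index, and the reference-dosimetry chain for
an ionization chamber inside a 1.5 T magnetic field. Because the analyses
are meaningless without data, the package ships a synthetic phantom/image
simulator with exact ground truth; every analysis is exercised and tested
against it. This vignette records the models, the conventions and the
numerical decisions, in the spirit of a methods section.

## Geometry and coordinate conventions

All analyses share one `machine_geometry()`: source-axis distance (SAD,
default 143.5 cm — this machine type places the isocentre 143.5 cm from
the source), source-to-imager distance (SID), panel pixel pitch, and the
maximum imaged field at the isocentre plane (22.0 x 9.5 cm). SID and pixel
pitch are not public machine constants, so they are configuration values;
the defaults (SID 215.25 cm, i.e. magnification M = SID/SAD = 1.5, and
0.25 mm/px) are round placeholders a user should replace with their
machine's values. None of the isocentre mathematics depends on their
absolute values, only on using the *same* geometry for simulation and
analysis.

Angles follow IEC61217: the beam points down (-Z) at gantry 0 and rotation
is about Y. The panel u axis increases with +X at gantry 0 and rotates with
the gantry; pixel coordinates are 0-based with (0, 0) top-left; physical
panel coordinates are mm relative to the central pixel. Projection uses
full similar-triangle magnification from the point's actual distance to the
source — no parallel-ray approximation — although for the millimetre-scale
offsets of isocentre work the difference from `M * offset` is below a
micrometre.

One sign subtlety deserves a paragraph, because it is the difference
between a correct and a mirrored isocentre. The gantry ring is rigid:
source and imager move together. When the beam axis wobbles to `+o` in the
isocentre plane, the phantom's ballbearing — fixed in the room — appears
displaced by `-M * o` relative to the central pixel. Back-projecting a
measured image displacement `u` therefore gives two different objects:
`displacement_to_axis_line(u, ...)` returns the *ray through the imaged
object* (perpendicular offset `+u/M`), while `run_isocentre_analysis()`
back-projects the *negated* displacement to obtain the beam-axis line in
phantom coordinates. The simulator and the analysis share this convention,
and the package tests verify the round trip both ways.

## The phantom simulator

`render_mvi()` renders the MV alignment phantom: a central 10.0 mm
ballbearing and two rings of twelve 4.0 mm ballbearings at 30.0 degree
spacing, offset +/-3.5 cm longitudinally. The ring radius is not a
published dimension; 6.5 cm is a fabricated default chosen to fit the
22 cm imaged width, and nothing downstream depends on it.

A ballbearing is drawn as a transmission dip: inside its projected disk of
radius `r` the intensity is multiplied by `1 - c * sqrt(1 - (rho/r)^2)`, a
normalized projected-chord profile with peak contrast `c` (default 0.35).
The normalization makes the integrated deficit proportional to the
projected *area* (diameter squared), which the tests assert. Overlapping
ballbearings multiply their transmissions, so an eclipsed pair is darker
than either alone but less than twice as deep — the behaviour that makes
the eclipse analysis meaningful. Edges are softened with a separable
Gaussian blur (default sigma 0.5 mm at the panel) standing in for source
size, detector glare and partial-volume effects.

The `wobble_model()` is the ground truth generator: a fixed beam-axis
offset plus cosine harmonics of gantry angle per transverse component, an
optional gantry-angle error, additive Gaussian pixel noise, and a
background field (affine ramp plus an optional couch-edge band modelled as
a step with a linear ramp, the artifact that motivates background
subtraction). Every stochastic element is seeded; the same seed renders
bit-identical images, and a projection series derives one seed per image
from the series seed.

What the simulator does *not* emulate — scatter, beam hardening, cryostat
transmission structure, MR distortion, detector lag, panel sag — bounds
what passing tests can claim: they demonstrate that the analysis chain is
correct and precise on images whose degradations are of the modelled kinds,
not that any physical machine meets tolerance.

For dosimetry, `make_dose_pair()` builds analytic reference/evaluated map
pairs (uniform, wedge with a 1 %/mm gradient, a peaked
flattening-filter-free-like field, a three-Gaussian composite) whose
perturbations — uniform scaling, rigid shift applied analytically, and
multiplicative noise — are exact by construction, and
`simulate_chamber_series()` generates reading tables whose influence
quantities are consistent with stated polarity/recombination factors, by
inverting the same formulas the analysis applies.

## Ballbearing localization

A profile through a ballbearing is inverted (`max - value`) so dips become
peaks. Background subtraction averages two flanking profiles symmetric
about the peak row and subtracts them; any background affine in the image
plane cancels *exactly*, and the couch-edge band cancels wherever it is
affine across the three rows. The sub-pixel centre is the midpoint of the
two half-maximum crossings, located by linear interpolation. Two choices
are deliberate:

* the baseline is the *median of the outer 20 %* of samples — robust to
  residual ramps, which a mean or a global minimum is not;
* a flat-topped peak takes the plateau midpoint (midpoint of first and
  last crossings), a stated tie-break rather than an accident of the data.

A peak that never falls below half maximum on one side is reported as
truncated; two disjoint regions above half maximum (two ballbearings in
the region of interest) are ambiguous. Both are errors, not warnings,
because a silently wrong centre corrupts the isocentre fit downstream.

Gantry-angle reproducibility replaces the visual judgement of overlay
images with three numbers: the RMS difference of peak-normalized profiles,
the change in blob centroid separations, and an eclipse score (ratio of
central-blob widths). Partially eclipsed peripheral pairs merge into
single blobs at small angular offsets, so their internal separation change
appears as blob *broadening*; around a degree of offset the pairs resolve
into doublets, which surfaces as a blob-count increase. The package does
not compute an absolute gantry angle — the method compares against a
baseline image and can only establish reproducibility.

## The isocentre fit

Each projection contributes one beam-axis line in the transverse plane.
The isocentre is the *Chebyshev point*: the centre minimizing the maximum
point-to-line distance, and the diameter is twice that minimax distance —
the smallest circle touched or crossed by every axis. Commercial tools do
not publish their definition (2 x RMS residual is another candidate, and
the spread among published values for the same machine suggests
definitional differences); the minimax circle is the standard geometric
construction for a radiation isocentre and, importantly, it is testable:
the package verifies the fit against an exhaustive 0.005 mm grid search on
randomized line sets.

The minimax problem is a three-variable linear program. Rather than
depending on an LP solver, the fit enumerates the LP vertices of a small
active set — pairwise line intersections and line triples under the four
distinct sign patterns of the active distance constraints (a global sign
flip only negates the radius variable, so the centre of a negative-radius
solution is kept as a candidate) — and grows the active set with the worst
violator until no line lies outside the fitted radius. This is exact,
deterministic, and fast for the 30-70 lines of a projection series. At
least three non-parallel lines are required; fewer, or an all-parallel
set, is an angular-coverage error.

`run_isocentre_analysis()` drops the conventionally excluded angles (10
and 20 degrees, where a cryostat pipe crosses the beam; 60 and 300, where
couch edges cross the ballbearing) with a per-image log, applies
background subtraction automatically inside the couch-distortion arcs
(50-130 and 230-310 degrees), skips images whose localization fails while
at least three lines remain, and reports per-projection residuals plus the
longitudinal (v) displacement, which is deliberately excluded from the
transverse diameter.

## Gamma comparison

`gamma_map()` computes the reference-to-evaluation gamma index: for each
reference point above the suppression threshold, the minimum over
evaluated positions within 3 x DTA of
`sqrt((dDose/dD)^2 + (r/DTA)^2)`. Conventions, each a decision where
vendors differ and do not document:

* direction: reference points interrogate the evaluated distribution (the
  dominant convention);
* "local" normalization uses the *reference* dose at the point;
* suppression applies to the reference dose relative to the reference
  maximum (default 10 %); suppressed points are excluded from the pass
  rate's denominator;
* boundary: gamma <= 1.0 passes;
* the evaluated map is bilinearly interpolated and searched at
  0.1 x DTA steps.

A coarse search can straddle a narrow minimum, so the implementation keeps
the twelve best coarse offsets per point and refines around each at a
tenth of the search step. On random map pairs this matches a brute-force
exhaustive search at the fine step to well within 0.02 in gamma, which the
acceptance tests assert. Grid spacing coarser than the DTA triggers a
warning (the criterion is then under-sampled), and non-overlapping grids
are an error.

## Reference dosimetry

The chain follows the standard absorbed-dose-to-water protocol for a
vented chamber, with the magnetic-field extension used on 1.5 T systems:

* `k_tp = (273.2 + T)/(273.2 + 20.0) * 101.325/P`;
* `k_pol = (|M+| + |M-|)/(2 |M|)`;
* `k_s` by the two-voltage method with the pulsed-beam quadratic
  coefficients, linearly interpolated in the voltage ratio over its 2-5
  validity range (this is an FFF pulsed beam; a non-uniformity correction
  is deliberately not applied, matching practice at 10 cm depth where the
  profile is flat over the chamber);
* the magnetic-field correction is the product of the detector-specific
  response factor and the dose conversion factor,
  `k_BQ = k_BMQ * c_B`, rounded to three decimals.

Because the water tank cannot reach the isocentre under 5 cm of water from
the lateral beam, the output is measured at 10 cm depth from G90 and
transferred to the 5 cm calibration depth with the TPR(10,5) measured from
the vertical beam: `D(5) = D(10)/TPR(10,5)`. The expected vertical-beam
output is the lateral output times the cryostat transmission difference
(0.5 % by default, giving the nominal 1.005 Gy per 100 MU for a 1.000 Gy
calibration). Anterior-coil attenuation is `100 * (1 - with/without)` per
gantry angle; the mean excludes angles where the beam misses the coil
entirely (recorded as 0.0 %), because including them would understate the
attenuation when the coil is actually traversed — with the bundled example
table the two conventions give 0.6 % and 0.5 % respectively.

Reported values use half-away-from-zero rounding (k-factors and outputs to
3 decimals, TPR to 3, attenuation to 1), matching how such quantities are
printed; base R's round-half-to-even would turn a 0.45 % mean into 0.4 %.

## Test problem sizes

The self-tests were sized to be thorough yet quick on a laptop: isocentre
series of 32 projections at 0.25 mm pitch, minimax-versus-grid-search
validation on 100 random line sets at 0.005 mm oracle resolution, gamma
oracle agreement on 11 x 11 maps with the exhaustive search at a
hundredth of the DTA, and dosimetry recovery over 7 sessions of reading
triplets at 0.3 % noise — the session structure of a routine output
measurement.

## Known limitations

* The simulator's image physics is stylized (see above); absolute
  contrasts and noise spectra are not those of a real panel.
* Only the transverse isocentre is fitted; longitudinal displacement is
  reported but not folded into a 3-D isocentre.
* The gantry-angle metrics are reproducibility metrics, not an angle
  measurement; thresholds for "discernible" offsets are
  simulator-calibrated, not physically derived.
* DICOM input is not read; images must be exported as 16-bit TIFF/PNG with
  a YAML sidecar.
* The two-voltage coefficients cover pulsed beams only; continuous or
  pulsed-scanned beams are out of scope.
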