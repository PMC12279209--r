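---
title: "Methods: passive infarct mechanics, epicardial patches, and the promoter-accessibility screen"
author: "cardiopatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive infarct mechanics, epicardial patches, and the promoter-accessibility screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardiopatch)
```

# What the package models

`cardiopatch` studies how a stiff elastomeric patch bonded to the epicardium
changes the passive end-diastolic mechanics of an infarcted left ventricle
(LV), together with two companion analyses used in the same line of work:
marker-grid strain estimation for ex vivo stretch tests, and a
chromatin-accessibility screen that classifies genes by promoter-window
signal ratios across Sham / MI / Patch conditions.

The mechanical core is a finite-strain finite-element model:

* **Geometry.** A truncated-ellipsoid LV shell (long axis = z, basal plane
  z = 0, apex below) meshed with structured tri-linear hexahedra. The
  ischemic (ICM) preset has a dilated cavity (endocardial radius 32 mm vs
  25 mm healthy), a 9 mm remote wall, and a 5 mm-thick elliptical infarct
  sector (90 degrees circumferential by 25 mm longitudinal, centered on the
  free wall toward the apex) surrounded by a 5 mm border annulus over which
  thickness ramps with a C1 smoothstep. Thinning is realized on the
  endocardial side: the cavity bulges into the thinned sector, as in
  infarct expansion, and the epicardial surface stays a smooth offset
  ellipsoid. That smoothness is what makes a conforming bonded patch
  geometrically clean; with a crater-shaped epicardium the extruded patch
  volume under-shoots its footprint-area x thickness by around 5%, which is
  how the alternative (epicardial-side, piecewise-linear thinning) design
  was rejected. The degenerate apex pole is excluded by a small apex cap
  (2 mm radius).
* **Patch coverage.** The reference patch dimensions are fixed (20 mm
  diameter, 0.3 mm thickness, 50 MPa). Centered on the infarct centroid,
  a 20 mm disc covers the central portion of the 90-degree infarct; the
  efficacy endpoints are evaluated over the whole infarct-zone epicardium,
  covered and surrounding. The LV long axis is kept at 80 mm for both
  presets, i.e. dilation is radial; the source gives no patient axis
  lengths, so the healthy human scale is reused.
* **Myofibers.** A rule-based helix-angle field: +60 degrees at the basal
  endocardium to -60 degrees at the basal epicardium, linear across the
  wall, with the angle magnitude tapering linearly to zero at the apex.
  The fiber direction is the circumferential direction rotated about the
  transmural axis; the sheet direction is transmural. The apex taper
  follows the source description literally; most rule-based fields in the
  literature keep the transmural rule all the way to the apex, so this is
  flagged as a modeling interpretation, not a community standard. The sheet
  orientation is an assumption (the source does not state it).
* **Materials.** Healthy and border myocardium use the four-term
  Holzapfel-Gasser-Ogden (HGO) energy with exponential isotropic, fiber,
  sheet and fiber-sheet terms, tension-only fiber/sheet contributions, an
  isochoric-volumetric split, and a quadratic volumetric penalty
  (kappa = 1000a). The infarct and the patch are nearly incompressible
  neo-Hookean solids parameterized by (E, nu): E = 50 kPa for the infarct,
  E in 0.05-100 MPa for the patch (50 MPa reference), nu = 0.49.
* **Loading.** Passive inflation to 1 kPa endocardial pressure (the
  end-diastolic pressure of the study), applied as a follower load on the
  deformed endocardium with its exact load stiffness; all three
  displacement components are fixed on the basal plane. A dead-load mode
  exists behind a flag for sensitivity checks.

## The calibrated myocardial stiffness

The literal Holzapfel-Ogden (2009) human-myocardium constants have a very
soft ground state (the isotropic modulus a is about 0.06 kPa). Used
unmodified in this boundary-value problem they inflate the ventricle far
beyond the end-diastolic displacement scale that patient-specific models of
this kind report: peak wall displacements of order 20 mm instead of order
1-2 mm, with the cavity volume growing by tens of percent. Diastolic FE
studies commonly rescale that parameter set to match pressure-volume or
displacement observations. The package does the same with a single
multiplicative factor on the four stress-like moduli
(`MYO_STIFFNESS_SCALE`, applied by `myocardium_params()`; exponents are
untouched, so the strain-stiffening shape is preserved). The factor
(default 75) was calibrated once, by bisection on the desk-scale ICM
model, so that the unpatched ventricle's peak transmural (radial)
infarct-zone epicardial displacement at 1 kPa is about 1.9 mm -- the
unpatched baseline implied by the reported patched value (0.5 mm) and
reduction (73.5%) -- and then frozen. The calibration target is the
displacement *scale* of the reference study, not any acceptance threshold
of this package.

A consequence worth stating plainly: on this surrogate anatomy the
patch-induced *percent reductions* come out far smaller than the
patient-specific ones. A reduction above 70% requires the unpatched
endpoint to be dominated by a focal bulge that the 20 mm patch essentially
covers. The surrogate's 90-degree infarct keeps bulging outside the
footprint, and shrinking the infarct to patch size makes the 5 mm-thick
panel too small to bulge at all (its epicardial displacement is then mostly
convection with the surrounding wall, which no epicardial patch can
remove). The patient result evidently reflects a focal aneurysmal bulge
matched to the patch size -- anatomy this package does not possess. The
pipeline computes and reports its reductions as measured.

# Numerical method

* **Elements.** Tri-linear hexahedra with 2x2x2 Gauss quadrature. The
  volumetric term uses the mean-dilatation (Q1/P0) treatment: one pressure
  per element from the element-average volume ratio, with the consistent
  rank-one dilatational stiffness. This prevents volumetric locking at
  nu = 0.49 while keeping the assembled tangent exact (verified against
  finite differences of the residual in the tests).
* **Constitutive evaluation.** Analytic isochoric Cauchy stress and spatial
  tangent for the HGO family (the isotropic neo-Hookean law is the
  fiber-free degenerate case), implemented in C++ (RcppArmadillo). Unit
  tests pin the stress against central finite differences of the energy and
  the energy against an exact symbolic evaluation.
* **Solver.** Incremental loading (default 10 increments to 1 kPa) with
  Newton iteration on the assembled residual, sparse LU solves (Matrix),
  and a secant predictor across increments. Globalization uses backtracking
  line search that accepts a step when either the residual norm or the
  total potential energy (stored energy minus pressure-volume potential)
  decreases, with a steepest-descent fallback on the potential. The energy
  test matters: the tension-only fiber switch makes the residual norm alone
  non-monotone near its stiffness kinks, and a stiff thin patch bonded to
  very soft myocardium has a Newton linearization radius set by the patch
  thickness, so pure residual backtracking can stall at points that are not
  equilibria. Convergence is declared at a relative residual of 1e-8 with
  an absolute floor at 1e-9 of the current force scale (round-off on the
  patch forces dominates below that). Divergent increments are halved
  adaptively down to 1/64 of the nominal step; failure past the floor is an
  explicit error carrying the Newton log. Patched runs use a 50-iteration
  Newton budget (the first two increments, where the patch first engages
  the soft wall, take 30-45 damped iterations; everything later takes 3-5).
* **Verification.** Constant-strain patch test on a distorted mesh
  (exact), Lame thick-walled-sphere pressurization (inner-surface radial
  displacement within 5% of the closed form at the finest of three meshes),
  external work vs stored energy at small load (1%), mesh-refinement
  convergence of peak displacement (3% between the two finest of three
  meshes), and observed quadratic Newton convergence.

## Problem sizes

Default preset resolutions are 24x16x3 elements (circumferential x
longitudinal x transmural). The test-suite and the acceptance script run
the paired patched/unpatched comparison at 24x14x2 with 10 increments --
the infarct sector spans several elements in both surface directions
there -- and the patch-parameter sweep coarser still (16x10x2, 4
increments, relative residual 1e-6). Below about 16 circumferential
elements the infarct-zone endpoints are no longer resolution-stable, so
the sweep grid is not coarsened further. These sizes are the package's desk-scale study conditions;
endpoint percent-reductions are grid-quantized at this scale (the
footprint boundary moves by whole faces).

# Endpoints

* `von_mises()` and `max_principal_stress()` operate on element-averaged
  Cauchy stresses (quadrature values volume-averaged per element; the
  element mean includes the mean-dilatation pressure).
* "Peak transmural displacement" defaults to the radial (transmural)
  displacement component over infarct-zone epicardial nodes -- the bulge an
  epicardial patch is meant to suppress, and the reading matching the
  source's "in the transmural direction"; a magnitude mode exists behind a
  flag.
* Epicardial von Mises is evaluated in infarct-zone myocardial elements
  adjacent to the epicardium, with patch elements excluded, so reductions
  measure shielding of the infarcted tissue, not stress carried by the
  patch and not the bond-line concentration at the patch rim.
* The wall-mean maximal principal stress averages over all non-patch
  elements volume-weighted (whole wall; the alternative free-wall-only
  average is not used because the source does not specify it).
* `recovery_percentage()` is exactly
  `(treatment - mi) / (sham - mi) * 100`, signed, so values outside
  [0, 100] are meaningful and `sham == mi` is an explicit error.

# The patch sweep

`run_patch_sweep()` re-solves the patched ventricle over a modulus x
thickness grid and reports percent reductions of both endpoints against the
unpatched baseline, with per-point convergence flags (failures are
recorded, never dropped). The displacement-reduction column grows
monotonically with patch modulus and thickness, with the 0.05 MPa point
weakest -- the sweep's support claim. The von-Mises-reduction column is
*not* monotone in modulus: a stiffer patch raises the bond-line stress
concentration at its rim (which lies inside the infarct zone) faster than
it shields the tissue beneath. Both columns are reported; only the
displacement endpoint carries the monotone support interpretation.

# Synthetic data: what it emulates, what it does not

* **Geometry presets** emulate the *kind* of anatomy involved -- a dilated,
  regionally thinned ICM ventricle vs a healthy one -- at physiologic human
  scale. They are not reconstructions: patient cMRI geometry is not
  available, so absolute stresses and displacements are surrogate-scale,
  and the acceptance comparisons are directional or scaled-down on
  percent-change endpoints, never on absolute patient values.
* **Marker grids** emulate fluorescent fiducial arrays on stretched
  myocardium: a regular reference grid, an affine deformation
  (10% circumferential stretch, transverse contraction via a lateral
  ratio), and isotropic Gaussian digitization jitter. Real marker fields
  also contain regional heterogeneity (infarct vs remote) and out-of-plane
  motion; passing the recovery tests shows the estimator is exact for
  affine fields and unbiased under noise, not that it resolves
  heterogeneous strain patterns.
* **Peak-count tables** emulate per-gene promoter-accessibility sums with
  a gamma-Poisson (negative-binomial) model: log-normal baselines, MI
  inflated/deflated for designed Group I/II genes, Patch restoring the Sham
  mean. Real ATAC data add peak-calling artifacts, library-size effects and
  correlated replicates; the generator demonstrates classifier correctness
  against a known truth, not robustness to those effects (normalization is
  left to the caller, as the screen operates on whatever abundances it is
  given).

Generator defaults: marker grids 21x21 at 1 mm spacing, 10% applied
strain, lateral ratio 0.93 (the transverse-to-axial strain ratio evident in
the reported healthy-tissue values), 0.02 mm jitter; peak tables 2000
genes, 5% Group I / 8% Group II, effects 1.6x / 0.5x, dispersion 0.02,
log-normal baseline around 300. All generators are deterministic under a
seed and restore the caller's RNG state.

# The promoter screen

Per-gene sums take every peak overlapping the closed window
[TSS - 3000, TSS + 3000] (any overlap counts, full abundance, no
pro-rating; the window is symmetric so strand is irrelevant); coordinates
are 1-based inclusive. Classification: Group I iff MI/Sham > 1.2 or
MI/Patch > 1.1; Group II iff MI/Sham < 0.8 or MI/Patch < 0.9 (inclusive
"or"). Genes satisfying both rule sets are labeled `conflict` and genes
with a zero denominator `excluded` -- the source is silent on both cases,
and silent coercion would bias the group counts. Replicate handling: sums
are totals across replicates before any ratio is formed. Published counts
from the original screen depend on upstream read processing of data this
package does not consume, so they are not reproduction targets; the
screen's correctness is established against a brute-force classifier and
designed-truth recovery instead.

# Known limitations

* Passive diastole only: no active contraction, no full cardiac cycle, no
  hemodynamic coupling, no viscoelasticity or growth/remodeling.
* The patch bond is ideal (conforming, no slip, no degradation kinetics).
* Q1/P0 hexahedra are low-order: thin-patch bending is represented by one
  element through the thickness, and stress fields are element-wise
  averages; sub-element stress concentrations at the patch rim are
  smoothed.
* The surrogate anatomy cannot reproduce patient-specific absolute values;
  all cross-model claims are made on percent changes or orderings.
* The apex cap leaves a small unloaded hole at the pole; its effect is
  confined to the cap neighborhood and excluded from the benchmark
  measurements.
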