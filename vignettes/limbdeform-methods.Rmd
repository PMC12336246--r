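---
title: "Methods: predicting and measuring tissue deformation under compression leggings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting and measuring tissue deformation under compression leggings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbdeform)
```

`limbdeform` couples an analytical elasticity model of the leggings–leg
system with a scan-based measurement pipeline. This vignette records the
model, the conventions, and the design choices that were genuinely open —
the things a maintainer would otherwise have to reverse-engineer from the
code.

## 1. The analytical model

### Fabric constants

Knitted legging fabric is treated as an orthotropic lamina with distinct
course (x) and wale (y) moduli. The plane-stress compliance matrix has
`S11 = 1/Ex`, `S22 = 1/Ey`, `S66 = 1/Gxy` and off-diagonals `-vxy/Ex`. Two
choices here:

* **Slope estimation.** `estimate_modulus()` fits an ordinary least-squares
  line *with* intercept and reports the slope, rather than taking a
  two-point stress/strain ratio. The measured fabrics are linear to a
  Pearson correlation of about 0.99 over the working range, so a fitted
  slope is the natural estimator, and the free intercept absorbs load-cell
  offset.
* **Reciprocity.** Only `vxy` is measured, so both off-diagonal compliance
  entries are stored as `-vxy/Ex`, imposing the orthotropic reciprocity
  `vxy/Ex = vyx/Ey`. Compliance symmetry is physically required; storing an
  asymmetric matrix would make the strain energy path-dependent.

Units are Pa throughout, engineering strain, no unit-conversion layer.

### Stretch to pressure

The worn garment's radial extension `ul` (mm) maps to interface pressure by

\[ P = \frac{\pi E_x u_l}{2 (1 - v_{xy}^2) R}. \]

This is a Boussinesq-lineage surface relation (deflection proportional to
\((1-v^2)P/(\pi E)\)); the exponent of \(R\) is the one genuinely ambiguous
piece of the derivation, and the choice (linear in \(R\)) is isolated in
`interface_pressure()` so it can be swapped. Dimensional analysis fixes
everything else: with \(P\) and \(E_x\) both in Pa, \(u_l\) and \(R\) carry
the same length unit, so the formula is scale-free in mm.

Garment stretch itself comes from circumferences:
`ul = max(0, limb_circumference - garment_circumference) / (2 pi)` — a loose
garment exerts nothing.

### Annulus stress field

`lame_field()` returns the classical thick-walled-cylinder solution
\(\sigma_\rho = A/r^2 + 2C\), \(\sigma_\varphi = -A/r^2 + 2C\) with
\(A = -P a^2 b^2/(b^2-a^2)\), \(2C = P a^2/(b^2-a^2)\), satisfying
\(\sigma_\rho(a) = -P\), \(\sigma_\rho(b) = 0\) to round-off. It documents
the fabric's stress state; the deformation chain does not consume it.

### Tissue constitutive model

Static deformation uses the linear surface-deflection form
\(u_s = (1 - v_s) P R / E_s\). The soft tissue is alternatively described by
Neo-Hookean constants with the standard conversions

\[ C_1 = \frac{E_s}{4(1+v_s)}, \qquad D_1 = \frac{6(1-2v_s)}{E_s}, \]

i.e. half the shear modulus and twice the inverse bulk modulus. The inverse
is closed-form: \(E_s = 18 C_1 / (3 + C_1 D_1)\),
\(v_s = (6 - D_1 E_s)/12\). `static_deformation_nh()` is *defined* as the
\((C_1, D_1)\) reparameterisation of the linear form, and the package
enforces their equivalence as a contract (tested to 1e-6 relative over
randomised parameters). At garment pressures the tissue operates at small
strain, so the hyperelastic model only reparameterises stiffness; a genuinely
finite-strain treatment is out of scope. The literature pair
\(C_1 \approx 5000\) Pa, \(D_1 \approx 1.4\times10^{-7}\) Pa\(^{-1}\)
inverts to a nearly incompressible tissue of \(E_s \approx 30\) kPa
(\(v_s \approx 0.4997\)) — physiologically sensible — and is the default
tissue in the pipeline configuration.

### Dynamics

Under whole-body vibration the garment obeys \(m u'' + k u' = F(t)\),
integrated by classical 4th-order Runge–Kutta on the first-order system
(observed convergence order ≈ 4 against the constant-force closed form).
The tissue follows the static relation at the effective pressure
\(P + F(t)/A_\text{contact}\); the additive pressure–force coupling needs a
contact-area normalisation to be dimensionally meaningful, and
\(A_\text{contact} = 2\pi R h\) (the lateral surface of the section of
height \(h\)) is the default, overridable per call. Defaults: damping
`k = 5` N·s/m, step `dt = 1e-4` s, forcing `F0 sin(2 pi 60 t)` — 60 Hz is
the vibration-platform protocol frequency. Because the tissue map is linear
in pressure, the cycle-mean dynamic displacement equals the static value at
the cycle-mean pressure; inertial forcing raises the per-cycle maximum, and
the per-cycle summary (max/min/mean) is what the trace reports. The mass and
damping used for any published dynamic numbers are not recoverable, so
dynamic magnitudes are reported for the synthetic world only.

All lengths are mm at module boundaries; the dynamics convert to SI
internally through one centralised pair of helpers.

## 2. The measurement pipeline

### Conventions

Section plane viewed from above: x runs to the subject's left, y posterior
to anterior. Ray angle 0 points anterior and increases counter-clockwise,
so the direction at angle \(\theta\) is \((-\sin\theta, \cos\theta)\).
Quadrants: anterior \([-45°, 45°)\), lateral \([45°, 135°)\), posterior
\([135°, 225°)\), medial \([225°, 315°)\). In a two-leg slice the loop whose
centroid has the smaller x is labelled `right` (the scanner faces the
subject); a flip flag inverts this.

### Contour extraction

Marker pixels are selected by the robust-yellow predicate
`R >= 200 & G >= 200 & B <= 100` on 8-bit channels; the permissive
threshold-of-1 variant is available via `marker_predicate(1)`. The largest
8-connected component wins (ties: topmost-then-leftmost centroid, logged);
its boundary pixels, ordered counter-clockwise about the component centroid,
become the contour, with the origin at the image's lower-left corner and
y up.

### Centroid anchoring and radial profiles

The centroid is the *vertex* mean, computed after resampling the contour to
uniform arc length (default 720 vertices). Without resampling, vertex
density — a tessellation artifact — biases the centroid; with it, the
estimator is mesh- and raster-independent. Radial profiles are exact
ray/segment intersections on a uniform angular grid (default 360), taking
the first outward crossing. Crossings more than 5% of the radius apart on
one ray indicate a genuinely non-star-shaped section (strongly curved hip
sections are the expected offenders) and raise a single warning; tighter
clusters are rasterisation jitter and stay silent. Grazing rays fall back to
the angularly nearest vertex.

### Deformation and what anchoring can and cannot cancel

Deformation is `control radius - garment radius` per angle, each profile
anchored at *its own* centroid. This cancels rigid displacement between
scans exactly (tested to 5e-14 mm for a 5 mm offset). The flip side is a
genuine identifiability limit: a pure \(\cos\theta\) (k = 1 harmonic)
component of a radial deformation field is geometrically the same thing as
a translation — a circle of radius \(R\) shifted by \(\delta\) has polar
radius \(\approx R - \delta\cos\theta\) — so centroid anchoring absorbs it
into displacement and reports only the remaining components. Any method
that cancels motion this way has exactly this null space. The end-to-end
accuracy checks therefore use fields built from k ≥ 2 harmonics, and the
k = 1 absorption itself is pinned by a dedicated test.

### Mesh slicing

STL scan meshes (binary or ASCII, units assumed mm with a scale override)
are sliced by intersecting each triangle with the plane and chaining the
segments into closed loops (endpoints matched after rounding to 1e-6 mm; an
open chain from a cracked mesh is closed with a warning). The plane is
nudged by 1e-7 of the z-extent when it hits a vertex exactly, avoiding
degenerate point intersections. Loops are sorted by descending area.

### Extreme frames

The vibration recording's first-occurring global maximum and minimum define
the dynamic measurement pair. A 60 Hz sinusoid filmed at 120 fps samples
each cycle twice; the synthetic recording defaults to phase \(\pi/2\) so the
frames land on the peaks and the peak-to-peak displacement (9.42 mm at
4.71 mm amplitude) is observable. The published half-cycle interval of
1/30 s is inconsistent with that sampling arithmetic (half a 60 Hz period is
1/120 s); the fixture reproduces the displacement and leaves the timing
discrepancy documented rather than resolved.

## 3. The synthetic world

Generators are pure functions of spec + seed; every output carries its
ground truth.

* **Contours** are Fourier polar curves
  \(r(\theta) = R + \sum_k a_k \cos(k\theta + \varphi_k)\) with
  \(\sum_k |a_k| < R\), guaranteeing star shape — matching the model's
  near-circular-leg assumption while allowing controlled asphericity (the
  hip stress test).
* **The default limb** takes the six section radii from a legging sample's
  garment circumferences divided by \(2\pi\), inflated 10% (within the
  5–15% band that produces positive stretch in every section), with 4%
  k = 2 and 1.5% k = 3 asphericity; the right side gets a different
  harmonic phase and 3% less deformation, emulating mild body asymmetry.
* **Stress–strain records** use 1% multiplicative Gaussian noise by default,
  consistent with the ~0.99 linearity of the measured fabrics; 50 points on
  a strain grid up to 0.5.
* **Images** are ~1 px polylines in marker yellow on black at 0.7 mm/px by
  default (so hip sections fit a 512 px raster); the accuracy acceptance
  check runs at 1024 px and 0.15 mm/px.
* **Vibration** is 4.71 mm amplitude at 60 Hz, 120 fps, 5 cycles.

What a green test establishes: the *measurement machinery* is accurate to
well under 0.1 mm on clean, star-shaped, known-truth sections, and the
model code implements its formulas exactly. What it does not establish:
scanner noise, occlusion, mesh cracks beyond simple open chains, breathing
and postural sway beyond rigid in-plane displacement, or subject-specific
anthropometry — none of which the synthetic world emulates. The pipeline's
predicted-vs-measured deviation on the synthetic world (~1.4 mm with
default settings) is a property of that stated world, not a reproduction of
any published deviation.

## 4. Statistics

`compare_deformation()` reports the mean absolute predicted-minus-measured
deviation (static, and dynamic when supplied), Shapiro–Wilk normality per
group (skipped with a warning below n = 3), and one-way ANOVA F-tests for
left-vs-right and across sections, with the two-tier significance labels
0.05 and 0.005. Whether groups pool angular positions or section means is
not fixed by the protocol; the default pools one mean per side × section,
with `pool = "none"` exposed. These are standard `stats` routines — the
bespoke part is only the grouping.

## 5. Known limitations

* The k = 1 deformation null space described above.
* Non-star-shaped sections are measured by first crossing, which
  under-reports deep concavities.
* The pressure–stretch relation's \(R\)-exponent rests on dimensional
  analysis, not a derivation the source material preserves.
* Viscoelasticity (fabric and tissue), bone, finite-strain tissue response
  and subject-specific geometry are out of scope.
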