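---
title: "Quantifying cranial asymmetry with spherical harmonics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cranial asymmetry with spherical harmonics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniosh)
```

## The problem

Deformational plagiocephaly (DP) is a positional flattening of one posterior
quadrant of an infant's skull, sometimes with a compensatory prominence
elsewhere. Clinically it is screened with calliper and tape measurements —
the cephalic index (CI), the cranial vault asymmetry index (AI, also written
CVAI), and the oblique cranial length ratio (OCLR) — whose interuser
reliability is notoriously poor. When a sparse 3D surface scan of the head is
available (a few hundred points from a coded-cap photogrammetric system),
much more of the shape can be used. `craniosh` implements a pipeline that
turns such a scan into a single asymmetry coefficient:

1. register the cloud into an anatomical frame from three landmarks;
2. fit the *ideal* cranial shape — an axis-aligned triaxial ellipsoid — by
   linear least squares;
3. compute the signed orthogonal distance from every head point to the
   ellipsoid surface;
4. expand those distances, indexed by the foot point's latitude/longitude on
   the ellipsoid, in real spherical harmonics up to a maximum degree
   `lmax` (default 4);
5. read off the degree-2, order −2 coefficient `f22` = \(f_2^{-2}\).

Because the ellipsoid is symmetric about the head's longitudinal axis, the
residual distance field carries the asymmetry. \(Y_2^{-2} \propto
\sin(2\,\mathrm{lon})\) divides the head into four alternating diagonal
quadrants — exactly the pattern of a diagonally flattened (plagiocephalic)
head — so its weight is a natural DP index. A head is screened as DP when
\(|f_2^{-2}| > 0.42\) (raw coefficient scale), alongside the classical rules
(\(|AI|, |AAI|, |PAI| > 4\) mm, OCLR outside 94–106%).

## The model

Each head point \(P\) is modelled as

\[ P \;=\; E(\theta,\varphi) \;+\; \hat v(\theta,\varphi)\,
   \mathrm{SH}(\theta,\varphi, l_{max}) \;+\; \varepsilon , \]

where \(E(\theta,\varphi)\) is the foot point of \(P\) on the best-fitting
ellipsoid, \(\hat v\) the outward unit normal there, and
\(\mathrm{SH} = \sum_{l=0}^{l_{max}} \sum_{m=-l}^{l} f_l^m\,Y_l^m\) a
truncated real spherical-harmonic series fitted to the signed orthogonal
distances by ordinary least squares over the scattered sample sites.

Conventions that matter, fixed package-wide:

* **Harmonic normalization** — 4π-normalized real harmonics *without* the
  Condon–Shortley phase (\(Y_0^0 \equiv 1\); negative orders carry
  \(\sin(|m|\,\mathrm{lon})\)). The 0.42 threshold is only meaningful under
  a fixed convention, so the tag is immutable and recorded in every report.
* **Chart** — geocentric latitude/longitude of the foot point about the
  ellipsoid center (Z pole, longitude from +X toward +Y). The chart is only
  an index for the expansion; geocentric is closed-form and invertible,
  which geodetic latitude is not.
* **Anatomical frame** — origin at the inter-preauricular midpoint, +X
  toward the glabella, +Y the patient's left. With this orientation a
  negative \(f_2^{-2}\) indicates right-side and a positive one left-side
  plagiocephaly.

## Pipeline stages and their numerical choices

**Alignment.** The rigid transform is closed-form: X from the glabella
direction, Y the component of the inter-preauricular vector orthogonal to X
(the exact least-squares axis for two points), Z their cross product. The
transform is orthonormal with determinant +1, so pairwise distances are
preserved to machine precision and alignment is idempotent.

**Ellipsoid fit.** The 6-parameter axis-aligned quadric
\(Ax^2+By^2+Cz^2+Dx+Ey+Fz=1\) is solved by linear least squares and
converted to center/semi-axes by completing the square. Algebraic (not
geometric) least squares is deliberate: it is deterministic and closed-form,
and for near-ellipsoidal clouds the two costs agree closely. Degenerate
clouds (rank < 6, non-positive quadratic coefficients) are rejected with the
offending axis named.

**Orthogonal distances.** The foot point solves a one-parameter Lagrange
problem, \(q_i = c_i + a_i^2 (p_i-c_i)/(a_i^2+t)\) with
\(\sum a_i^2(p_i-c_i)^2/(a_i^2+t)^2 = 1\). On \((-\min a_i^2, \infty)\) this
function is convex and strictly decreasing, so a bisection-safeguarded
Newton iteration converges globally; we iterate to a relative parameter step
of 1e−13 (at most 100 iterations), giving foot points on the surface to
better than 1e−9 relative. Points on the medial axis (never surface data)
are resolved deterministically along the shortest semi-axis and flagged
ambiguous. Signed distance is positive outside the surface.

**Expansion.** Scattered-data OLS on the \((l_{max}+1)^2\) basis values at
the sample sites; no weighting and no regularization by default (an optional
ridge penalty exists for badly covered clouds and is recorded in the
report). The design must be well-conditioned (condition number ≤ 1e8) and
overdetermined, otherwise the fit refuses with a specific error. With ~530
cap-distributed sites and `lmax = 4` (25 unknowns) the system is strongly
overdetermined and the recovered coefficient is unbiased with SD well below
0.1 even at 0.3 mm noise (verified by the parameter-recovery tests).

**Anthropometry.** The cranial perimeter is the maximal 2D convex-hull
perimeter over planes containing the Y direction, searched on a 1° tilt grid
within ±30° of horizontal and a 2 mm offset grid, with a ±4 mm slab to
populate each slice from a sparse cloud (the slab and grid constants are
package constants, recorded in every report). Ties are broken toward the
least-tilted plane so that rotationally degenerate shapes (a sphere) give
the canonical horizontal slice. The oblique diagonals are chords of that
slice through the anatomical origin at ±30° azimuth; splitting each chord at
the origin makes \(AI = AAI + PAI\) an exact identity of this
implementation. Printed clinical tables do not always satisfy that identity,
so their frontal/back split was operationally different; no attempt is made
to force agreement. CI is computed as 100·width/length — printed clinical
CI values of 76–90% force this reading even where the formula is typeset the
other way around.

**Screening.** Asymmetry flags use a *strict* 4 mm rule (printed tables
leave |value| = 4 unflagged, although the accompanying text says "below
4 mm" is normal — the table wins); OCLR bounds [94, 106] are
inclusive-normal; CI outside [75, 95] raises an informational
brachy-/scaphocephaly flag that never enters the DP call. The harmonic rule
is strict: DP iff \(|f_2^{-2}| > 0.42\) at `lmax = 4`. Group comparison
takes absolute values, reports Shapiro–Wilk and Levene diagnostics without
gating, and ranks parameters by the two-sided pooled-variance Student
t-test, uncorrected (ranking, not inference).

## The synthetic-data generator

Real infant scans cannot be redistributed, so the generator is a first-class
module. A head is a triaxial ellipsoid (default semi-axes 85, 65, 60 mm)
sampled at 530 area-uniform Fibonacci-spiral sites restricted to latitudes
above −25° (emulating a cap that does not reach the head base), deformed by
smooth Gaussian bumps in great-circle angle applied along the outward
normal, plus 0.3 mm Gaussian measurement noise along the normal. Landmarks
sit exactly at the ±Y and +X surface points. Defaults were chosen once to
match the clinical description of the source system: ~530 evenly distributed
points, sub-millimetre noise, head-sized ellipsoid; the bump latitude (10°)
and angular SD (45°) are the package's own choice of a smooth, realistic
posterior flattening (the SD floor of 20° keeps the planted field
representable at low degree). Deformation is parameterised as Gaussian bumps
rather than as a planted \(Y_2^{-2}\) precisely so that coefficient-recovery
tests are not circular.

Cohorts mirror a small clinical study: 8 healthy + 10 DP heads, DP
amplitudes uniform in 5–10 mm, azimuth uniform in the posterior band
[120°, 240°], 50% with an opposite-sign compensation bump at the antipodal
azimuth, per-head semi-axes jittered ±10%, all randomness derived from one
master seed.

What the generator does *not* emulate: skull growth, scalp texture,
landmark placement error (available as an option but off by default),
craniosynostosis shape families, and — important for interpreting the
statistical tests below — the *parallelogram* compensation pattern of real
DP, in which the ipsilateral forehead bosses. Passing tests on synthetic
cohorts therefore validate the measurement pipeline, not the clinical
discrimination performance on real heads.

### Two properties that looked obvious and are false

Both are direct consequences of the generator's geometry and worth recording.

*Antipodal compensation is invisible to both f22 and AI.* Since
\(\sin(2(\mathrm{lon}+180°)) = \sin(2\,\mathrm{lon})\), a flattening at
azimuth \(\varphi_0\) and an equal opposite-sign bump at \(\varphi_0+180°\)
cancel exactly in \(f_2^{-2}\); the same pairing cancels in the oblique
chord difference. Likewise a flattening centred on the sagittal plane
(azimuth ≈ 180°) has no \(\sin 2\varphi\) content at all. Roughly half the
generated DP heads therefore carry little or no signal in *either* index,
which makes |f22| and |AI| almost perfectly correlated across heads: in 50
simulated cohorts the t-test p value for |f22| is lower than that for |AI|
in 68% of replicates — a real but much weaker ranking advantage than
clinical data shows, where compensation is diagonal and reinforces f22
while cancelling AI. The posterior-only indexes (PAI, |AAI|+|PAI|) remain
sensitive in these cases, which is exactly the clinical argument for them.

*p values are not monotone in severity.* Doubling every DP amplitude
doubles the mean |f22| group gap (a property the tests assert), but once
the DP group's between-head spread dominates the pooled variance the t
statistic is invariant under amplitude scaling, so the p value can tick up
as well as down.

## Worked example

```{r example}
g <- generate_head(synthetic_spec(
  deformations = list(list(azimuth = 135, lat = 10, amplitude = -8, sd = 45)),
  seed = 42), id = "demo-dp")
report <- analyze_head(g$model)
report
```

A back-left flattening of 8 mm yields a positive \(f_2^{-2}\) well above
0.42 (left-side DP), while the classical indexes respond through PAI and
AI. An undeformed head gives \(|f_2^{-2}|\) at the noise floor (~0.01–0.04):

```{r null}
h <- generate_head(synthetic_spec(seed = 7), id = "demo-healthy")
analyze_head(h$model)$indexes$f22
```

## Problem sizes and determinism

All analysis stages are seed-free and deterministic; randomness exists only
in the generator and flows from explicit seeds. The validation suite uses
the cohort sizes of the emulated study design (18 heads), 100 healthy heads
for the false-positive control of the 0.42 threshold, 50 cohort replicates
for the ranking comparison, 200 replicates for coefficient-recovery
statistics, and 1000 points for the foot-point oracle comparison — sizes
chosen to make the Monte-Carlo error comfortably smaller than the margins
being tested while keeping a laptop run short.

## Known limitations

* The algebraic ellipsoid fit slightly biases semi-axes on strongly deformed
  heads relative to a geometric fit; both the deformation and the reference
  surface move together, so the *coefficient* is barely affected, but the
  fitted center/axes should not be over-interpreted.
* With cap coverage only (no head base), degrees above ~6 become
  progressively ill-conditioned; the fit refuses above condition number 1e8
  rather than silently extrapolating, and the optional ridge penalty is the
  escape hatch.
* The screening thresholds (4 mm, 94–106%, 75–95%, 0.42) are fixed clinical
  conventions, not fitted quantities; no ROC optimisation is attempted.
* CP from a ±4 mm slab of ~530 points underestimates a true tape perimeter
  by a fraction of a percent; the 1°/2 mm search grid quantises the plane
  choice.
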