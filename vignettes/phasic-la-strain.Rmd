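---
title: "Phasic left atrial strain from 4D gated CT: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasic left atrial strain from 4D gated CT: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lastrain)
```

## The measurement problem

Left atrial (LA) mechanical function cycles through three phases: the
**reservoir** phase, in which the atrium fills and stretches while the
ventricle contracts; the **conduit** phase, in which it empties passively
during early ventricular diastole; and the **contractile** phase, the active
atrial kick that completes emptying. Impaired passive mechanics reflect
stiffening of the atrial wall (interstitial fibrosis), and impaired active
contraction reflects electrical remodelling — both of clinical interest in
atrial fibrillation.

Conventional 2D strain imaging forshortens the atrium and misses genuinely
three-dimensional motion. Retrospective ECG-gated CT (RGCT) reconstructs the
full 3D anatomy at 10 or 20 phases of the R-R interval at sub-millimetre
resolution, which permits strain measurement directly on the 3D endocardial
surface. `lastrain` implements that measurement chain: deforming surface
meshes in, per-subject phasic strain and strain-rate parameters and cohort
statistics out.

## Area strain and curve aggregation

The deformation measure is **area strain**. For surface element $e$ with
area $A_e(t)$ at normalized R-R time $t$ and end-diastolic reference area
$A_e(0)$,

$$\varepsilon_e(t) = 100\,\frac{A_e(t) - A_e(0)}{A_e(0)}\ [\%],$$

positive for endocardial expansion, negative for contraction. Strain is
elemental, so region labels live on faces, not vertices. The global curve is
the unweighted mean of elemental strains over all LA-body elements
(pulmonary-vein and appendage analogues are labelled `excluded` and
omitted); the five regional curves (septal, lateral, posterior, anterior,
inferior walls) are unweighted means within each label. An area-weighted
mean is available behind the `area_weights` argument but is off by default,
matching the convention of averaging elemental strains directly. Elements
whose reference area falls below $10^{-12}$ mm$^2$ are excluded from
averaging and logged; the geometry core otherwise treats meshes as exact
(areas via the cross product, volumes via the divergence theorem, both
rigid-motion invariant to near machine precision).

Strain rate (SR) is the first derivative of strain with respect to
normalized R-R time: central differences at interior frames and one-sided
differences at the ends, with no smoothing by default so that the SR curve
has an exact discrete inverse (the reconstruction recurrence
$S_{i+1} = S_{i-1} + 2\,\Delta t\,\mathrm{SR}_i$ is tested to machine
precision). Spline differentiation would look smoother but makes peak SR
depend on a tuning parameter; we keep it opt-in by smoothing the input
curves instead, should a user want it.

## Phase segmentation

Phases are read off the **global** curve and applied to every scope:

* End-diastole ($t_{ed}$) is the strain minimum. If the minimum is not at
  frame 1, the curve is cyclically re-referenced: times rotate and strains
  re-zero at the minimum frame. This honours the convention that minimum LA
  strain defines end-diastole while keeping frame 1 as the tracked
  reference.
* $t_{peak}$ is the argmax of a monotone-cubic (Fritsch–Carlson)
  interpolant of the sampled curve, so a peak falling between frames is not
  truncated to the nearer sample.
* $t_{cc}$, the conduit–contractile boundary, is the **level-off point**:
  on the interpolant's post-peak segment, the earliest time at which the
  downslope magnitude falls below $\alpha$ times the peak *conduit*
  downslope, with $\alpha = 0.2$ (exposed as `alpha` everywhere). The peak
  conduit downslope is the first local minimum of $dS/dt$ after the peak —
  at coarse sampling the later contractile downslope can be steeper, and
  must not win. The detected $t_{cc}$ is snapped to the nearest frame time:
  phases are ultimately read at frame resolution, as in manual review.
* Detection failures (no positive peak, no post-peak level-off, level-off
  inside the terminal return to baseline or the last sampling interval)
  return an explicit `needs_correction` status. `correct_phases()` is the
  manual-review hook; it overrides $t_{cc}$ and records
  `detection_mode = "corrected"`. Nothing is silently defaulted.

Given boundaries, the phasic strains are

$$\text{reservoir} = S(t_{peak}),\qquad
  \text{conduit} = S(t_{peak}) - S(t_{cc}),\qquad
  \text{contractile} = S(t_{cc}),$$

so reservoir $=$ conduit $+$ contractile **exactly**, for the global curve
and each regional curve alike (regional metrics reuse the global
boundaries). Peak SRs are the maximum SR on the reservoir window and the
signed minima on the conduit and contractile windows; conduit and
contractile SRs are stored negative, with magnitude formatting left to the
reporting layer. Six scopes times six parameters yield the 36-feature
vector used by the cohort statistics.

Volumetrics follow the standard CT conventions: LA EDV is the frame-1
(minimum) volume and LA ESV the maximum, LAEF $= 100\,(ESV - EDV)/ESV$; the
LV reverses the convention. Body surface area uses the Mosteller formula
$\sqrt{h\,[\mathrm{cm}]\cdot w\,[\mathrm{kg}]/3600}$ — the choice of BSA
formula is not dictated by the measurement itself, so it is documented here
and swappable.

## The synthetic 4D cohort

No patient data ship with the package, so validation rests on a generator
whose ground truth is known in closed form.

**Anatomy.** A superellipsoid-deformed icosphere (default mean radius 25
mm, mild axis anisotropy, shaping exponent 2.5) stands in for the LA body;
its end-diastolic volume lands in the tens of mL. Five contiguous surface
patches in a fixed spherical chart stand in for the walls; a full atlas
parameterization is deliberately out of scope, since only the
regional-analysis *structure* matters for testing.

**Motion.** The prescribed global transient rises from 0 to the reservoir
amplitude $A$ at $t_{peak}$ (default 0.4), falls by $(1 - c)A$ to the
boundary $t_{cc}$ (default 0.7) where $c$ is the contractile fraction,
holds a diastasis plateau to $t_{act}$ (default 0.85), and returns to 0 at
cycle end. Segments are smoothstep polynomials: the `"cubic"` mode is
$C^1$ with an exact plateau onset (an easy, well-defined target for the
detector), and the `"smooth"` mode uses quintic segments that are $C^2$
everywhere, so the slope eases gradually into the plateau and genuinely
stresses the level-off rule. Both modes pass exactly through the prescribed
knot values, so recovery errors are attributable to sampling and detection,
never to the generator. Vertices move radially with scale
$\sqrt{1 + m_v\,S(t)/100}$; with all regional modifiers $m_v = 1$ this
makes every element's area strain equal the transient *identically* (the
uniform-scaling law $\varepsilon = (s^2 - 1)\cdot 100$), which is the
package's machine-precision oracle. Regional modifiers scale amplitudes per
wall; they are averaged onto vertices so the surface stays continuous
across patch boundaries, which pulls regional means slightly toward 1 at
the boundaries — tests account for that. Tracking jitter is emulated by
isotropic Gaussian vertex noise applied after motion.

**Frames.** 10-frame (10% R-R) and 20-frame (5%) sequences sample the same
continuous transient, which is what makes the 10- vs 20-frame comparison
well-posed: `frame_count_comparison()` re-analyses a 20-frame sequence
using every other frame and reports per-parameter absolute differences. On
the default smooth-mode cohort the mean absolute phasic-strain difference
sits near 0.25%, comfortably below the 1.2% reproducibility bound reported
for this class of measurement; SR differences are larger, as expected from
halving the sampling rate of a derivative.

**Cohort.** `generate_cohort()` samples per-subject reservoir and
contractile strain targets from group means (defaults: an event group of 18
at contractile 9.3% vs an event-free group of 51 at 15.9%, reservoir
shifted −4%, matching the registry-scale contrasts the statistics are meant
to detect), timing jitter (SD 0.02 on $t_{peak}$, $t_{cc}$), a ±6%
anatomical scale SD, and clinical covariates (age 61 ± 12, 39% female,
comorbidity prevalences at registry-like rates) from which CHA2DS2-VASc is
scored. When the detector flags a sampled subject's curve (e.g. a very
small contractile fraction leaves no detectable level-off), the known
boundary stands in through the manual-correction hook, exactly as a human
reviewer would; the event is recorded per subject in `phase_corrected`.
These defaults are the study conditions for every seeded validation in the
package and are not tuned per test.

**What the generator does not emulate.** Real atria are not star-shaped
superellipsoids; real motion includes translation, torsion and
through-plane components beyond radial scaling; CT intensities carry
contrast gradients, streak artefacts and wall signal rather than a binary
blood pool; and real phase timing varies with heart rate. Passing tests
therefore demonstrate the *correctness of the measurement chain* under
known deformations, not clinical accuracy on patient scans.

## Baseline tracking

The image path voxelizes each mesh frame onto a common grid (z-column
parity rasterization, blood pool bright), optionally blurs and noises it,
and estimates motion with a deliberately plain deformable registration: a
multi-resolution cubic B-spline free-form deformation (default control
spacing 12 mm, two image levels) maximizing global normalized
cross-correlation with a bending-energy penalty ($\lambda = 10^{-4}$),
optimized by L-BFGS-B with an analytic gradient. Global rather than
locally-windowed correlation is sufficient here because the synthetic
volumes contain a single tissue class; the analytic gradient keeps the
solver deterministic and fast at desk scale. Consecutive frames are
registered pairwise and the end-diastolic mesh is transported through the
composed fields, bounding per-pair motion as temporal trackers do; a
ground-truth tracker that replays the generator's analytic motion isolates
downstream stages from registration error. The tracker is an interface —
externally tracked mesh sequences enter through `read_mesh_sequence()` and
bypass it entirely.

Accuracy under the validation conditions (40³-voxel volumes at 2–2.5 mm,
smoothing SD 1 voxel): self-registration is an identity fixed point
(max displacement < 0.1 voxel), 3 mm translations are recovered to
~0.15 mm, a 10% dilation's propagated mesh volume lands within 1%, and
end-to-end phasic strains from tracked images stay within 15% relative of
the prescribed values — an order of magnitude looser than the mesh path,
which is near-exact by construction.

## Statistical battery

The cohort statistics deliberately mirror a clinical analysis plan:
two-sided *pooled-variance* Student's t-tests (Welch behind a flag;
`t_test_summary()` applies the identical formula to published
mean/SD/count triples so printed tables can be re-tested), χ² or Fisher's
exact test with the expected-count<5 auto rule, two-way mixed ANOVA
(between = group, within = region) with Greenhouse–Geisser correction
reported alongside uncorrected p-values, rank-based ROC with the
orientation chosen so AUC ≥ 0.5 (direction recorded; reduced strain
typically predicts events), stratified subject-level percentile bootstrap
CIs (default 2000 replicates, seeded), Youden-point operating
characteristics, DeLong's test for paired AUCs, and k-means phenotype
clustering on the z-scored 36-feature matrix with silhouette-selected k,
a sole-member-cluster outlier rule (remove, re-standardize, repeat,
logged) and a PCA projection for display. Initialization uses 10 seeded
random restarts rather than a k-means++ scheme; with the restart count
this is equally stable and fully reproducible under the seed. **No
multiple-testing correction is applied anywhere** — each test is reported
at α = 0.05, matching the analysis plan this battery reproduces; treat
marginal p-values accordingly.

## Numerical choices and degenerate inputs

* Monotone-cubic interpolation is used for all curve evaluation; it cannot
  invent oscillations between frames, at the cost of a small (≲0.01%)
  overshoot near sampled peaks.
* $t_{cc}$ ties break earliest; the level-off search runs on a 2001-point
  grid of the interpolant.
* Degenerate statistical inputs fail loudly: zero pooled variance with
  unequal means, empty contingency margins, single-subject groups,
  single-class outcomes, all-constant feature matrices.
* The voxelizer offsets ray columns by an irrational sub-voxel shift so
  rays never graze vertices or edges of generic meshes; odd crossing
  counts (grazing hits) skip the column rather than mis-fill it.
* Registration reports — not silently accepts — failure to improve on the
  identity, and refuses vertices outside the deformation domain.

## Problem sizes

Validation runs use icosphere subdivision 2 (320 faces) for cohort-scale
work and subdivision 3 (1280 faces) for geometry-sensitive checks; cohorts
of 4–40 subjects for pipeline tests, 500 for the law-of-large-numbers
check; 1000 replicates for the mixed-ANOVA type-I simulation; 200–2000
bootstrap replicates for ROC CIs; and single-subject image tracking at
2 mm voxels. These sizes were chosen so the whole validation suite runs on
a laptop-class single core in a few minutes while keeping Monte-Carlo
error well inside the asserted tolerances.

## Known limitations

* Area strain on a coarse mesh under-resolves sharp regional gradients;
  regional means at patch boundaries blend neighbouring amplitudes.
* The level-off rule depends on α when the plateau is short or the
  contractile phase merges into the conduit; such curves are flagged for
  review rather than guessed.
* The baseline tracker is a reference implementation: adequate for
  synthetic single-class volumes, not tuned for clinical CT (no local
  windowing, no mask, no temporal regularization).
* Peak SR magnitudes are sampling-rate dependent by construction; compare
  SRs only at matched frame counts.
* The statistics assume two groups and complete feature rows (listwise
  exclusion elsewhere, logged); the clustering assumes features are
  meaningfully comparable after z-scoring.
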