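# lastrain

Phasic left atrial (LA) strain analysis from 4D (3D + time) retrospective
ECG-gated cardiac CT, for imaging researchers studying atrial mechanics in
atrial fibrillation.

Gated CT reconstructs the full 3D endocardial surface at 10 or 20 phases of
the R-R interval. `lastrain` turns a deforming surface-mesh sequence into
per-subject phasic mechanics: for every triangular surface element it
computes the **area strain**

ε_e(t) = 100 · (A_e(t) − A_e(0)) / A_e(0)  [%]

relative to the end-diastolic anatomy (positive = expansion), averages
elements into one global and five regional wall curves (septal, lateral,
posterior, anterior, inferior), automatically splits the cycle into the
**reservoir** (filling), **conduit** (passive emptying) and **contractile**
(atrial kick) phases from the global curve, and extracts phasic strains and
peak strain rates — 3 phases × {strain, SR} × {global + 5 regions} = 36
parameters per subject — plus CT volumetrics (EDV/ESV, LAEF, LVEF,
BSA-indexed volumes). By construction, reservoir = conduit + contractile
strain exactly, for every scope.

Around that core the package provides:

* a **synthetic 4D cohort generator** (LA-like superellipsoid anatomies with
  prescribed, closed-form phasic motion, regional amplitude modifiers,
  noise, voxelized CT-like frames, and two-group cohorts with configurable
  effects) so every stage is testable without patient data;
* a **baseline 3D feature tracker** (multi-resolution cubic B-spline
  free-form deformation, normalized cross-correlation, bending-energy
  penalty, deterministic L-BFGS-B) with a pluggable interface for external
  trackers;
* the **cohort statistics** of a clinical analysis plan: pooled Student's
  t-tests (including from published summary statistics), χ²/Fisher, mixed
  ANOVA with Greenhouse–Geisser correction, ROC with stratified bootstrap
  CIs and DeLong comparisons, CHA2DS2-VASc scoring, and k-means phenotype
  clustering with silhouette-selected k;
* mesh (OFF/PLY + JSON sidecar) and NIfTI volume I/O, and a reproducible
  `run_pipeline()` orchestrator with a manifest (also scriptable via
  `inst/cli/lastrain.R`).

## Worked example

Generate one synthetic subject at 20 frames and analyse it:

```r
library(lastrain)

p   <- motion_params(reservoir_amplitude = 25, contractile_fraction = 0.55,
                     n_frames = 20, transient_mode = "smooth")
seq <- generate_mesh_sequence(p)          # 20 meshes, 5% R-R increments
ana <- analyze_sequence(seq)

ana$phases
#> phase_boundaries: t_ed = 0, t_peak = 0.401, t_cc = 0.650 [automatic, automatic]

ana$metrics[ana$metrics$scope == "global", ]
#>    scope reservoir_strain conduit_strain contractile_strain reservoir_sr conduit_sr contractile_sr
#>   global               25           10.9               14.1          112      -65.3           -160
```

The detector found peak reservoir strain at t = 0.40 of the R-R interval
and the conduit–contractile level-off one frame before the prescribed 0.70
(the C² transient eases gradually into its plateau). The prescribed
reservoir strain (25%) is recovered exactly; emptying splits into a passive
conduit share (10.9%) and an active contractile share (14.1%) that sum to
the reservoir strain. Strain rates are in % per normalized R-R time, with
conduit/contractile peaks stored negative (emptying).

Published group summaries can be re-tested directly — e.g. contractile
strain 9.3 ± 6.0% (n = 18) vs 15.9 ± 9.1% (n = 51):

```r
t_test_summary(9.3, 6.0, 18, 15.9, 9.1, 51)
#>   mean_a mean_b statistic df p_value                      method
#> 1    9.3   15.9     -2.86 67 0.00567 Student t (pooled, summary)
```

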