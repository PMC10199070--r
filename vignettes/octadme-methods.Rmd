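---
title: "Methods: OCTA morphometrics and DME treatment-response modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OCTA morphometrics and DME treatment-response modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the measurement
chain, the statistical model, the synthetic world the tests run in, the
numerical choices, and what a green test does and does not establish. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

# The measurement chain

An en-face OCTA angiogram enters as a raster of vessel probabilities in
[0, 1] (the package deliberately consumes segmentation output; vessel
segmentation itself is out of scope) together with the eye's biometry.
`measure_eye()` applies, in order:

1. **Quality gate** — the recorded signal strength must be *strictly above*
   50 (configurable). "Above" is read literally: a value of exactly 50
   fails, and an absent value fails. Failing eyes are excluded with a
   logged reason, never dropped silently.
2. **Frame averaging** — pixel-wise mean of the co-registered repeats;
   residual noise shrinks like $\sigma/\sqrt{n}$. Frames are assumed
   registered upstream; an optional integer-shift alignment (exhaustive
   cross-correlation within ±5 px) is provided but off by default, because
   the upstream averaging protocol we mirror registers frames before
   export.
3. **Binarization** at threshold 0.5 with the `>=` convention. The
   boundary convention is arbitrary; it is pinned, documented, and tested
   so that results are reproducible to the pixel.
4. **Magnification correction** — the lateral scale (µm/px) is
   `nominal_scan_width / width_px` times
   $(AL_{subj} - 1.82)/(AL_{assumed} - 1.82)$, the modified Bennett
   relation $q = 0.01306\,(AL - 1.82)$ reduced to a ratio. The constant
   1.82 mm (distance from corneal vertex to the eye's second principal
   plane) comes from the Littman/Bennett literature. The device's assumed
   axial length defaults to 23.95 mm and must be overridden per device;
   refraction and keratometry are carried in metadata and a
   `custom_q(AL, refraction, keratometry)` hook accepts a three-parameter
   variant, but the default uses axial length only. Note VD and PD are
   pixel *ratios* and therefore magnification-invariant; FAZ metrics are
   not, which the tests verify explicitly.
5. **Densities** — perfusion density (PD) is the foreground fraction;
   vessel density (VD) is the foreground fraction of the skeleton.
6. **FAZ extraction and morphometrics** (below).

## Skeletonization

VD requires a 1-px, topology-preserving skeleton. The pinned algorithm is
classic two-subiteration Zhang–Suen thinning with two amendments, both
forced by contract:

* **Survivor protection.** Classic Zhang–Suen deletes simultaneously
  within a subiteration and can erase an isolated 2×2 square entirely,
  changing the component count. A pixel is therefore only deleted if at
  least one of its 8-neighbors survives the same subpass.
* **Residual 2×2 pruning.** The classic scheme can leave 2×2 staircase
  blocks. A sequential pass removes a pixel of each remaining block when
  its foreground neighbors stay 8-connected within the 3×3 neighborhood
  after deletion (a local simple-point test).

The vectorized implementation is tested for exact equality against an
independent per-pixel scalar implementation of the same pinned algorithm,
and property tests assert: skeleton ⊆ mask, no 2×2 block, and component
count preserved, on batches of random masks.

## FAZ extraction and shape metrics

The paper-level description reports FAZ metrics but no extraction
algorithm, so extraction is package-defined: close the vessel mask with a
disc of radius `max_bridge_px` (default 2 px at a 3-mm scan — large enough
to seal capillary gaps of a few pixels, small enough not to hallucinate
vessels across the FAZ), then take the 4-connected background component
containing the raster center. A fully vascular center is a hard "no FAZ
found" error; a region touching the raster border is flagged unreliable.

Shape metrics, computed after hole-filling:

* **area** = pixel count × scale²;
* **perimeter** = marching-squares contour length (`contourLines` at level
  0.5) on a 3×3 box-blurred copy of the mask. Marching squares on the raw
  binary mask overestimates a disc's perimeter by ~5.5% (staircase
  effect); the light blur reduces the error below ~1% on discs, ellipses
  and rotated squares. Boundary-pixel counting was rejected because its
  upward bias would propagate directly into acircularity;
* **max/min Feret diameters** — rotating calipers over the convex hull of
  the contour;
* **axis ratio / eccentricity** — from the eigenvalues of the
  second-central-moment matrix of the pixel set (with the 1/12
  pixel-square correction), i.e. the equivalent ellipse:
  $e=\sqrt{1-\lambda_2/\lambda_1}$;
* **acircularity** $= P / (2\sqrt{\pi A})$, perimeter relative to the
  equal-area circle, 1 for a disc.

Tests pin these against closed forms (disc, 2:1 ellipse where
$e=\sqrt{3}/2$) and against a vertex-space polygon oracle on rasterized
random convex polygons, at ~2–3% discretization tolerance for radii ≥ 30 px.

# The synthetic angiogram world

`simulate_angiogram()` must deliver *exact* ground truth: the skeleton
density is defined as (rasterized centerline pixels) / (total pixels), and
the pipeline is tested to recover it.

Centerlines are placed as **evenly spaced streamlines** of a smooth random
direction field (quasi-radial toward the fovea plus low-frequency
sinusoidal perturbation), in the manner of Jobard–Lefér placement:
lines are seeded at separation `dsep ≈ 0.85/density`, traced until they
come within `dtest ≈ dsep/2` (floored at width + 1.2 px) of any other
line, the image border, or the FAZ; a relaxed in-fill stage and a final
deterministic grid scan top the count up to the target, stopping exactly
at the requested pixel count. A biased branching random walk was tried
first and rejected: at realistic density it produced ~300 short
anastomosing segments per image whose junction and end-cap erosion under
thinning biased measured VD by −0.016, against a contract of |bias| <
0.005. Streamlines are long and never merge, so thinning the dilated mask
nearly reproduces the centerline: measured bias at the cohort operating
point (density 0.098, width 3 px) is ≈ +0.003. The residual positive bias
is an end-cap effect (~1 extra thinned pixel per streamline end), so it
grows as segments shorten near the packing limit: at density 0.14 it
reaches ~+0.01, which is why the span test (0.05 vs 0.14) carries a
±0.015 tolerance while the operating-point contract stays at ±0.005.
Near that packing limit the generator may also stop up to 0.005 short of
the requested density (recorded exactly in the truth); a target beyond
reach is an explicit error, never a silent clip.

The FAZ is an ellipse (default semi-axes 28×22 px at 256 px / 3 mm ≈ a
0.28 mm² zone, typical of DME eyes). No centerline pixel may fall strictly
inside it (enforced and tested). The optional intact terminal capillary
ring is traced at semi-axes + (width−1)/2 + 0.5 so that the *dilated*
ring's inner edge coincides with the truth ellipse — this is what makes
the extraction-overlap test (Jaccard ≥ 0.95 against the truth ellipse)
meaningful rather than vacuously offset. Bounded Gaussian noise
(default sd 0.05, clamped to [0, 1]) is added last; at the 0.5 threshold
this never flips background (0) or vessel (1) pixels, so binarization of a
noise-free image equals the dilated centerline exactly — tested.

What the generator does *not* emulate: projection artifacts, motion
stripes, vessel-caliber heterogeneity, capillary dropout texture, device
noise physics. A green imaging test therefore establishes correctness of
the *measurement arithmetic*, not robustness to real-device artifacts.

# The synthetic cohort world

`simulate_cohort()` draws 48 patients, each contributing a second study
eye with probability 28/48 (≈ 76 eyes in expectation). Covariates use the
published marginal frequencies (e.g. 60.4% male, 16.7% type 1 diabetes,
46.5% peripheral non-perfusion, LDL ~ N(2.5, 1.0) mmol/L) and are drawn
independently — the source reports no correlation structure. VD is
truncated-normal 0.098 ± 0.018 on [0.05, 0.14], matching the published
mean, SD and range; the ≥ 0.1 flag then splits eyes ≈ 43/32, matching the
published split.

The outcome model is additive, exactly as specified:

$$y_{ijt} = \mu_{g(i)} + b_j + \Delta_{g(i)}(t) + \varepsilon_{ijt}$$

with patient intercept $b_j$ shared by both eyes, subgroup baseline mean
$\mu$ and mean-change trajectory $\Delta(t)$ keyed by **one grouping
variable per outcome**: BCVA by the VD ≥ 0.1 group (final-visit gains
6.7 vs 1.0 letters, earlier months interpolated monotonically with the
described early-gain/plateau shape), CRT by peripheral non-perfusion
(printed month-1/3/4/6 anchors 102.6/115.1/129.7/117.3 µm present vs
44.7/63.4/61.7/80.0 µm absent; months 2 and 5 interpolated). A preset
(`ldl_bcva_trajectory()`) re-keys BCVA by the LDL group (4.0 vs 1.8
letters at month 6). One grouping per outcome is deliberate: the published
subgroup trajectories of *different* groupings are marginals of correlated
real data and are mutually inconsistent as additive components; stacking
them would bias every subgroup recovery. Linear covariate effects (e.g.
120 letters per unit VD, constant over post-baseline months and centered
at the realized covariate mean) can be injected via `extra_effects` for
model-recovery simulations.

Dispersion defaults: the additive model cannot reproduce the published
baseline SDs (~110–140 µm CRT) and final-visit SDs (~56–60 µm)
simultaneously, because baseline and final visits enter symmetrically. The
defaults match the final-visit dispersion — patient intercept 45 µm +
residual 37 µm for CRT, 9 + 4 letters for BCVA — for two reasons: the
response trajectory is the quantity under study, and large dispersions
push simulated month-6 CRT into the 150 µm physiological floor (at the
originally considered 80 + 86 µm, ~11% of values would clamp, biasing
subgroup recovery by ~6 µm; at the defaults the clamp is essentially
inactive, bias ~0.15 µm). The 4-letter BCVA residual sits inside the
published ETDRS test-retest range and keeps the simulated world in the
power regime the recovery simulations assert (a c ≈ 120 letters-per-unit-VD
effect retained by backward elimination in well over 90% of replicates);
5 letters had been considered first and puts that retention rate on the
90% boundary. BCVA is clamped to [0, 100] letters and CRT floored at
150 µm after noise. Letters are kept continuous (clamping aside): rounding
to chart precision would break the exact noise-free-limit contract and
adds nothing to the statistics. A drop-out probability and a
VD-missingness probability are exposed, both 0 by default (no attrition
mechanism is published; the 76th eye whose VD was evidently ungradable has
no stated mechanism either, so analyses exclude-and-count VD-missing eyes
rather than assume one).

Seeding: one global integer seed; every generator derives a named
substream via a 31-bit string hash (`seed_substream`), so adding a
generator never perturbs existing draws, and all acceptance quantities are
reproducible from `--seed` alone.

# The statistical pipeline

* **Adjudication** — two masked graders, agreement stands, disagreement
  resolved by the third grader; `disagreement_rate()` reports the fraction
  needing reconciliation.
* **Deltas** — BCVA change is visit − baseline; CRT change is baseline −
  visit so that positive means *reduction*. Month-0 deltas are identically
  zero; missing months stay missing (no imputation); duplicate (eye,
  month) rows are an error.
* **Dichotomization** — flag = value ≥ threshold. Defaults: VD 0.1 (the
  published median 0.097 falls in the low group, which the boundary test
  pins), LDL 2.6 mmol/L, excellent BCVA 70 letters. Missing values are
  excluded and counted.
* **Univariate tests** — Welch's t (identical constant groups return
  statistic 0, p = 1 by convention) and Wilcoxon rank-sum. The named
  "signed-rank" test is a paired test; it is exposed for within-eye month
  contrasts, while unpaired group contrasts use the rank-sum, matching
  each test to its sampling design. The rank-sum uses exact enumeration
  for untied groups up to n = 20 and otherwise a normal approximation with
  continuity and tie corrections *plus an Edgeworth kurtosis term*
  ($\kappa_4 = -mn(N{+}1)(m^2{+}n^2{+}mn{+}N)/120$, exact for untied
  data): the plain corrected normal approximation misses exact enumeration
  by up to ~0.015 at group sizes 6–10, the Edgeworth-corrected version by
  < 0.002, which is what the ≤ 0.01 agreement contract requires.
  `welch_from_summary()` reconstructs Welch tests from printed mean/SD/n.
* **Mixed models** — longitudinal responses (monthly deltas) get fixed
  month effects (categorical by default; continuous available) plus random
  intercepts for patient and eye; the final-visit excellent-BCVA indicator
  is fitted on the linear-probability scale by default (keeping
  coefficients in letter-equivalent units, which is evidently how the
  published letter-scale coefficients for a binary outcome arise) with a
  logistic option. Fits use `lme4` with `bobyqa` and no derivative check:
  delta responses cancel the patient intercept exactly, so its variance
  sits on the boundary and the default Hessian check raises spurious
  non-convergence warnings. p-values are Wald normal-approximation tests
  (single Wald z per column; joint Wald χ² for multi-level factors);
  with ~450 longitudinal rows the z-vs-t difference is negligible, and a
  Satterthwaite package is deliberately not a dependency. Rank-deficient
  designs error with the offending columns named; cohorts without at least
  two two-eye patients degrade to fixed-effects least squares with a
  warning.
* **Backward elimination** — refit, remove the predictor with the largest
  p ≥ 0.05 (ties broken toward the alphabetically last name, making the
  procedure deterministic and input-order invariant), repeat until all
  remaining p < 0.05. A refit failure keeps the candidate, flags it, and
  continues. VD and the FAZ metrics enter the same initial set so FAZ is
  assessed net of VD. The full trace is kept. No multiplicity adjustment
  by default (mirroring raw-p reporting); a Benjamini–Hochberg switch
  exists.
* **Reporting** — `build_table3()` assembles one row per baseline variable
  × three response families, flags p < 0.05, and attaches coefficients for
  significant entries. Trajectory summaries use mean ± t(0.975, n−1)·SE
  per month per group.

# Interfaces and formats

Cohorts travel as `eyes.csv` (one row per eye) and `visits.csv` (one row
per eye-month); metrics as one CSV row per eye with stable column names.
Images are plain-text PGM (P2, 16-bit) with a JSON metadata sidecar — PGM
rather than PNG/TIFF because the deployment environment guarantees no
image codec package, and a 20-line text codec removes the dependency; PNG
is supported opportunistically via the suggested `png` package. Config is
strict-keyed JSON (same reasoning versus YAML). Every pipeline stage
writes a JSON manifest with the config snapshot, file hashes, and a QC
ledger satisfying rows_in = rows_out + rows_excluded.

# Known limitations

* The angiogram generator's network is geometrically plausible but
  statistically idealized (no artifacts, no caliber variation); its bias
  contract holds at width 3 px and densities ≤ ~0.13.
* The cohort generator is additive with independent covariates; it cannot
  and does not claim to reproduce the joint distribution of the real
  cohort, only the marginals and the keyed subgroup trajectories.
* Wald p-values are asymptotic; at 75 eyes they are adequate for
  screening, not for confirmatory inference.
* The frame-alignment option is integer-shift only; the upstream protocol
  this mirrors uses a registration method not reproduced here.
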