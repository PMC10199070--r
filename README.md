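# octadme

Quantitative OCTA biomarkers of the macula and treatment-response modelling
for diabetic macular edema (DME).

## The problem

Up to 40% of eyes with DME respond poorly to intravitreal anti-VEGF therapy,
and poor responders can currently only be identified after months of
injections. Baseline retinal angiographic biomarkers — macular capillary
density measured on OCT angiography (OCTA) and peripheral non-perfusion on
ultrawide-field angiography — are candidate predictors of who will gain
vision and whose edema will resolve. `octadme` implements the two halves of
that analysis as a reusable, fully tested pipeline:

1. **OCTA morphometrics.** From an en-face vessel-probability map
   (pixel values in [0, 1], e.g. the output of an upstream segmentation
   network) plus the eye's biometry:
   - binarize at threshold 0.5 (`p >= 0.5` is vessel);
   - *perfusion density* `PD = (vessel pixels) / (all pixels)`;
   - *vessel density* `VD = (skeleton pixels) / (all pixels)`, where the
     skeleton is a topology-preserving Zhang–Suen thinning of the mask —
     VD is insensitive to vessel width, PD is not;
   - foveal avascular zone (FAZ) extraction (central background component
     after morphological closing) and shape metrics: area, perimeter,
     max/min Feret diameters, axis ratio, eccentricity, and acircularity
     `AI = P / (2·sqrt(pi·A))` (1 for a circle);
   - ocular magnification correction by the Littman / modified Bennett
     relation `q = 0.01306·(AL − 1.82)`, i.e. lateral scale factor
     `(AL_subject − 1.82) / (AL_assumed − 1.82)`.
2. **Response analysis.** For a 6-month monthly-injection cohort with one
   or two study eyes per patient: delta-from-baseline outcomes
   (BCVA letters gained; CRT reduction in µm), threshold dichotomization
   (VD ≥ 0.1, LDL ≥ 2.6 mmol/L, excellent BCVA ≥ 70 letters), masked-grader
   adjudication, Welch/Wilcoxon univariate comparisons, and linear
   mixed-effects models with a random intercept per patient (two eyes share
   it) and per eye (months within an eye share it), screened by backward
   elimination at `alpha_stay = 0.05`.

Because the underlying clinical data are not public, the package ships a
**synthetic-data module**: capillary-network angiograms with exact
skeleton-density ground truth and a controllable FAZ ellipse, and
longitudinal cohorts whose subgroup trajectories are parameterized to the
published summaries — so every stage runs, and is tested, without any
download.

## Worked example

```r
library(octadme)

# --- one synthetic eye, measured end to end -------------------------------
sim <- simulate_angiogram(seed = 11)          # 256 px, 3 mm scan
m   <- measure_eye(list(sim$angiogram))
sim$truth$true_skeleton_density               # 0.098
m$density$vessel_density                      # 0.1024
m$density$perfusion_density                   # 0.3641
m$faz
#> <faz_metrics> area 0.2582 mm2, perim 1.831 mm, Dmax 0.657 / Dmin 0.516 mm,
#>   axis ratio 1.266, eccentricity 0.613, acircularity 1.016
```

Measured VD tracks the generator's ground truth (0.102 vs 0.098); PD is
about `vessel width × VD`; the FAZ metrics are in physical units after
magnification correction.

```r
# --- a 48-patient cohort, analyzed ----------------------------------------
ch <- simulate_cohort(seed = 11)              # ~76 eyes, months 0..6
d  <- compute_deltas(ch$visits)
group_trajectory_summary(d, ch$eyes, "vd_hi", "d_bcva_letters") |>
  subset(month == 6)
#>  group month  n mean    lo   hi
#>  FALSE     6 43 1.94 -0.02 3.91
#>   TRUE     6 32 6.87  4.36 9.39

backward_eliminate(d, ch$eyes, "bcva_improvement",
                   predictors = c("vd", "age", "male", "hba1c", "ldl_hi"))
#> <screening_report> bcva_improvement (alpha_stay = 0.05)
#>  predictor retained coefficient p_value step_removed
#>         vd     TRUE      76.756  0.0196           NA
#>       male    FALSE       1.671  0.1540            4
#>      hba1c    FALSE       0.368  0.1890            3
#>        age    FALSE      -0.038  0.3040            2
#>     ldl_hi    FALSE      -0.965  0.4120            1
```

Eyes with preserved capillary density (VD ≥ 0.1) gain ~6.9 letters by month
6 in this draw while low-VD eyes do not improve significantly, and backward
elimination retains VD (a letters-per-unit-VD coefficient; 1 unit of VD is
far larger than the observed 0.05–0.14 range, hence the large magnitude)
while discarding the null covariates.

## Command line

```sh
Rscript -e 'octadme::octadme_cli()' simulate --seed 3 --out fixtures
Rscript -e 'octadme::octadme_cli()' metrics  --out fixtures
Rscript -e 'octadme::octadme_cli()' analyze  --out fixtures
```

`simulate` writes PGM angiograms + JSON sidecars, `eyes.csv`, `visits.csv`
and `truth.json`; `metrics` writes one row of VD/PD/FAZ metrics per eye;
`analyze` writes `table3.csv` (the three-family screening table),
`group_comparisons.csv`, trajectory figures with 95% CIs, and a JSON run
manifest with config, file hashes, and a per-eye QC ledger. Exit codes:
0 ok, 1 usage, 2 data error.

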