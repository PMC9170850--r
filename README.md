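# amapet

Quantification of sodium [18F]fluoride PET uptake in the abdominal aorta.

Sodium fluoride PET highlights developing microcalcification in the
aortic wall, a marker of disease activity in abdominal aortic aneurysms.
Quantifying it reproducibly is awkward: the standard slice-wise
tissue-to-background ratio (TBR) requires contouring the aorta on every
trans-axial plane, intense physiological tracer uptake in the adjacent
vertebrae spills into the aneurysm through the scanner's point-spread
function, and the aneurysmal aorta changes diameter continuously along its
length, so no single-radius volume of interest fits it.

`amapet` implements, for image analysts and cardiovascular imaging
researchers, the two measurement approaches used for this problem and the
statistics to compare them:

- **TBR** — circular regions of interest of 3&nbsp;mm thickness drawn around
  the aorta on consecutive trans-axial planes. For a region,
  `TBR_mean = mean(per-slab SUV_mean) / SUV_blood` and
  `TBR_max = max(per-slab SUV_max) / SUV_blood`.
- **AMA** (aortic microcalcification activity) — a tubular volume of
  interest swept along the vessel centerline covering lumen, thrombus and
  wall. `AMA_mean = (cumulative SUV / VOI volume) / SUV_blood` and
  `AMA_max = SUV_max / SUV_blood`, with two enhancements:
  an **upper-intensity threshold** (the SUV_max of a reference sphere
  placed over the hottest aortic uptake clearly distinct from the
  vertebra; voxels above it are excluded from the cumulative SUV and
  volume) to suppress vertebral spill-over, and a **variable-radius**
  centerline whose per-point radius follows the local aortic diameter.

The blood-pool denominator `SUV_blood` is the volume-weighted mean SUV in
two 8-mm-radius spheres placed in the cardiac blood pool.

Method agreement and observer repeatability are assessed with Pearson
correlation, the two-way consistency intraclass correlation ICC(C,1) with
its F-based 95% CI and the poor/moderate/good/excellent reliability bands,
Bland–Altman bias with 95% limits of agreement (absolute and percentage),
and the coefficient of repeatability `1.96 * sd(differences)`.

Because no patient data ship with the package, a digital phantom module
generates co-registered PET/CT volumes of an aneurysmal aorta (Gaussian
bulge, radius 10&nbsp;mm neck to 20&nbsp;mm peak by default) beside a hot
vertebral column and a separate blood-pool cylinder, blurred by an
isotropic Gaussian point-spread function with additive noise — with full
ground truth, so every operation is testable end to end.

## Worked example

```r
library(amapet)

ph <- make_phantom(phantom_spec(seed = 7))          # PET + CT + centerline + truth
spheres <- phantom_study_spheres(ph)                # blood-pool + threshold spheres

bg <- background_activity(ph$pet, spheres$blood[[1]], spheres$blood[[2]])
bg
#> <background_activity> mean blood-pool SUV 0.9753 (total volume 4.19 cm^3)

res <- analyze_study(ph$pet, ph$centerline, spheres,
                     method = c("tbr", "ama"), threshold = TRUE)
res[, c("label", "method", "volume_cm3", "suv_mean", "tbr_mean", "ama_mean")]
#>        label method volume_cm3 suv_mean tbr_mean ama_mean
#> 1   aneurysm    ama      70.74    0.994       NA    1.019
#> 2   aneurysm    tbr      71.97    0.985    1.009       NA
#> 3       neck    ama      10.14    0.958       NA    0.983
#> 4       neck    tbr      10.62    0.968    0.993       NA
#> 5 suprarenal    ama       8.82    1.017       NA    1.043
#> 6 suprarenal    tbr       9.60    1.037    1.063       NA
#> 7   thoracic    ama       8.77    0.956       NA    0.980
#> 8   thoracic    tbr       9.60    0.981    1.006       NA

tbr <- res[res$method == "tbr", ]; ama <- res[res$method == "ama", ]
compare_methods(tbr$tbr_mean, ama$ama_mean[match(tbr$label, ama$label)])
#> <agreement_report> n = 4
#>   A: 1.018 +/- 0.03083   B: 1.006 +/- 0.03028
#>   Pearson r = 0.870 (p = 0.13)
#>   ICC(C,1) = 0.870 (95% CI -0.037-0.991), good
#>   bias = -0.01186 (LoA -0.04243 to 0.01871)
#>   CR = 0.03057 (3.0% of mean), paired t p = 0.226
```

The per-region `ama_mean` and `tbr_mean` are dimensionless uptake ratios
(tissue relative to blood, near 1 for this mildly active phantom); the
threshold column of the full result records the per-region upper SUV limit
and how many spill-over voxels it excluded. On a 25-phantom cohort the two
methods agree closely once thresholding and the variable radius are
applied (see below).

A command-line pipeline wraps the same functions
(`inst/cli/amapet.R phantom|quantify|compare`); each subcommand is
deterministic given its YAML configuration and seed.

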