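# helixdti

Transmural helix- and sheet-angle analysis for ex vivo cardiac diffusion
tensor imaging (DTI), aimed at quantifying myocardial microstructure in
congenital heart disease specimens — and at anyone who needs a fully
testable cardiac-DTI analysis chain driven by synthetic phantoms.

## What it computes

Myocytes wind helically around the ventricle: right-handed near the
endocardium (positive helix angle, HA), circumferential at mid-wall,
left-handed at the epicardium. From a diffusion tensor field `D` with
eigensystem `λ₁ ≥ λ₂ ≥ λ₃`, eigenvectors `ê₁, ê₂, ê₃`, and a local wall
frame (radial `r̂`, circumferential `ĉ`, longitudinal `l̂`):

- **HA** = angle of `ê₁`'s projection in the `ĉ`–`l̂` plane from `ĉ`;
- **E2A** (sheet angle) = angle of `ê₂`'s projection in the `r̂`–`l̂` plane
  from `r̂`;
- **HA gradient** = OLS slope of mean HA versus transmural depth
  (°/% depth), fitted over 20–80 % depth (20–70 % for walls with a
  transition zone), normally ≈ −1.2 °/%;
- **HA asymmetry (HA₀)** = depth at which the fitted line crosses HA = 0,
  with a confidence interval from the intersections of the fit's 95 %
  confidence band with zero; HA₀ < 50 % flags left-handed dominance,
  > 50 % right-handed;
- **group comparisons**: two-slope Welch t-test
  `t = (β₁−β₂)/√(SE₁²+SE₂²)` with Satterthwaite degrees of freedom, and
  Welch t-tests on segment E2A values;
- **MD / FA** maps, and the b-value planning rule `b = 1.11/ADC`
  (853 s/mm² at ADC = 1.30×10⁻³ mm²/s).

Because the historical specimen scans are not distributable, the package
includes a first-class synthetic module: a voxelized myocardial annulus (or
biventricular) phantom with prescribed HA/E2A laws and a DWI simulator
(32-direction half-shell scheme with interleaved b0 volumes, Rician noise,
magnitude averaging). Every downstream stage is validated against this
ground truth; see the vignette in `vignettes/` for the model, parameter and
design discussion.

## Worked example

```r
library(helixdti)

## simulate the standard acquisition of the default phantom and recover
## its helix-angle law (truth: slope -1.2 deg/%, crossing at 50 %)
scheme <- gradient_scheme(generate_half_shell_directions(32, seed = 0))
rec <- recover_phantom(phantom_spec(snr = 25, seed = 2025), scheme = scheme)
rec$fit
#> HA gradient fit over [20, 80]% depth (n = 38 bins)
#>   slope     -1.201 deg/% (SE 0.007)
#>   intercept +60.01 deg
#>   HA0       50.0% depth, 95% CI [49.8:50.2] (left-handed-dominant)

## the packaged specimen cohort table
s <- cohort_summary(load_cohort(system.file("extdata", "cohort_table1.csv",
                                            package = "helixdti")))
s$n; s$n_vsd           # 24 specimens, 17 with a ventricular septal defect
s$formalin_years       # min 29, median 41, max 57 years in formalin

optimal_bvalue(1.30e-3)
#> [1] 853
```

The recovered slope and crossing match the phantom's prescribed law to
within simulation noise; the cohort numbers are recomputed from the
packaged table.

A complete two-group pipeline (simulate → fit → mask-derived geometry →
angles → group tables) runs with:

```r
res <- run_pipeline(demo_config(seed = 7), "demo_out")
read_result_table(file.path("demo_out", "ha_gradient.tsv"))
```

and a thin CLI wraps the same functions (`exec/helixdti simulate|fit|
geometry|cohort|run`).

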