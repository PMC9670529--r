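# ivimdwi

Quantitative intravoxel incoherent motion (IVIM) analysis of multi-b-value
diffusion-weighted MRI, built around the use case of detecting knee-joint
synovitis without gadolinium contrast: voxelwise segmented bi-exponential
fitting with intensity masking, D/f/D\*/ADC parameter maps, ROI-level
quantification with nonparametric group comparison, a reader-agreement
toolkit (Likert ratings, dichotomization, Cohen's kappa), and a synthetic
knee phantom so the entire pipeline is testable end to end without patient
data.

## The model

IVIM describes the diffusion-weighted signal of a voxel as the superposition
of slow tissue diffusion and fast capillary pseudo-diffusion:

```
S(b) = S0 * ( (1 - f) * exp(-b D) + f * exp(-b D*) )
```

where `D` (mm²/s) is the tissue diffusion coefficient, `f` the perfusion
fraction of the unweighted signal, and `D*` the pseudo-diffusion
coefficient, typically an order of magnitude larger than `D`.  Because the
perfusion term has decayed away at high diffusion weighting (b ≥ 200 s/mm²),

```
S_high(b) = S0 * (1 - f) * exp(-b D)
```

and the parameters can be estimated with the standard **segmented two-step
fit**: (1) an ordinary least-squares line through `log S` vs `b` over the
high-b points gives `D` from the slope and `f` from the intercept relative
to the measured `S(0)`; (2) with `D` and `f` fixed, `D*` is found by bounded
one-parameter least squares of the full bi-exponential over all b-values.
Voxels below 30 % of the maximum b = 0 intensity are masked out.  A
two-point mono-exponential ADC over b = 0/1000 is computed alongside.

## Worked example

Simulate two 10-subject cohorts (a synovitis "patients" group and a healthy
"volunteers" group, tissue parameters drawn from published group
means/SDs), fit every voxel, quantify muscle / synovium / effusion ROIs and
compare the groups:

```r
library(ivimdwi)
res <- run_pipeline(run_config(out_dir = "demo", seed = 1, n_per_group = 10))
res$summary[, c("tissue", "variable", "mean_patients", "mean_volunteers",
                "U", "p", "ranges_overlap")]
```

```
    tissue variable mean_patients mean_volunteers   U        p ranges_overlap
1   muscle        D          1.61            1.73  38 3.93e-01           TRUE
2   muscle        f          7.17            7.84  39 4.36e-01           TRUE
3 synovium        D          1.81            2.52   0 1.08e-05          FALSE
4 synovium        f         10.75            4.83 100 1.08e-05          FALSE
5 effusion        D          2.56            2.07  94 3.25e-04           TRUE
6 effusion        f          3.77           12.19   0 1.08e-05          FALSE
```

D is reported in 10⁻³ mm²/s, f in percent.  The run reproduces the clinical
signature of synovitis: muscle is indistinguishable between groups
(Mann-Whitney p ≈ 0.4, a good internal reference tissue), while inflamed
synovium shows restricted diffusion (lower D) with increased perfusion
(higher f), and joint effusion shows the opposite f pattern — with
completely non-overlapping per-group f ranges at these effect sizes.

The reader-study arm reproduces a two-reader agreement analysis on the
built-in 10-knee rating fixture:

```r
rep <- agreement_report(study_fixture())
rep$comparisons[, c("comparison", "scale", "kappa_round", "label")]
```

```
        comparison       scale kappa_round          label
1  r1_ce_vs_r1_dwi  categories       0.655    substantial
2  r1_ce_vs_r1_dwi dichotomous       1.000 almost perfect
3   r1_ce_vs_r2_ce  categories       0.048         slight
4   r1_ce_vs_r2_ce dichotomous       0.737    substantial
5  r1_ce_vs_r2_dwi  categories       0.219           fair
6  r1_ce_vs_r2_dwi dichotomous       0.375           fair
```

i.e. an experienced reader diagnoses synovitis on DWI in perfect agreement
with contrast-enhanced imaging (kappa = 1 after dichotomization), while
between-reader agreement is far weaker — DWI reading is experience-dependent.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ivimdwi", package = "ivimdwi"))')
Rscript $CLI demo --out out/ --seed 1 --n 10          # full paper-style run
Rscript $CLI phantom --group patients --n 2 --seed 7 --out phantoms/
Rscript $CLI fit --nii dwi.nii --bval dwi.bval --out maps/
Rscript $CLI agreement --fixture --out report/
```

## Layout

* `R/ivim-core.R` — forward model, segmented fit, ADC, fit configuration
* `R/param-maps.R` — masking, voxelwise fitting, NIfTI map export
* `R/phantom.R` — multi-compartment knee phantom, Rician noise, cohorts
* `R/roi-analysis.R` — ROI statistics, repeat CoV, Mann-Whitney
* `R/agreement.R` — ratings, kappa, Landis-Koch labels, the 10-knee fixture
* `R/pipeline.R`, `R/cli.R` — orchestration, manifest, CLI
* `vignettes/ivim-methods.Rmd` — model, assumptions, numerical choices
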