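# petconseg

Consensus contouring and robustness evaluation for ¹⁸F-FDG PET tumor
delineation.

Automatic PET tumor delineation is method-dependent twice over: different
algorithms disagree on the same lesion, and each algorithm's output depends
on the initial mask a reader crops around the lesion. `petconseg` provides a
tested, fully reproducible pipeline to study whether *majority-vote consensus
contours* mitigate that variability. It simulates heterogeneous lung lesions
with known ground truth, delineates them with four automatic methods under
two initial-mask conditions, fuses the results, and quantifies accuracy and
test–retest robustness with the field's standard metrics and nonparametric
statistics.

## What is inside

**Kinetic simulation.** Lesion and background uptake derive from the
two-tissue compartment FDG model

    dCf/dt = K1*Cp - (k2 + k3)*Cf + k4*Cb
    dCb/dt = k3*Cf - k4*Cb
    CT     = (1 - vB)*(Cf + Cb) + vB*Cp

driven by the Feng population arterial input, solved in closed form
(`solve_2tc()`). Shipped parameter sets (`fdg_tissue_params()`) give three
intratumoral uptake levels plus normal thoracic tissues; at 70 min post
injection the lesion-to-lung activity ratios evaluate to ≈ 11.03 : 10.15 : 6.63.

**Phantom generator.** Seeded irregular lesions (log-uniform volumes,
concentric three-level heterogeneity) in uniform lung on a 200 × 200 grid
with 0.50 × 0.41 × 0.41 cm³ voxels; optional 10-bin respiratory-motion
averaging (1.5 cm diaphragm / 0.5 cm AP, bin-3 static reference); PET-like
degradation as Gaussian blur → Poisson noise → 2 mm post-filter.

**Segmentation.** Four methods, each confined to a user-style initial mask
(`rectangle` bounding box vs seeded `irregular` crop): 41% of maximum
(`seg_41max`), contrast-oriented thresholding (`seg_st`), affinity-propagation
clustering (`seg_ap`, compiled message passing), and a region-based
active-contour method (`seg_masac`).

**Consensus + metrics.** Majority vote (`majority_vote`, default 3-of-4),
metric-level averaging (`aveseg`), MATV / RE / DSC (`matv`, `rel_vol_error`,
`dsc`), and the test–retest statistic between mask conditions (`trt`).

**Statistics.** Friedman omnibus test, pairwise Wilcoxon signed-rank (Pratt
zeros, exact small-sample enumeration) with Bonferroni adjustment, and
1.5·IQR box summaries.

## Worked example

```r
library(petconseg)

# lesion-to-lung uptake ratios at 70 min for the three intratumoral levels
p <- fdg_tissue_params()
uptake_ratios(p[c("level1", "level2", "level3")], p$lung)
#> [1] 11.026739 10.154668  6.632351

# a small cohort: simulate, segment with 4 methods x 2 masks, fuse, score
st <- run_study(study_config(n_cases = 3, seed = 1))
st
#> <pet_study> 3 cases, motion TRUE, noise TRUE, methods MASAC/AP/ST/41MAX + ConSeg/AveSeg
#> median (IQR) by method and mask condition:
#>   irregular 41MAX     MATV   9.50 (  8.40,  14.25) cm^3  RE  -47.93%  DSC 0.68
#>   irregular AP        MATV   0.17 (  0.13,   0.17) cm^3  RE  -99.08%  DSC 0.02
#>   irregular AveSeg    MATV   6.20 (  5.38,   9.75) cm^3  RE  -65.07%  DSC 0.48
#>   irregular ConSeg    MATV   7.14 (  6.14,  11.77) cm^3  RE  -56.95%  DSC 0.60
#>   ...
```

The negative median RE values say that every method underestimates the
motion-averaged lesion relative to the motion-union ground truth. The
per-method test–retest summary makes the robustness point directly — the
consensus contour is nearly insensitive to the initial-mask choice while
affinity propagation is highly sensitive:

```r
subset(st$trt_summary, metric == "MATV_cm3")
#>    method   metric  median_TRT median_abs_TRT
#> 2   41MAX MATV_cm3  0.00000000     0.00000000
#> 5      AP MATV_cm3 -0.66666667     0.66666667
#> 8  AveSeg MATV_cm3  0.03416149     0.03416149
#> 11 ConSeg MATV_cm3  0.01626016     0.01626016
#> 14  MASAC MATV_cm3  0.10000000     0.10000000
#> 17     ST MATV_cm3  0.00000000     0.00000000
```

`summary(st)` adds the Friedman/Wilcoxon layer, `plot(st, what = "trt")`
draws the box-whisker panels, and `write_report(st, dir)` exports CSV/JSON
reports. Single phantoms and segmentations are available as standalone steps
(`build_phantom`, `apply_motion`, `degrade`, `gen_masks`, `segment_pet`) and
through a thin command-line front end (`inst/cli/petconseg.R`) with
`simulate | segment | consensus | metrics | study` subcommands operating on
NIfTI volumes.

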