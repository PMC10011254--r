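---
title: "Consensus contouring for PET tumor delineation: models and methods"
author: "petconseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus contouring for PET tumor delineation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petconseg)
```

## The problem

Automatic delineation of the metabolically active tumor volume (MATV) on
¹⁸F-FDG PET is notoriously method-dependent: threshold-based, clustering-based
and active-contour methods can disagree substantially on the same lesion, and
each method's result also depends on the user-drawn initial mask inside which
it operates. A common mitigation is the *consensus contour*: run several
independent methods and keep the voxels on which a majority agrees.
`petconseg` implements a complete, reproducible evaluation of that idea on
synthetic thoracic lesions with known ground truth: it simulates heterogeneous
lung lesions with kinetics-derived uptake, segments them with four methods
under two initial-mask conditions, fuses the results by majority vote, and
quantifies accuracy (relative volume error RE, Dice coefficient DSC) and
robustness (test–retest TRT between mask conditions) with nonparametric
statistics.

## Kinetic model of lesion and background uptake

Tissue uptake is generated with the two-tissue compartment (2TC) model of FDG
kinetics. With arterial plasma input $C_p(t)$, free and phosphorylated
compartments evolve as

$$\dot C_f = K_1 C_p - (k_2 + k_3) C_f + k_4 C_b, \qquad
  \dot C_b = k_3 C_f - k_4 C_b,$$

and the measured tissue activity is
$C_T = (1 - v_B)(C_f + C_b) + v_B\,C_p$, taking whole-blood activity equal to
plasma (no metabolite correction — a deliberate simplification; the package's
ratios are insensitive to the overall input scale). `fdg_tissue_params()`
ships literature-derived parameter sets for three intratumoral uptake levels
(Level I the hottest core tissue, Level III the coldest) plus normal lung,
liver, myocardium and marrow; parameters printed as "–" in the source tables
are taken as 0.

The arterial input is the Feng 4-exponential population model with its
published coefficients (`feng_input()`), which is zero at $t=0$, peaks within
the first minute, and decays as a sum of exponentials. The input function is
exposed in configuration because it is an assumption, not a measurement: the
simulation's lesion-to-lung activity ratios at 70 min therefore carry that
assumption. With the defaults they evaluate to approximately
11.03 : 10.15 : 6.63,

```{r ratios}
p <- fdg_tissue_params()
uptake_ratios(p[c("level1", "level2", "level3")], p$lung)
```

and the ordering Level I > Level II > Level III > lung is a hard invariant of
the parameter sets (it follows from the net-influx ordering), which the test
suite checks separately from the numeric values.

`solve_2tc()` evaluates the model in closed form — the 2TC impulse response is
a sum of two exponentials with rates
$\alpha_{1,2} = \tfrac12\big(s \mp \sqrt{s^2 - 4k_2k_4}\big)$, $s=k_2+k_3+k_4$,
and its convolution with an exponential-polynomial input is analytic. A stiff
numeric integrator (`deSolve::lsoda`) serves as the fallback for arbitrary
function inputs and for the defective double-eigenvalue case, and as the
independent oracle in the test suite (agreement to relative tolerance 1e-6 on
every shipped parameter set).

## The synthetic phantom

`phantom_spec()` / `build_phantom()` generate one lesion-in-lung case on a
200 × 200 transaxial grid with voxel size 0.50 × 0.41 × 0.41 cm³ (axial extent
configurable; the defaults use 48 slices, enough for the largest default
lesion plus motion). The phantom deliberately emulates only the features the
evaluation needs:

* **Irregular lesion geometry.** A sphere of the requested volume is perturbed
  by a smoothed Gaussian random field on its implicit surface
  (`perturb_amp = 0.25`, smoothing 3 voxels), cleaned to a single filled
  component. Volumes of the default 13-case cohort are log-uniform in
  3.5–55 cm³, mirroring realistic static lesion ranges.
* **Intratumoral heterogeneity.** Lesion voxels are partitioned into three
  concentric shells (core = Level I) with equal voxel counts by default. The
  spatial arrangement and the fractions are not constrained by the kinetic
  model; concentric-with-equal-thirds is the package's choice, and a seeded
  random partition can be obtained by permuting the level masks.
* **Background.** Uniform normal lung, normalized to 1, with lesion voxels
  carrying their kinetic lesion-to-lung ratio at the scan time. Other organs
  are not placed in the field of view — the segmentation always operates
  inside a local initial mask, so distant anatomy would be inert.
* **Respiratory motion** (`apply_motion()`). Ten bins over the breathing
  cycle, displacement $d(t) = \tfrac{A}{2}(1-\cos 2\pi t)$ sampled at bin
  midpoints along the cranio-caudal axis (peak-to-peak `diaphragm_cm = 1.5`)
  and anterior-posterior axis (0.5 cm), expressed relative to bin 3 — the
  mid-range "intermediate" phase — so the built lesion is itself the static
  bin-3 reference. Displacements are rounded to whole voxels; rigid integer
  shifts conserve total activity exactly and make the motion-union ground
  truth a strict superset of the static mask whenever the motion exceeds one
  voxel. The averaged activity map assumes no uptake change over the 5 s
  cycle.
* **Image degradation** (`degrade()`). Gaussian blur at
  `psf_fwhm_mm = 12` → Poisson resampling at `noise_scale = 25` expected
  counts per unit activity → Gaussian post-filter of 2 mm. This is an
  image-domain stand-in for the full sinogram/OSEM reconstruction chain, and
  12 mm should be read as an *effective reconstruction resolution* (scanner
  PSF plus partial OSEM convergence and filtering), not a hardware PSF. The
  blur width was fixed once so that degraded lesion-to-background contrast of
  the default motion cohort falls in the 3–4.5 range typical of reconstructed
  thoracic FDG simulations; the static cohort comes out somewhat higher
  (≈5.5–7) because a single image-domain Gaussian cannot reproduce all
  reconstruction losses — a known limitation of the stand-in, not a tunable
  target. Poisson sampling is mean-preserving, so the noise scale controls
  variance only.

What the phantom does **not** emulate: anthropomorphic anatomy, attenuation
and scatter, sinogram-domain noise correlations, time-of-flight effects, and
deformable (non-rigid) respiratory motion. Conclusions from passing tests are
therefore about the behavior of the segmentation/consensus machinery under
controlled degradation, not about any specific scanner.

## Initial masks

Every method runs inside a user-style initial mask (`gen_masks()`):

* **rectangle** — the ground truth's bounding box expanded by 3 voxels per
  axis (clipped at the grid border): generous, contains substantial
  background;
* **irregular** — the ground truth dilated by a seeded, spatially varying
  radius of 1–4 voxels, hole-filled: tight and lesion-shaped.

Both strictly contain the ground truth. The pair emulates the two ways a
reader might crop a lesion, and the TRT metric quantifies how much each
method's output depends on that choice.

## The four delineation methods

* **41MAX** (`seg_41max()`): voxels at or above 41% of the maximum intensity
  inside the mask. Scale-invariant by construction.
* **ST** (`seg_st()`): contrast-oriented threshold
  $T = a\,\mathrm{mSUV}_{70} + b\,\mathrm{BG}$ with $\mathrm{mSUV}_{70}$ the
  mean of the region above 70% of the maximum (recomputed on the current
  estimate until stable) and BG the mean background, taken from a 3-voxel
  shell around the mask unless a background mask is supplied. The calibration
  constants are scanner-specific in the source method; the package defaults to
  $a = b = 0.5$ with configuration override. Setting
  $a = 0.41\,\max/\mathrm{mSUV}_{70},\ b = 0$ reduces ST to 41MAX, which the
  tests exploit as an algebraic cross-check.
* **AP** (`seg_ap()`): affinity-propagation clustering of mask voxels with
  similarity $-(I_i - I_k)^2$ and the median pairwise similarity as shared
  exemplar preference. The tumor is the cluster whose exemplar has the
  highest intensity (the `"largest"`-cardinality alternative is available;
  in a generous mask the largest cluster is usually background, which is why
  hottest-exemplar is the default reading of "largest grouping").
* **MASAC** (`seg_masac()`): two-phase region-based active contour of
  Chan–Vese type in a discrete (morphological) scheme: alternate re-estimation
  of the inside/outside means with reassignment by the two-region data term,
  plus binary-median curvature smoothing that may overrule the data term only
  for voxels whose normalized data margin is below $1/\lambda$. The default
  contrast weight $\lambda = 3$ thus smooths only genuinely ambiguous
  boundary voxels; sharp two-level images are recovered exactly, and
  $\lambda \to \infty$ yields the pure two-region partition. Initialization
  is the 41% mask; evolution is deterministic.

All four retain the largest 26-connected component (single-primary-tumor
setting) and guarantee result ⊆ initial mask.

### Numerical choices for affinity propagation

Three implementation details matter and are worth recording:

1. **Exact duplicates.** Noise-free images contain large intensity plateaus,
   on which per-point message passing provably degenerates (every point its
   own exemplar — reference implementations behave identically). The package
   collapses exact duplicates into weighted points with row-scaled
   similarities, an exact reformulation of the net-similarity objective, and
   computes the preference as the weighted median over distinct-value pairs.
   Noisy inputs (all values unique) are untouched by this.
2. **Damping.** One-dimensional intensity similarities carry many near-ties;
   lightly damped message passing (the classical 0.5) oscillates into the
   degenerate all-singleton state on realistic mask sizes, so the default
   damping is 0.9, and the solver deterministically escalates to
   0.95/0.975/0.99 only when it detects that degenerate state (exemplar
   count exceeding half the points). A seeded jitter at machine precision
   breaks exact message ties, as in the reference implementations.
3. **Scale cap.** Message passing is $O(n^2)$; masks above 3000 voxels are
   intensity-stratified subsampled and the remaining voxels assigned to the
   nearest exemplar by intensity.

A consequence of the specified similarity (intensity only) and preference
(median) is that on noisy images AP partitions the mask into several narrow
intensity bands, so the hottest-exemplar cluster is a small high-uptake core.
This reproduces — and amplifies — the qualitative behavior that motivates the
consensus approach in the first place: AP is by far the most sensitive of the
four methods to the initial-mask choice.

## Consensus and metrics

`majority_vote()` includes a voxel iff at least $k$ of the input masks contain
it (default: strict majority, 3 of 4; $k=1$ gives the union, $k=N$ the
intersection — the tie convention at 2-of-4 is not canonical, so $k$ is
configurable). `aveseg()` is the *metric-level* average of the four methods'
values for one case — averaging metrics, not contours; metric-level averaging
is what makes per-method summary rows arithmetically consistent, and a
probability-map reading of "average segmentation" is deliberately not the
default.

Metrics: MATV (voxel count × voxel volume, cm³),
RE $= (\mathrm{MATV}_{SM} - \mathrm{MATV}_{GT})/\mathrm{MATV}_{GT} \times 100\%$,
DSC $= 2|SM \cap GT|/(|SM| + |GT|)$, and the test–retest value

$$\mathrm{TRT} = \frac{M_\text{rectangle} - M_\text{irregular}}
                     {(M_\text{rectangle} + M_\text{irregular})/2},$$

which is 0 for perfect reproducibility and bounded in $[-2, 2]$ for
non-negative metrics. TRT of signed metrics (RE) can have a near-zero
denominator; values with $|{\rm denominator}| < 10^{-9}$ are reported missing
rather than amplified. DSC of two empty masks is treated as undefined rather
than 1 (conservative). Evaluation ground truth is the motion-union mask for
the motion cohort and the static (bin-3) mask otherwise.

## Statistics

Differences across methods are assessed with the Friedman rank test
(tie-corrected, delegated to `stats::friedman.test`; the all-tied case is
defined as statistic 0, p = 1) followed by pairwise Wilcoxon signed-rank
tests with Bonferroni multiplication capped at 1. The signed-rank test uses
Pratt zero handling (zeros ranked, then discarded) with average ranks,
exact enumeration of the sign-flip distribution up to 25 non-zero
differences and a tie-corrected normal approximation beyond — the variant
choices are documented here precisely because the test names alone do not
pin them down. Box summaries use linear-interpolation quantiles
(`stats::quantile` type 7) with whiskers at 1.5·IQR and outliers beyond the
whiskers flagged (and suppressed in plots).

## The study pipeline

```{r study, eval = FALSE}
cfg <- study_config(n_cases = 13, seed = 1, motion = TRUE)
st <- run_study(cfg)
summary(st)
plot(st, metric = "MATV_cm3", what = "trt")
write_report(st, "report")
```

`run_study()` is fully reproducible from its configuration: per-case phantom
seeds derive from the master seed, and all stochastic stages (lesion shape,
Poisson noise, irregular mask) are seeded. Per mask condition it runs the
four methods, forms ConSeg, computes the metrics against the cohort's ground
truth, adds AveSeg rows, computes per-case TRT values, and summarizes
medians (IQR) with the statistics above. The default cohort (13 cases,
motion, noise) reproduces the qualitative findings the consensus idea rests
on: every method's median RE against the motion-union ground truth is
negative (motion-averaged lesions are underestimated), the consensus
contour's median |TRT| for MATV is far smaller than AP's, and per case the
consensus MATV lies within the span of the four methods. The example sizes
used in the automated checks (grids of 48 × 200 × 200, 13 cases) were chosen
as the smallest cohort at which those orderings are stable.

## Known limitations

* The degradation model is image-domain; absolute contrast and noise
  correlations of a real reconstruction are only approximated (see above),
  so absolute DSC/RE levels are not comparable to scanner data — the
  package's claims are about orderings and reproducibility, which are robust
  to this.
* AP's feature space is intensity-only; adding spatial coordinates would
  change its granularity substantially and is deliberately out of scope.
* The MASAC energy is a documented Chan–Vese stand-in for the original
  method's energy, with $\lambda$ mapped to the data-vs-smoothing balance.
* Lesions are single, solid and lung-embedded; multi-focal disease, necrotic
  cores with inverted contrast, and PET/CT fusion are out of scope.
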