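---
title: "Methods: mechanism mapping of resting-state functional connectivity alterations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanism mapping of resting-state FC alterations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

In relapsing-remitting multiple sclerosis (RRMS), resting-state functional
connectivity (FC) within large-scale brain networks is found both increased
and decreased relative to healthy controls, and the interpretation of either
direction is contested: an FC increase may be compensatory or maladaptive,
and an FC decrease may be driven by focal lesions or by diffuse
neurodegeneration. `fcmech` implements an analysis chain that tries to
disambiguate these possibilities by relating voxelwise FC change to two
clinical covariates — total T2-hyperintense lesion load (T2LL, in mL) and
the Multiple Sclerosis Severity Score (MSSS, a disability score normalized
by disease duration) — and classifying each altered voxel into one of six
mechanism scenarios according to the sign pattern of the associations.

The chain is:

1. **Per-subject preprocessing** — high-pass temporal filtering (150 s
   cutoff), 5 mm FWHM Gaussian spatial smoothing, optional voxelwise
   variance normalization.
2. **Group spatial ICA** — subjects are temporally concatenated; the
   decomposition order is chosen automatically by the Laplace approximation
   to the Bayesian evidence of a probabilistic PCA model; spatially
   independent component maps are extracted by a fixed-point negentropy
   iteration with symmetric decorrelation; components are labeled as
   resting-state networks (RSNs) or artifacts by template correlation and
   time-course spectral content.
3. **Dual regression** — stage 1 regresses each subject's volumes on the
   group maps (time courses); stage 2 regresses each voxel's time series on
   those time courses (subject-specific parameter-estimate and Z maps).
4. **Permutation inference** — voxelwise GLM contrasts (MS < HC, MS > HC,
   and MS_short vs MS_long) with age, gender, education and gray-matter
   ratio as nuisance covariates; Freedman-Lane permutation of the
   explanatory variable; threshold-free cluster enhancement (TFCE); FWE
   correction by the permutation distribution of the image-wide maximum.
5. **gFC ranking** — a per-network global alteration index summing |t| over
   FWE-significant voxels, capturing both the extent and the magnitude of
   the change.
6. **Covariate cascade** — voxels surviving FWE p <= 0.05 in a group
   contrast form the mask for a second permutation analysis with T2LL as
   the explanatory variable (`tstatFC_T2LL`); its significant voxels form
   the mask for a third analysis with MSSS (`tstatFC_T2LL_MSSS`). The three
   significant sets are strictly nested by construction. Per-subject mean Z
   values over the masked regions give Pearson correlations with the
   covariates, Bonferroni-corrected over the tests actually run.
7. **Scenario classification** — each FC-altered voxel is labeled by the
   sign triple (FC direction, T2LL association, MSSS association):

   | scenario | FC | T2LL | MSSS | mechanism |
   |---|---|---|---|---|
   | 1  | − | − | (any) | FC reduction driven by lesions |
   | 2  | + | − | (any) | true functional compensation |
   | 3a | + | + | − | functional compensation attempt |
   | 3b | + | + | + | false functional compensation |
   | 4a | − | + | − | neurodegeneration |
   | 4b | − | + | + | pre-symptomatic condition |

   Signs are the signs of the covariate *t* statistics (positive = FC
   increases with the covariate). Scenarios 1 and 2 do not consult the MSSS
   stage; a voxel whose T2LL association is positive but whose MSSS stage
   is not significant remains unlabeled. Because published descriptions of
   the 4a/4b pair are internally inconsistent (level language vs
   correlation language), both conventions are implemented;
   `scenario_sign_table(convention = "methods")` swaps the 4a/4b MSSS
   signs. The default follows the correlation-sign reading used in the
   results and figure captions of the source analysis.

No public dataset accompanies the analysis, so the package ships a
synthetic-cohort generator with planted ground truth; every downstream
stage is validated against what the generator planted.

## The synthetic cohort

`cohort_config()` defaults encode the reference study conditions:
29 healthy controls and 62 RRMS subjects, subdividable into 36 with short
(≤ 5 years) and 26 with long (5–15 years) disease duration; TR 2.5 s;
T2LL lognormal with meanlog `log(16.63) − 0.5` and sdlog 1 (mean 16.63 mL,
SD ≈ 22 mL, matching the reported cohort moments); MSSS uniform on 0–6
(the cohort was mildly disabled; no distribution is reported, so a
noncommittal uniform is used); age, education, gender fractions and GM
ratio drawn around the reported group means. HC rows carry missing T2LL,
MSSS and disease duration, and are never imputed: covariate stages use MS
subjects only.

Volumes are generated on a 20×20×12 voxel grid with 120 timepoints — a
desk-scale stand-in for a 64³-voxel acquisition that preserves genuine 3D
cluster topology for TFCE. Each of 6 network templates is a smooth
Gaussian blob (σ = 1.6 voxels) normalized to peak 1, placed by maximin
sampling so suprathreshold (> 0.5) extents are disjoint. Each voxel's
signal is

    y(v, t) = Σ_k c_k(subject, v) · w_k(v) · s_k(t) + ε,  ε ~ N(0, noise_sd²)

with `s_k` unit-variance band-limited (0.01–0.1 Hz) Gaussian time courses —
the canonical resting-state frequency band — and `c_k` the subject's
network coupling: baseline 1 plus N(0, 0.15²) between-subject jitter, plus,
inside a scenario region for MS subjects,
`fc_effect + t2ll_slope·T2LL + msss_slope·MSSS`.

Default planted magnitudes are `fc_shift = 0.5` (the *net* mean MS-vs-HC
coupling difference at the covariate means; `fc_effect` is solved from it),
`t2ll_slope = ±0.015` per mL and `msss_slope = ±0.15` per MSSS unit. These
were fixed once, from two structural constraints rather than from any
particular test run: the net shift must stay well below the baseline
coupling, because a reduced-FC region whose mean MS coupling crosses zero
cancels out of the pooled group map and becomes invisible to dual
regression; and each covariate's coupling spread across subjects
(slope × covariate SD ≈ 0.26–0.33) must exceed the between-subject jitter
so the planted associations are identifiable at n = 62 while the group
shift still dominates the within-group spread. An MS_short-specific shift
(+0.6) is planted in the true-compensation region, emulating the reported
overlap of short-duration FC increases with compensation areas.

What the generator deliberately does **not** model: hemodynamic response,
head motion, physiological noise, scanner drift, registration error, or
spatially varying noise. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated on network-structured
band-limited signals in homoscedastic Gaussian noise — not that the
pipeline is robust to the artifact structure of real acquisitions (the
reference pipeline delegates that to single-subject ICA denoising, which
is out of scope here).

## Numerical and design choices

**High-pass filter.** Implemented as projection-removal of a discrete
cosine drift basis (all DCT frequencies below 1/cutoff, plus the constant),
matching the "equivalent to 150 s" phrasing; deterministic and phase-free.
The exact filter of the reference implementation (Gaussian-weighted running
lines) is not reproduced; the passband/stopband contract is tested
spectrally instead.

**Smoothing.** Separable Gaussian, σ = FWHM/(2√(2 ln 2)) in mm converted to
voxels via the affine; reflective boundaries, so the spatial sum is
conserved exactly; sheared affines are rejected rather than silently
mishandled.

**Variance normalization.** `variance_normalize()` scales every in-mask
voxel to unit sample variance (zero-variance series untouched). The
pipeline default leaves it **off**: the generator's noise is homoscedastic,
and total-variance scaling erases the amplitude profile that carries the
planted couplings — on noiseless data it reduces every network blob to an
indicator-like plateau and destroys map recovery. On real data with
spatially varying noise floors it is the standard pre-decomposition
conditioning, hence the exposed switch.

**Order selection.** The Laplace/Stiefel evidence is evaluated on the
eigen-spectrum of the samples-dimension covariance, candidates 1 to
min(rank, samples − 2, 40). Exactly low-rank inputs make the profiled
residual variance vanish, so the evidence is taken as unbounded at the
rank (the exact-reconstruction case) with a warning. On temporally
concatenated cohorts the true temporal rank is ≈ subjects × networks, so
the automatic order correctly saturates the cap (the reference analysis
similarly retained 35 components of which 18 were RSNs); the estimator's
accuracy is validated on samples × voxels benchmarks with a planted order.
For order estimation the concatenated series is temporally subsampled to
500 samples so the voxels-exceed-samples regime of the evidence model
holds.

**ICA.** Whitening uses a seeded randomized SVD (oversampling 10, two
power iterations): only `order` components are needed and the exact
crossproduct of a ~10⁴×5·10³ concatenated matrix would dominate the whole
pipeline's runtime. The fixed-point iteration uses the tanh (log-cosh)
contrast, symmetric decorrelation, tolerance 1e-6, max 500 iterations, and
up to 5 seeded restarts. Component sign is fixed by making the
largest-magnitude voxel positive, and components are ordered by explained
variance, giving bit-reproducible output for a fixed seed. Maps are
Z-scaled to mean 0, sample variance 1 over the mask.

**Dual regression.** Stage-1 time courses are variance-normalized before
stage 2 by default (the common convention; the source analysis does not
state its choice), which makes subject maps carry amplitude as well as
shape. Group statistics consume the parameter-estimate maps; the Z maps
feed the region mean-Z summaries of the cascade. Stage-2 Z values are the
coefficient t statistics mapped through the t → standard-normal quantile
transform at T − k degrees of freedom, computed on the log scale for
numerical stability.

**TFCE.** `TFCE(p) = Σ_h e(h,p)^E · h^H · dh` with the standard E = 0.5,
H = 2, 26-connectivity, and dh = (observed max)/100 unless given.
Negative statistics are enhanced on the negated map separately. The
implementation inserts voxels into a weighted union-find in decreasing
height order and sweeps thresholds downward, accumulating per-cluster
increments on the root with per-node offsets — identical (to machine
precision, and tested) to per-threshold relabeling, but roughly an order
of magnitude faster, which is what makes 200-cohort calibration
experiments and multi-seed closed-loop runs affordable.

**Permutation scheme.** Freedman-Lane in the model-permutation form: the
data are residualized against the nuisance regressors once, and the
explanatory variable column is permuted (for a binary EV, group
relabelings; for a continuous EV, row permutations). The observed
statistic is then algebraically identical to the full-model t on the raw
data, because components in the nuisance span affect neither the contrast
estimate nor the residual sum of squares. When the number of distinct
relabelings/permutations does not exceed `n_perm`, the set is enumerated
exhaustively and p-values are exact fractions; otherwise
`p = (1 + #{max ≥ obs})/(1 + n_perm)`. One-sided contrasts are run
separately per direction. Both covariate stages retain the demographic
nuisance covariates by default (the source is silent; `keep_nuisance`
switches this off).

**gFC.** The source cites its global FC index to prior work without
reproducing the formula, stating only that it combines cluster extension
and magnitude. Here `gfc = Σ |t|` over FWE-significant voxels inside the
network's extent (extent enters through the count, magnitude through
|t|); the scorer is a pluggable function argument. Network extent for
ranking is the group component map thresholded at |Z| ≥ 3 (a standard
display threshold; configurable). Each component's cascade is also
restricted to its own extent, which prevents adjacent components'
significance masks from cross-labeling boundary voxels.

**Problem sizes.** The shipped analyses and checks use the default
20×20×12 grid with 91 subjects, 150–500 permutations per inference in the
scripted runs (5000 remains the package default for a standalone
analysis), 200 null cohorts for FWE calibration, and 6–10 seeded
closed-loop runs; these sizes were chosen so a complete reproduction runs
on a laptop core in minutes while keeping every statistical check at a
meaningful resolution (500 permutations bound attainable p at 0.002).

## Known limitations

- The scenario classifier consumes marginal significance signs per stage;
  it does not model the joint distribution of the three statistics, so
  borderline voxels can drop out of the classification (label `none`)
  rather than receive an uncertain label.
- The gFC formula is an interpretation of a verbal description, not a
  reproduction of the cited index.
- Order selection on concatenated data reports the concatenation rank, not
  the number of biological networks; RSN identification relies on the
  template-matching step, which in turn presumes templates are available
  (on synthetic data they are the generator's own).
- Pearson summaries use the mean Z over the masked region; other regional
  summaries (medians, first eigenvariates) are not implemented.
- The permutation engine assumes exchangeable subjects; there is no
  support for exchangeability blocks (e.g., repeated measures).
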