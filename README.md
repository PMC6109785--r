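# fcmech — mechanism mapping of resting-state FC alterations

`fcmech` implements a complete resting-state fMRI group analysis for
two-group cohorts (multiple sclerosis patients vs healthy controls) whose
goal is not just to *detect* functional connectivity (FC) alterations but
to *interpret* them mechanistically. FC within large-scale resting-state
networks (RSNs) is found both increased and decreased in MS; whether an
increase is compensatory, or a decrease lesion-driven, cannot be decided
from the group contrast alone. The package relates every altered voxel to
two clinical covariates — T2 lesion load (T2LL, mL) and the Multiple
Sclerosis Severity Score (MSSS) — through a sequential masked permutation
cascade, and classifies voxels into six mechanism scenarios by the sign
pattern of the associations:

| scenario | FC | FC~T2LL | FC~MSSS | mechanism |
|---|---|---|---|---|
| 1  | ↓ | − |   | FC reduction driven by lesions |
| 2  | ↑ | − |   | true functional compensation |
| 3a | ↑ | + | − | functional compensation attempt |
| 3b | ↑ | + | + | false functional compensation |
| 4a | ↓ | + | − | neurodegeneration |
| 4b | ↓ | + | + | pre-symptomatic condition |

The analysis chain: per-subject preprocessing (150 s high-pass, 5 mm FWHM
smoothing) → temporally concatenated group spatial ICA with automatic
model-order selection (Laplace evidence of a probabilistic PCA model) and
RSN/artifact component classification → dual regression (subject time
courses, then subject spatial maps) → voxelwise GLM contrasts with
Freedman–Lane permutation testing, threshold-free cluster enhancement
(TFCE) and max-statistic FWE correction → a per-network global alteration
index, `gFC = Σ|t|` over FWE-significant voxels, ranking networks by
combined extent and magnitude of change → the masked T2LL and MSSS
cascades (`tstatFC` → `tstatFC_T2LL` → `tstatFC_T2LL_MSSS`, strictly
nested) → the scenario classifier and overlap reports against the
disease-duration subgroup contrasts (MS_short vs MS_long).

Because no public dataset accompanies the analysis, the package includes a
first-class synthetic-cohort generator (`simulate_cohort()`): 29 HC + 62 MS
subjects (36 short / 26 long disease duration) with band-limited
(0.01–0.1 Hz) network-structured BOLD signals, planted group coupling
differences of both signs, per-subject couplings tied linearly to T2LL and
MSSS with configurable signs, and a ground-truth scenario label map. Every
stage of the pipeline is validated closed-loop against what the generator
planted. See the methods vignette (`vignettes/fcmech-methods.Rmd`) for the
model, parameter choices, and what the synthetic data do and do not
emulate.

## Worked example

Simulate the default cohort with four planted mechanisms (1, 2, 3b, 4b)
and run the full pipeline:

```r
library(fcmech)
cfg <- cohort_config(scenarios = c("1", "2", "3b", "4b"))
run <- run_pipeline(pipeline_config(cohort = cfg, n_perm = 500, seed = 42))
run
#> <pipeline_run> 91 subjects, 6 RSN components, seed 42
#> scenarios present: 1, 2, 3b, 4b

tb <- run$gfc_table; tb[tb$gfc > 0, ]
#>  network contrast      gfc n_sig_voxels
#>    PNsup    MS<HC 441.7365           87
#>      MVN    MS<HC 423.3751           72
#>      LVN    MS>HC 583.4342           78
#>       PN    MS>HC 121.2446           29
```

The four planted networks — and only those — show FWE-significant
alterations, with the FC reductions (scenario 1 in MVN, 4b in PNsup) under
MS&nbsp;<&nbsp;HC and the increases (2 in LVN, 3b in PN) under
MS&nbsp;>&nbsp;HC. The cascade's Pearson summaries (per-subject mean Z over
each significant region vs the covariate) recover the planted association
signs:

```r
do.call(rbind, lapply(run$cascades, `[[`, "pearson"))
#>                       region covariate      r p_bonferroni  n
#>   LVN:MS>HC:T2LL-correlated      t2ll -0.299     1.81e-02 62
#>    PN:MS>HC:T2LL-correlated      t2ll  0.529     1.98e-05 62
#>    PN:MS>HC:MSSS-correlated      msss  0.724     5.80e-11 62
#>   MVN:MS<HC:T2LL-correlated      t2ll -0.600     2.60e-07 62
#> PNsup:MS<HC:T2LL-correlated      t2ll  0.500     7.03e-05 62
#> PNsup:MS<HC:MSSS-correlated      msss  0.720     8.66e-11 62
```

and the voxelwise scenario labels match the ground truth exactly on this
seed (100% inside the planted regions), with the MS_short > MS_long
subgroup map overlapping only the true-compensation region — the planted
duration effect:

```r
run$report$overlaps[run$report$overlaps$percent > 0, ]
#>             query scenario percent
#>  MS_short>MS_long        2     100
```

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate.R` … `04_scenario_report.R`), each writing its tables under
`results/`.

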