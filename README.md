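# ecgscar

Explainable detection and localization of left-ventricular (LV) scar from
12-lead ECGs in hypertrophic cardiomyopathy (HCM).

LV scar (replacement fibrosis) is normally assessed by
late-gadolinium-enhancement MRI, which is costly and often unavailable.
Because scar slows depolarization and disperses repolarization, it leaves
lead-specific traces in the routine 12-lead ECG. `ecgscar` turns a
fiducial-annotated ECG into three regional scar probabilities (basal, mid,
apical LV) plus a global call, and explains every prediction feature by
feature. It is aimed at researchers building or evaluating ECG-based scar
markers; since the original clinical cohorts are not public, the package
ships a synthetic ECG/cohort generator with analytically known ground truth
so the entire pipeline is testable end to end.

## Method

1. **Features.** Each beat in each lead yields 23 interpretable
   depolarization/repolarization features (amplitudes, durations, slopes,
   energies `∫(v−b)²dt`, signed areas `∫(v−b)dt`, ST/TP geometry,
   fragmentation, T inversion); beat-averaged per lead and concatenated
   lead-major into a 12 × 23 = 276-dimensional vector *V*.
2. **Confounder adjustment (training only).** Every feature is regressed on
   LV mass index, age and sex; training uses the re-centred OLS residuals,
   while inference always uses raw features.
3. **Patient partitioning.** A variational Dirichlet-process Gaussian
   mixture clusters patients by ECG similarity; clusters where one class
   outnumbers the other by the current dominance ratio (2.0, halved each
   iteration) are pooled into merged groups until everyone is assigned —
   with defaults this provably stops after ≤ 2 iterations with ≤ 2 groups.
   New ECGs route to the nearest group centroid.
4. **Self-supervised classification.** Per group and region, an encoder *f*
   is pretrained with SCARF-style random feature corruption (60 % of
   coordinates resampled from the empirical marginals) under an InfoNCE
   contrastive loss, then a head *h* is attached and both are fine-tuned on
   class-weighted cross-entropy. Global scar = basal **or** mid **or**
   apical.
5. **Explanation.** Kernel SHAP (exact on full enumeration, sampled
   otherwise) attributes each prediction to the 276 features; summaries
   report mean |φ| per ECG component × lead and the frequency with which a
   feature lands in a prediction's top-20 % attributions, alongside Welch
   t-tests of scar vs no-scar feature values.

## Worked example

```r
library(ecgscar)

# a synthetic cohort with planted clusters, confounders and scar signatures
fit <- run_train(pipeline_config(seed = 101,
                                 cohort = cohort_config(seed = 7)))
print(fit)
#> scar_pipeline (trained)
#>   basal   F1 0.803  Se 0.757  Sp 0.895  PPV 0.853
#>   mid     F1 0.837  Se 0.825  Sp 0.917  PPV 0.850
#>   apical  F1 0.848  Se 0.865  Sp 0.913  PPV 0.832
#>   global  F1 0.896  Se 0.855  Sp 0.905  PPV 0.941
```

Regional rows are the held-out confusion metrics per LV region; `global`
is the inclusive-OR call. Predict and explain new ECGs:

```r
res <- run_predict(fit, fit$cohort$features[1:2, ], explain = TRUE)
res$predictions[1, c("p_basal", "p_mid", "p_apical", "pred_global")]
#>        p_basal        p_mid     p_apical pred_global
#> 1 0.0004207263 9.768264e-06 6.621019e-07           0
print(res$explanations$basal[[1]])
#> shap_explanation: f(x) = 0.0004, base = 0.1873, 276 features
#>   V1_q_amplitude               -0.0240
#>   I_q_amplitude                -0.0231
#>   V6_q_amplitude               -0.0119
#>   V1_t_downslope               -0.0111
#>   aVR_qrs_fragmentation        -0.0100
```

This ECG is scar-negative everywhere: its basal probability (0.0004) sits
far below the background expectation (`base` = 0.187), and the largest
attributions — shallow Q waves in V1 and I — push away from scar, matching
the planted basal signature read in reverse. `base + sum(phi) = f(x)`
holds exactly for every explanation.

Waveform-level input works through `extract_from_files(waveform.csv,
fiducials.json)`; a command-line front end with `simulate / extract /
train / predict / explain / evaluate` verbs is installed at
`system.file("cli", "ecgscar", package = "ecgscar")`.

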