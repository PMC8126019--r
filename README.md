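# habitomics

Radiomic classification of glioblastoma tumor habitats from multiparametric
MRI.

Glioblastoma (GBM) lesions decompose on MRI into four tissue habitats —
necrotic core, solid enhancing part, peritumoral tissue, and peritumoral
edema — whose demarcation guides biopsy, resection and radiotherapy
planning. `habitomics` implements a complete radiomics pipeline for
classifying these habitats from co-registered multiparametric volumes
(T1-CE, T2-WI, T2-FLAIR, ADC; NIfTI) plus an integer label mask
(0 = background, 1 = necrosis, 2 = solid, 3 = peritumoral, 4 = edema):

* **Feature extraction** — a fixed 1316-value vector per (subject, habitat)
  region: per modality, 16 first-order statistics, 16 local-binary-pattern
  histogram statistics, 8 three-dimensional shape descriptors, 22 gray-level
  co-occurrence (GLCM) and 11 run-length (GLRLM) texture statistics, and 256
  aggregated SIFT descriptor values (4 × 329 = 1316; the battery decomposes
  as 128 intensity-histogram + 32 geometry + 132 texture + 1024 SIFT
  features).
* **Classification** — leave-one-out cross-validation (LOOCV) of k-nearest
  neighbours, Gaussian naive Bayes, random forest (500 trees, 8 candidate
  features per split) and a two-hidden-layer MLP, with exhaustive grid
  search, one-vs-rest recall/precision/F1/accuracy, and rank-statistic
  ROC/AUC. For a class dissected one-vs-rest from the confusion matrix,

      recall = TP/(TP+FN)        precision = TP/(TP+FP)
      F1 = 2·P·R/(P+R)           accuracy = (TP+TN)/(TP+FP+TN+FN)

* **Feature analysis** — impurity-based random-forest importance averaged
  over 10 seeded forests, top-20 selection, and Pearson/Spearman correlation
  of the selected features with the ordinal habitat label.
* **Synthetic phantoms** — a generator of multiparametric cohorts with four
  nested ellipsoidal habitats whose per-region intensity, texture
  correlation length and histogram skew are controllable, including a
  `separation` dial from fully contrasted (1) to statistically
  indistinguishable (0). All tests and examples run on phantoms; no patient
  data are required.

## Worked example

```r
library(habitomics)

spec   <- phantom_spec(n_subjects = 6, seed = 1)   # 64x64x32, 1 mm voxels
cohort <- generate_cohort(spec)
print(cohort[[1]])
#> Multiparametric sample S001
#>   volume: 64 x 64 x 32 voxels, spacing 1 x 1 x 1 mm
#>   modalities: T1CE, T2W, FLAIR, ADC
#>   region voxels: necrosis=508, solid=2396, peritumoral=6109, edema=15483

feats <- extract_cohort_features(cohort)   # 24 rows x (2 + 1316) columns
fm    <- feature_matrix(feats)

cv <- habitat_loocv(fm$x, fm$y, "random_forest", seed = 1)
summary(cv)
#> Leave-one-out cross-validation: random_forest on 24 samples
#> Overall accuracy: 1.000
#>
#> Confusion matrix (rows = truth):
#>              predicted
#> truth         necrosis solid peritumoral edema
#>   necrosis           6     0           0     0
#>   solid              0     6           0     0
#>   peritumoral        0     0           6     0
#>   edema              0     0           0     6
#> ...
#> Per-class AUC:
#>    necrosis       solid peritumoral       edema
#>           1           1           1           1

imp <- rank_importance(fm$x, fm$y, seed = 1)
head(imp$ranking, 3)
#>                  name    score rank
#>  FLAIR_firstorder_P90 0.004316    1
#>    ADC_firstorder_RMS 0.003673    2
#>  ADC_shape_Sphericity 0.003641    3
```

Each held-out (subject, habitat) region was classified from its 1316
features; at full profile separation the forest recovers all 24 regions
(overall accuracy 1.000, per-class AUC 1), and the importance ranking mixes
intensity, shape and texture features — exactly the behaviour expected when
every feature family carries region signal. With
`phantom_spec(separation = 0, ...)` the same pipeline scores at chance
(0.25), since the generator then makes the label independent of every
feature.

`run_pipeline(out_dir, spec = spec, seed = 1)` runs the whole chain and
writes `features.csv`, `predictions.csv`, `metrics.json`, `importance.csv`
and correlation matrices; re-running with the same seed reproduces the files
byte-identically.

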