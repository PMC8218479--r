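# abeT1

Semi-quantitative diagnosis of neonatal acute bilirubin encephalopathy
(ABE) from T1-weighted MRI.

Neonates with severe hyperbilirubinemia (HB) are screened with T1-weighted
MRI for the basal-ganglia hyperintensity of ABE, but visual reading of the
globus pallidus (GP) and subthalamic nucleus (STN) is unreliable: normal
myelination mimics the signal and inter-rater agreement is only moderate.
This package implements the semi-quantitative alternative: on the axial
slice covering the largest cross-section of both nuclei, measure

    GP_norm  = mean(GP intensity)  / mean(WM intensity)
    STN_norm = mean(STN intensity) / mean(WM intensity)

with WM an anterior subcortical white-matter reference region, and call a
subject ABE when the score exceeds the cutoff maximizing the Youden index
J = sensitivity + specificity − 1 over the empirical ROC curve. Because
the scores are ratios, they are invariant to the scanner's arbitrary
intensity scale.

The package provides, as tested R code:

* a synthetic phantom-image cohort generator (`phantom_config()`,
  `generate_phantom_dataset()`) emulating the clinical study design — 47
  ABE vs 32 non-ABE subjects, GP_norm 1.39 ± 0.06 vs 1.33 ± 0.06, STN_norm
  1.47 ± 0.09 vs 1.42 ± 0.07, cohort covariates, 18-slice stacks — with
  NIfTI + CSV output and seeded reproducibility;
* ROI quantification (`roi_mean()`, `select_slice()`,
  `normalized_intensities()`, `build_feature_table()`);
* from-scratch ROC analysis with oracles (`roc_curve()`, `auc()`,
  `auc_rank()`, `binormal_auc()`, `youden_cutoff()`) and the
  `semiquant()` model interface with `print`/`summary`/`coef`/`predict`/
  `plot`/`simulate` methods;
* diagnostic metrics with the clinical display convention
  (`classification_metrics()`), Fleiss' kappa, accuracy comparison by
  chi-squared, Welch tests from summary statistics, and covariate-adjusted
  group tests (`adjusted_group_test()`);
* a compact residual network with SGD-momentum training, the 80/20 +
  fivefold protocol, augmentation, and class activation mapping
  (`build_backbone()`, `train_eval()`, `class_activation_map()`,
  `cam_localization_experiment()`), runnable from scratch on one CPU.

## Worked example

Generate a study-sized phantom cohort, extract the per-subject scores,
and fit the threshold model:

```r
library(abeT1)
set.seed(17)
cfg <- phantom_config(seed = 17)
ds  <- generate_phantom_dataset(cfg)   # 79 subjects, 18 slices each
ft  <- feature_table(ds$stacks, ds$records)
head(ft, 3)
#>   subject_id  gp_norm stn_norm label selected_slice_index
#> 1       S001 1.405358 1.461554   ABE                    8
#> 2       S002 1.449707 1.331597   ABE                    8
#> 3       S003 1.371769 1.355617   ABE                    8

fit <- semiquant(label ~ gp_norm, ft)
fit
#> Semi-quantitative threshold diagnostic model
#>   score: gp_norm   positive class: ABE
#>   AUC = 0.8032; Youden cutoff = 1.3653 (J = 0.5898)

fit$metrics
#> sensitivity  80.90%
#> specificity  78.10%
#> precision    84.44%
#> f1           82.61%
#> accuracy     79.75%

predict(fit, data.frame(gp_norm = c(1.30, 1.37, 1.40)))
#> [1] "non-ABE" "ABE"     "ABE"
```

The fitted cutoff (1.3653 on this replicate) sits where the two group
score distributions cross, near the midpoint of the configured group
means (1.39 and 1.33); across many replicate cohorts its average matches
the published optimum. The apparent AUC of a single 79-subject cohort
scatters around the population value
`binormal_auc(1.39, 0.06, 1.33, 0.06)` = 0.760 with a standard error of
about 0.06, so individual replicates between roughly 0.70 and 0.82 are
expected.

## Documentation

The methods vignette (`vignettes/semiquant-methods.Rmd`) describes the
score, the ROC and display conventions, what the phantom generator does
and does not emulate, the desk-scale network design and its measured
trade-offs, and the package's numerical conventions.
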