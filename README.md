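# rpvpipe

Multi-region CT radiomics signatures with reproducibility filtering,
harmonisation, and survival evaluation.

## The problem

In thoracic oncology, quantitative features computed from routine CT scans
("radiomics") can act as non-invasive biomarkers — for example, predicting
whether a non-small-cell lung cancer harbours an actionable driver mutation
and stratifying patients into prognostic risk groups. A robust workflow of
this kind involves far more than fitting a classifier: segmentations of
several tissue regions per scan, a large standardised feature catalogue,
filtering of features that are not reproducible across observers or repeat
scans, removal of scanner/site batch effects, leakage-free model
selection, and survival analysis of the resulting score.

`rpvpipe` implements that whole chain as composable, tested R functions,
for methodologists who want to study or extend multi-region radiomics
pipelines. Because clinical cohorts cannot ship with a package, it also
provides a synthetic phantom generator reproducing the statistical
structure the pipeline assumes (label-dependent lesion intensity/texture,
site batch effects, two raters, test–retest pairs, label-linked survival),
so every stage is verifiable end to end without any external data.

## The model in brief

Per scan, three regions of interest (ROIs) on a common 1 × 1 × 2 mm grid:
the **lesion**, a **perilesional annulus** of 5 mm physical thickness
(metric dilation minus lesion), and a **2 cm spherical parenchymal patch**.
Each ROI yields **666 features** (1,998 per scan): 18 image types
(original, 8 undecimated coiflet-1 wavelet subbands, a
Laplacian-of-Gaussian response at σ = 2 mm, and 8 wavelet subbands of the
LoG) × 36 intensity features (18 first-order + 18 GLCM texture), plus 14
shape and 4 box-counting fractal-dimension features.

Modelling: features with inter-observer ICC(2,1) < 0.8 or test–retest
ICC < 0.9 are discarded; the rest are standardised, harmonised across
sites with parametric empirical-Bayes ComBat, reduced by Spearman
relevance ranking with pairwise redundancy elimination (|ρ| > 0.9), and
fed to L1-penalised logistic regression with cross-validated penalty. The
non-zero coefficients define the radiomics predictive vector (RPV):

    score(x) = logistic( b0 + Σ_i w_i x_i ),

thresholded at the Youden-optimal training cutoff. Evaluation covers ROC
analysis with bootstrap CIs, uni-/multivariable logistic models with a
points-based nomogram, Kaplan–Meier/log-rank/Cox stratification, and
cohort-comparison statistics (Pearson chi-square, Wilcoxon rank-sum).

## Worked example

```r
library(rpvpipe)

spec  <- phantom_spec(label_texture_effect = 25)           # strong label effect
train <- generate_cohort(spec, cohort_spec(n_cases = 40, prevalence = 0.5,
                                           survival_hr = 2.5, seed = 11))
test  <- generate_cohort(spec, cohort_spec(n_cases = 40, prevalence = 0.5,
                                           survival_hr = 2.5, seed = 12))

x_train <- extract_cohort(train$cases)   # 40 x 1998 feature matrix
x_test  <- extract_cohort(test$cases)

fit <- rpv_train(x_train, train$cohort$label,
                 batch = train$cohort$site_id, seed = 1)
fit
#> <rpv_fit> standardise:1983 -> combat -> spearman:50 -> lasso:14

pred <- rpv_predict(fit, x_test, batch = test$cohort$site_id)
roc_analysis(pred$probability, test$cohort$label, seed = 1)
#> <roc_result> AUC = 0.792 (95% CI 0.637-0.921), accuracy 0.775 at threshold 0.671

survival_stratification(pred$probability, test$cohort$survival_months,
                        test$cohort$event, cut_rule = "median")
#> <survival_result> log-rank p = 0.215; Cox HR = 1.61 (95% CI 0.75-3.42)
```

Reading the output: 15 of the 1,998 features were constant on this small
cohort and dropped at standardisation; the Spearman stage kept 50
candidates and the LASSO retained 14 (several of them wavelet first-order
features of the annulus — perilesional signal is deliberately planted by
the phantom). The signature separates the held-out classes well above
chance (AUC 0.79); at 40 test cases the survival stratification is
directionally right (HR 1.61) but, as the wide CI shows, underpowered —
which is exactly what a 40-case cohort should look like.

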