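# cytosig

Multivariate cytokine signature analysis for case-control immunoassay
panels.

## What problem this solves

Multiplexed Luminex-style panels measure dozens of cytokines/chemokines
(pg/mL) per plasma or tissue sample. In small case-control cohorts —
patients with a rare disease versus familial controls, knockout versus
wild-type mice — inflammatory mediators are co-regulated and individually
noisy, so the informative object is a weighted multivariate *profile*, not
any single analyte. cytosig is for biostatisticians and translational
researchers who need that workflow end to end:

* **Discriminant / continuous PLS** (`cyto_pls()`): analytes are z-scored
  per column and regressed against a two-group label (coded ±1) or a
  clinical score by NIPALS partial least squares with two latent
  variables. For a single response the component-1 weights have the closed
  form $w_1 \propto X^\top y$; the fitted latent plane is orthogonally
  rotated so all group separation lies along LV1 with cases positive. The
  per-analyte LV1 weights ("loadings") are the signature.
* **Leave-K-out stability** (`lkocv_profile()`): the model is refitted 100
  times with K random samples removed; sign-aligned replicate loadings
  give each analyte a mean ± SD and coefficient of variation.
* **Rank-based univariate screens** (`dunn_test()`, `wilcoxon_rank_sum()`,
  `univariate_screen()`): Dunn's test with Bonferroni correction for
  3-group comparisons, Wilcoxon rank-sum (exact by enumeration for small
  samples) for 2-group comparisons.
* **Outlier screening** (`remove_outliers()`): iterative PCA +
  Mahalanobis distance against a chi-square 99.5% confidence ellipse.
* **Cross-dataset signatures** (`harmonize()`, `select_coincident()`,
  `reduced_fit()`, `transfer_signature()`): restrict two panels (e.g.
  human plasma and mouse brain) to shared analytes, select the analytes
  whose loadings satisfy |mean| ≥ 0.2 and CV < 1 in *both* datasets with
  agreeing direction, refit on the reduced panel, and project one
  dataset's model onto the other, reporting the case-control AUC.
* **Synthetic cohorts with ground truth** (`gen_cohort()`,
  `gen_clinical_scores()`, `gen_paired_datasets()`): log-normal
  concentrations with one latent inflammation factor, planted case
  effects, a "mild" attenuated subgroup, and ordinal clinical scores —
  for power and recovery studies when real tables are unavailable.
* **One-call pipeline** (`run_pipeline()`): simulate → preprocess → fit →
  stability → univariate → coincident selection → reduced refit →
  transfer, with seeded, bit-reproducible TSV/JSON outputs.

See the methods vignette (`vignettes/cytokine-signatures.Rmd`) for the
model, its assumptions, and the design choices.

## Worked example

```r
library(cytosig)

# a human-like cohort: 18 controls vs 18 cases (3 mild), 41 analytes,
# 8 planted case-up analytes at 1.5 SD (log scale)
cohort <- gen_cohort(synthetic_preset("human41", seed = 42))

fit <- cyto_pls(cohort$panel, target = "group", case = "MLIV")
summary(fit)
#> <cyto_pls> discriminant PLS, 36 samples x 41 analytes, 2 latent variables (rotated to LV1)
#>   case 'MLIV' (positive on LV1) vs 'CTRL'
#>   top |LV1| loadings: CK01 (+0.39), CK07 (+0.31), CK02 (+0.29), CK08 (+0.27), CK39 (+0.26)
#>   LV1 group means: CTRL -1.59, MLIV +1.59
#>   LV1 case-vs-control AUC: 1.000

prof <- lkocv_profile(cohort$panel, "group", case = "MLIV", K = 5,
                      n_iterations = 100, seed = 7)
prof
#> <stability_profile> 41 analytes, K = 5, 100 iterations (0 redraws)
#>  analyte   mean     sd     cv
#>     CK01  0.372 0.0347 0.0933
#>     CK07  0.297 0.0318 0.1071
#>     CK02  0.293 0.0352 0.1202
#>     ...
```

The LV1 profile separates the groups completely (AUC 1.000; group means
±1.59 on LV1), and the planted analytes (CK01–CK08 here) dominate the
loadings with low CVs — their contribution is stable against which
samples were drawn. Univariate follow-up per analyte, with Dunn's test
across control/typical/mild and Bonferroni adjustment within analyte:

```r
scr <- univariate_screen(cohort$panel, "subgroup")
head(scr[order(scr$p_adjusted), c("analyte", "group_a", "group_b", "statistic", "p_adjusted")], 3)
#>    analyte group_a      group_b statistic   p_adjusted
#> 16    CK06    CTRL MLIV-typical -4.168972 9.179306e-05
#> 13    CK05    CTRL MLIV-typical -4.159922 9.550692e-05
#> 4     CK02    CTRL MLIV-typical -3.888426 3.026894e-04
```

Negative Dunn z means higher concentrations in the typical-case group —
the planted direction. Cross-dataset transfer is a one-liner once two
panels share analyte names (or an `analyte_map`):

```r
tr <- transfer_signature(fit, other_panel, case = "KO")
tr$auc   # case-control separation of the projected LV1 scores
```

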