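# targetprops

Comparative analysis and prediction of **drug targetability** from protein
properties. Drug-target proteins differ from the rest of the proteome in
composition, physicochemistry, localization, modification and expression;
`targetprops` implements the complete workflow for quantifying those
differences and turning them into a classifier, for computational
biologists studying druggable proteomes:

* **Family-aware cohorts** — four nested target/non-target datasets
  (A: all proteins; B: one longest-CDS representative per gene family per
  label; C/D: non-targets from mixed-label families excluded), so paralog
  redundancy cannot inflate group differences.
* **Descriptors** (67 by default) — amino-acid and group composition,
  length, hydrophobic moment
  μH = √[(Σ Hᵢ sin iδ)² + (Σ Hᵢ cos iδ)²] (Eisenberg scale, window 10,
  δ = 100°), isoelectric point (bisection on the Henderson–Hasselbalch net
  charge), Wilkinson–Harrison solubility, PEST-region count, PTM
  proportions overall and on solvent-accessible residues, mean
  accessibility, expression level and tissue specificity
  τ = Σⱼ(1 − log₂S(j)/log₂S_max)/(n−1) over 79 tissues (floor 100),
  essentiality, EC classes, signal peptide, TM helices, a ten-term
  subcellular-location consensus (curated sources win; otherwise ≥ 3 of 5
  predictors must agree).
* **Screening** — chi-square (discrete) and Wilcoxon rank-sum (continuous)
  per feature, with BH q-values and a one-sided hypergeometric enrichment
  test for category tables.
* **Classification** — balanced downsampling, stratified k-fold CV with
  per-fold p < 0.05 feature selection and min–max scaling fit on training
  folds only (leakage-proof by construction and by test), a linear
  squared-hinge SVM (C = 1.3) and a 100-tree random forest
  (mtry = ⌊log₂(p+1)⌋), pooled recall/precision/F1.
* **Synthetic data** — a seeded generator with planted class effects
  (length 418 vs 342, signal-peptide rates 0.452 vs 0.226, enzyme rates
  0.571 vs 0.152, expression/τ shifts, exposure-biased PTMs, mixed-label
  families) plus a truth manifest, so the whole pipeline runs and is
  tested without any external database.

## Worked example

```r
library(targetprops)

b  <- generate_bundle(synthetic_config(n_target = 150, n_nontarget = 600,
                                       seed = 42))
build_datasets(b$records)
#> dataset_quad (targets / nontargets):
#>   A: 150 / 600
#>   B: 114 / 385
#>   C: 150 / 558
#>   D: 114 / 365

fm <- build_feature_matrix(b$records,
        list(annotations = b$annotations, ptm = b$ptm,
             accessibility = b$accessibility, expression = b$expression))
fm
#> feature_matrix: 750 proteins x 67 features (47 continuous, 20 discrete)

pt <- property_table(fm, b$records$label)
head(pt[order(pt$p_value),
        c("feature", "test", "p_value", "summary_target",
          "summary_nontarget")])
#>                    feature       test  p_value summary_target summary_nontarget
#> 47                expr_tau   wilcoxon 1.01e-67        0.38406           0.26562
#> 48               is_enzyme chi_square 1.16e-32        0.63333           0.16000
#> 39     ptm_phosphorylation   wilcoxon 2.25e-29        0.01990           0.01106
#> 42 ptm_phosphorylation_acc   wilcoxon 5.65e-26        0.01624           0.00891
#> 40      ptm_ubiquitination   wilcoxon 2.88e-18        0.00654           0.00344
#> 35          tm_helix_count   wilcoxon 2.15e-14        1.00000           0.00000

run_cv(fm, b$records$label, svm_config(), scheme = "5-fold", seed = 7)
#> cv_result (5-fold, seed 7): recall 0.9667  precision 0.9667  F1 0.9667
```

Dataset A→C keeps all 150 targets while dropping the 42 non-targets that
share a family with a target; the screen ranks the planted effects (tissue
specificity, enzyme status, PTM density) exactly where the generator put
them; and the cross-validated F1 of 0.97 reflects the strong planted
separation at this sample size. On null bundles
(`null_synthetic_config()`) the same protocol returns F1 ≈ 0.5.

The methods vignette (`vignettes/drug-target-properties.Rmd`) documents
the models, defaults, tie-breaks and the generator's scope.

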