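# emtscape

EMT signature scoring and immune landscape analysis for bulk tumor
transcriptomes.

Epithelial-mesenchymal transition (EMT) has been associated with immune
evasion and resistance to checkpoint immunotherapy in non-small cell lung
cancer. `emtscape` is for bioinformaticians who want to ask, on a z-scored
gene × sample expression matrix, whether mesenchymal-skewed tumors exclude
immune cells from their microenvironment — and to test every step of that
question against planted ground truth.

The pipeline:

1. **EMT score** per sample from a 16-gene canonical signature
   (3 epithelial: CDH1, DSP, TJP1; 13 mesenchymal: VIM, CDH2, FOXC2,
   SNAI1, SNAI2, TWIST1, FN1, ITGB6, MMP2, MMP3, MMP9, SOX10, GSC):

   EMT(s) = mean z(mesenchymal) − mean z(epithelial)

2. **Tertile groups**: the highest third ("mesenchymal") versus the lowest
   third ("epithelial"), split deterministically (base ⌊N/3⌋, remainder to
   high then mid — 515 samples → 172/172/171, 501 → 167/167/167).
3. **Infiltration calls**: per-sample single-sample enrichment of immune
   metagene signatures with a weighted Kolmogorov–Smirnov running-sum
   statistic (ES ∈ [−1, 1]), a gene-label permutation null, and
   Benjamini–Hochberg FDR across cell types within each sample; a cell
   type is *positively infiltrating* when ES > 0 and q ≤ 0.10.
4. **Group statistics**: chi-square on call counts and fold changes of
   infiltration fractions; Welch's t and OLS-on-EMT-score for cytokine and
   immune checkpoint panels; a CD8 T-cell score (mean z of CD8A, CD8B,
   IFNG, PRF1).
5. **Survival**: Kaplan–Meier curves and log-rank tests for the
   mesenchymal/epithelial contrast and the four EMT × activated-CD8-call
   subgroups.
6. **Synthetic cohorts**: `generate_cohort()` plants a latent EMT axis,
   coupled immune metagene blocks, binary infiltration events, panel
   shifts and censored survival so every stage is testable without access
   to tumor data.

## Worked example

```r
library(emtscape)

sim    <- generate_cohort(simulation_config(n_samples = 300, seed = 42))
emt    <- emt_score(sim$expression)
groups <- stratify_tertiles(emt)            # 100 / 100 / 100
enr    <- sample_enrichment(sim$expression, sim$cell_sets,
                            n_perm = 1000, seed = 43)
calls  <- call_infiltration(enr, q_threshold = 0.10)
land   <- landscape(calls, groups)
head(land[order(land$p), c("cell_type", "frac_high", "frac_low",
                           "fold_change", "p")], 5)
#>               cell_type frac_high frac_low fold_change        p
#> 1  Activated_CD8_T_cell      0.14     0.39       2.724 6.19e-05
#> 10   Gamma_delta_T_cell      0.36     0.13       0.370 1.56e-04
#> 5             Th17_cell      0.14     0.37       2.586 1.90e-04
#> 12                 MDSC      0.33     0.14       0.433 1.53e-03
#> 9      Activated_B_cell      0.30     0.12       0.410 1.78e-03
```

The default generator plants immune exclusion (coupling −0.6): activated
CD8 T cells and Th17 cells infiltrate 14% of mesenchymal tumors versus
37–39% of epithelial ones (fold change ≈ 2.6–2.7 in favour of epithelial),
while immunosuppressive γδ T cells, MDSCs and activated B cells show the
reverse — the directional pattern the pipeline is designed to detect.

```r
surv <- emt_survival_analysis(sim$clinical, groups, calls = calls)
surv$two_group$test$p    # 0.646  — no survival effect is planted
surv$four_group$test$p   # 0.487

truth_report(sim$truth, emt, calls = calls)
#> $emt_spearman        0.938   rank correlation, latent EMT vs score
#> $call_sensitivity    0.942   calls vs planted infiltration events
#> $call_specificity    0.985
```

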