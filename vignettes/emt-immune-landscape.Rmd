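---
title: "EMT scoring and the tumor immune landscape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMT scoring and the tumor immune landscape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtscape)
```

## The problem

Epithelial-mesenchymal transition (EMT) — the shift of tumor cells from an
adhesive epithelial phenotype toward a motile mesenchymal one — has been
linked to immune evasion and to resistance to checkpoint immunotherapy.
`emtscape` implements a transcriptome-level workflow for asking whether
mesenchymal-skewed tumors exclude immune cells from their microenvironment:
score each sample on an EMT signature, split the cohort into mesenchymal
and epithelial thirds, call per-sample immune cell infiltration from
metagene signatures, and contrast infiltration fractions, cytokine and
checkpoint expression, and overall survival between the groups.

All scores are defined on cohort-relative RNA-seq z-scores. The package
takes z-scores as given numbers; when raw expression is supplied,
`zscore_normalize()` standardises each gene with the sample standard
deviation (n − 1). Different providers compute z-scores against slightly
different references (all samples versus diploid samples), so scores
should be read as cohort-relative quantities.

## The EMT score and tertile groups

The signature has 3 epithelial markers (CDH1, DSP, TJP1 — TJP1 standing in
for OCLN, whose z-scores were unavailable in the cohorts the method was
developed on) and 13 mesenchymal markers. For sample $s$,

$$\mathrm{EMT}(s) = \frac{1}{13}\sum_{g \in \mathrm{mes}} z_{gs}
 \;-\; \frac{1}{3}\sum_{g \in \mathrm{epi}} z_{gs},$$

so positive scores are mesenchymal-skewed. The running text of the source
material names only ten of the thirteen mesenchymal genes; the packaged
fixture completes the canonical set with GSC, SNAI2 and TWIST1 and is
fully configurable through `emt_signature()`.

Cohorts are split into thirds by score, descending, ties broken by sample
identifier so the split is deterministic and independent of input order.
The base group size is $\lfloor N/3 \rfloor$; remainders go to the high
group first, then the mid group. This is the only remainder rule consistent
with both published splits: 515 samples give 172/172/171 and 501 samples
give 167/167/167. The mid tertile is excluded from all group contrasts;
the CD8 T-cell score (mean z of CD8A, CD8B, IFNG, PRF1) keeps its
"intermediate" third for descriptive use.

## Infiltration calls

The landscape requires a *per-sample* verdict for each immune cell type,
so enrichment runs in single-sample mode: each sample's genes are ranked
by z-score descending (ties by symbol), and each metagene set is scored
with the classic weighted Kolmogorov-Smirnov running sum — hits advance
the sum by $|z|^\alpha / \sum_{\mathrm{set}} |z|^\alpha$, misses retreat it
by $1/(N-k)$ — whose signed maximum deviation is the enrichment score
$\mathrm{ES} \in [-1, 1]$. An exact tie between the positive and negative
extreme (routine at $\alpha = 0$, where the statistic is rank-only)
resolves to the positive deviation.

Significance comes from a gene-label permutation null: random sets of the
same size drawn from the measured universe, scored on the same ranking.
Phenotype permutation is undefined for single-sample scoring, which is why
the gene-label null is used. The one-sided empirical p is
$(1 + \#\{\mathrm{ES}_\mathrm{null} \ge \mathrm{ES}\})/(1 + B)$, floored at
$1/(B+1)$; $B = 1000$ by default and a seed is mandatory, making call
matrices bit-reproducible. q-values are Benjamini-Hochberg across the cell
types within each sample (31 by default; a global scope across all
sample-set pairs is available), and a cell type is called *positively
infiltrating* when $\mathrm{ES} > 0$ and $q \le 0.10$.

Two numerical consequences of these defaults are worth knowing:

* With $B$ permutations the smallest attainable q in a sample is
  $31/(B+1)$ divided by the number of tests at the floor. At $B = 200$ a
  lone strong signal cannot clear $q \le 0.10$; the default $B = 1000$
  exists precisely so that single strong signals remain callable.
* As noise vanishes, $|z|^1$ weights concentrate entirely on the shifted
  genes and almost every random permutation set touches one of them, so
  the weighted null turns sharply conservative and sensitivity collapses.
  The rank-only mode ($\alpha = 0$) is immune to this and is the right
  choice for sharply bimodal data; $\alpha = 1$ is the default because
  z-scores with realistic noise are the intended input.

## Group statistics

Infiltration fractions are contrasted with the Pearson chi-square test on
the 2×2 call table (no continuity correction by default; Yates by flag),
and summarised as a fold change of fractions with a Haldane-Anscombe
pseudocount of 0.5 guarding zero counts. Cytokine and checkpoint panels
(16 cytokines; CD274, CTLA4, HAVCR2, ICOS, TNFRSF4, TNFRSF9, plus FASLG)
are contrasted with Welch's t-test and regressed on the EMT score with
ordinary least squares. Per-gene raw p-values reproduce the uncorrected
convention of the original analyses; a Benjamini-Hochberg column is
emitted alongside so either convention is available.

Overall survival uses the Kaplan-Meier product-limit estimator and the
k-sample log-rank test (`survival` package), with censoring ordered after
events at tied times. The two-group contrast compares mesenchymal versus
epithelial; the four-group contrast crosses EMT group with the
activated-CD8 infiltration call. Samples without survival data are dropped
before grouping, which is why survival n runs smaller than landscape n.
Empty subgroups are dropped with a warning and the degrees of freedom
adjusted. Cox modelling and hazard-ratio confidence intervals are out of
scope.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the pipeline is
meant to resolve, not RNA-seq counts. Each sample has a latent EMT level
$e_s \sim N(0,1)$. Gene means are:

* mesenchymal signature genes: $+\beta e_s$, epithelial: $-\beta e_s$,
  with `emt_effect` $\beta = 1$ by default — so in the small-noise limit
  the EMT score is affine in $e_s$ with slope $2\beta$;
* immune metagene blocks (31 disjoint sets of 20 genes): a coupling term
  $c \cdot e_s$ — `immune_coupling` $c$ for anti-tumor cell types
  (activated CD4/CD8 T cells, Th17, mature dendritic cells, ...), $+|c|$
  for immunosuppressive ones (Tregs, activated B cells, ...), 0 for
  neutral types — plus `infiltration_effect` (default 2 z-units) when the
  planted binary infiltration indicator fires. Indicators are independent
  Bernoulli draws at `base_infiltration_rate` 0.25; they exist because
  sensitivity/specificity of the boolean calls needs a boolean truth,
  which the continuous coupling alone cannot supply;
* cytokine/checkpoint genes: a per-gene shift times $e_s$, default 0.5
  for every panel gene except CD274, planted flat to mirror the null
  PD-L1 finding the method reproduces;
* CD8A/CD8B/PRF1 track the activated-CD8 block so the CD8 score is
  meaningful.

Unit Gaussian noise (`noise_sd`) is added everywhere; the matrix is
emitted as z-scores directly, since marginal normality is the natural
emulation of provider z-scores, and is deliberately *not* re-standardised
so planted slopes stay interpretable. Survival times are exponential with
log-hazards on the latent tertiles (defaults 0 — the null the original
survival analysis found) and independent exponential censoring calibrated
to the configured censoring rate (default 0.4). The defaults — 300
samples, coupling −0.6, 31 cell types — are the conditions under which a
cohort-scale immune-exclusion signal should be comfortably detectable
while single-seed contrasts remain honestly noisy.

What the generator does not emulate: count-level noise, tumor purity,
batch effects, correlated or overlapping metagene blocks, and non-Gaussian
marginals. Passing tests therefore demonstrate that the machinery recovers
planted structure under idealised noise, not that any biological claim
holds in real tumors.

## Problem sizes and numerical choices

The test suite exercises the pipeline at the sizes the analyses were
designed around where that is cheap (tertile splits at 501 and 515), and
at reduced but adequately powered sizes elsewhere: the FDR audit runs 200
samples × 31 cell types × 1000 permutations; the power study runs 100
seeds of 300-sample cohorts at 200 permutations per sample (within-sample
BH keeps single-seed calls attainable there because coupled cohorts carry
several hits per sample); oracle checks use exhaustive enumeration at
universes of ≤ 12 genes. Enrichment p-values are floored at $1/(B+1)$;
z-scoring treats constant genes as all-zero rows with a warning; duplicate
gene symbols collapse to the highest-variance row; gene symbols match
case-insensitively after whitespace trimming.

## Known limitations

* The immune metagene collection used in the original analyses is not
  redistributable; the packaged 31 synthetic disjoint blocks emulate its
  role and real collections are supplied as GMT. Whether the original
  aggregation from hundreds of signatures to 31 cell types involved
  combining sets is unknown; this package takes one set per cell type.
* Broad-tool GSEA normalised ES and its phenotype-permutation FDR are not
  reproduced, by design; the per-sample statistic here is the package's
  own, with its null and FDR scheme stated above.
* The alpha = 1 weighting degenerates when expression is nearly
  noiseless (see above).
* Chi-square contrasts assume the original infiltration comparison was of
  call counts; the source material does not state the quantification more
  precisely.
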