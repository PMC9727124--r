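---
title: "Methods: integrative immune transcriptomic classification of gastro-oesophageal adenocarcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative immune transcriptomic classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Advanced gastro-oesophageal adenocarcinoma (GEA) patients with a PD-L1
combined positive score (CPS) below 5 derive uncertain benefit from immune
checkpoint inhibitors (CPIs), and no established biomarker separates the
responders within that stratum. The premise of this package is that a
tumour's immune microenvironment should be read on two axes, not one: how
much immune infiltrate is present, and how functionally active that
infiltrate is. Crossing the two axes yields four profiles — IIL-FL, IIL-FH,
IIH-FL and IIH-FH (infiltrate low/high x function low/high) — of which the
infiltrate-rich, functionally active IIH-FH profile is the candidate
CPI-sensitive group.

`immunoclass` implements that classification and every analysis around it
as a tested pipeline, from a gene x sample expression matrix and
gene-signature collections through class labels, group statistics,
enrichment, survival screening, and the test of whether the class adds
response information beyond CPS. Because the original cohorts are not
publicly deposited, a synthetic-cohort generator with planted ground truth
stands in for them; every stage is validated against what was planted.

# The classification procedure

## Scores

Counts are first normalised against housekeeping genes, emulating
panel-style control normalisation. Each sample's scale factor $s_j$ is the
geometric mean of its housekeeping counts and values map as
$v \mapsto \log_2(1 + v\,\bar s/s_j)$ with $\bar s$ the cohort mean factor.
This form was chosen over the more common $\log_2((v+1)/s_j \cdot \bar s)$
deliberately: with the pseudocount inside the ratio, multiplying a whole
sample by a constant changes its normalised profile, whereas the form used
here is exactly invariant to per-sample library scaling whenever the
housekeeping genes scale with the sample. A pseudocount enters the scale
factor only if a housekeeping count is zero (with a warning).

Immune cell-type abundance is summarised by marker-mean scores: the score
of a signature in a sample is the arithmetic mean of the log2 expression of
the signature's genes present in the matrix (median available as an
option). An ESTIMATE-style immune score is computed by single-sample GSEA:
genes are ranked per sample (average ranks on ties), and the score is the
sum over the ranked list of the difference between the weighted in-set ECDF
(steps proportional to $\mathrm{rank}^\alpha$, default $\alpha = 0.25$) and
the unweighted out-of-set ECDF, without rank renormalisation by gene count.
The score is rank-based, hence invariant to any strictly monotone
per-sample transform; only the within-cohort ordering of scores is
meaningful, not their absolute magnitude.

## Two-level clustering

Both classification levels use the same primitive: agglomerative
clustering of samples cut at exactly two groups, Ward linkage on Euclidean
distances of row-z-scored data by default (complete linkage and correlation
distance are available to mimic common heatmap defaults). Determinism is a
design requirement — there is no random initialisation anywhere in the
classification, and all ties break by fixed documented rules.

* **Infiltrate level.** Samples are clustered on the cell-type score
  matrix; the cluster with the higher mean total cell score is IIH. An
  exact tie labels the smaller cluster IIH, with a warning.
* **Function level.** For each functional signature (T/NK/B-cell,
  macrophage and leucocyte function, cytokines, chemokines, interleukins,
  complement), samples are clustered on the submatrix of that signature's
  genes and the cluster with higher mean expression is "high". A sample is
  FH when strictly more than half of its per-signature labels are high; an
  exact tie resolves by the sign of the sample's mean z-score over all
  functional-signature genes. The alternative integration — one second-level
  two-group cut on the matrix of per-signature mean scores — is implemented
  behind `consensus = "two_level"`; the majority vote is the default
  because it is transparent, signature-balanced, and reproduces the planted
  truth as well as the second-level cut in simulation.

Function clustering runs cohort-wide rather than within the IIH stratum
only (a within-stratum reading of the source heatmaps is possible);
cohort-wide is the default because it treats both axes symmetrically and
keeps the FL/FH boundary comparable across infiltrate groups.

## Statistics across the classes

Checkpoint and immunomodulatory genes (PD1, PD-L1, CTLA4, HAVCR2, IDO1,
LAG3, TIGIT, TNFRSF4, BTK, TGFB, CDH1) are compared across the four classes
by Kruskal-Wallis tests with Benjamini-Hochberg adjustment across the gene
panel; BH is applied within each analysis family separately, mirroring
per-panel adjusted p-values.

Differential expression is deliberately **method-substituted**: instead of
a negative-binomial Wald model, the package uses a two-sided Wilcoxon
rank-sum test per gene with log2 fold change defined as the difference of
group means, at the same thresholds (BH-adjusted p < 0.05 and |log2FC| >
1). Re-implementing count-model dispersion shrinkage is out of scope, and
on log-scale data the rank test is assumption-light. The consequence is
stated wherever DE counts appear: the number of significant genes is
method-dependent and is validated against planted truth (sensitivity and
FDR), never against counts from count-model pipelines.

Over-representation uses the one-sided upper-tail hypergeometric test with
BH across sets. Preranked GSEA uses the weighted KS enrichment score
(weights $|\mathrm{stat}|$), a gene-label permutation null, NES normalised
by same-sign mean permuted ES, and the classic pooled same-sign FDR rule.
Gene-label permutation was chosen over phenotype permutation because the
class sizes this package targets (cohorts of a few dozen) are too small to
permute phenotypes meaningfully; the variant is recorded in the report
options.

## Survival screening

On platinum-exposed samples, an L1-penalised Cox model (Breslow ties,
coordinate descent via glmnet) is fitted over a log-spaced penalty path
from $\lambda_{max}$ down two decades, with tenfold cross-validated
partial-likelihood deviance selecting $\lambda$; folds are seeded and
stratified by event status so no fold is event-free. Features are
standardised internally and coefficients reported on the original scale.
When features outnumber samples the partial likelihood saturates at tiny
penalties and the solver truncates the tail of the path; this is expected
and does not affect the CV selection, which happens at larger penalties.

Genes retained by the penalty are dichotomised by maximally selected rank
statistics: the cutpoint maximising the standardised linear rank statistic
with log-rank (Nelson-Aalen) scores over candidate cutpoints (midpoints of
consecutive unique values within the 0.1-0.9 feature quantiles, avoiding
degenerate extreme splits; ties take the lower cutpoint). Inference on the
maximum is by a seeded permutation test (default 10,000 permutations of the
feature against survival) rather than the improved-Bonferroni
approximation: at cohort scale the permutation test is exact, free of
approximation-validity conditions, and costs little. The four classes are
compared by the K-group log-rank test with Kaplan-Meier step tables.

## Response beyond CPS

Association of the class with CPI response uses Fisher's exact test on the
2 x K response-by-class table (probability-mass rule for two-sidedness, the
convention of the canonical implementation). The added predictive value of
the class is the likelihood-ratio chi-square between nested logistic models
`response ~ CPS` and `response ~ CPS + class`, with df equal to the added
indicator terms. Suspected quasi-separation (diverging coefficients) is
flagged with a warning and the statistic still reported.

# The synthetic cohorts

The generator encodes the data-generating assumptions the analysis
targets, with defaults fixed once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| n_samples, n_genes | 60, 2000 | discovery-cohort scale |
| class proportions | 0.35/0.10/0.30/0.25 | IIL-FL/IIL-FH/IIH-FL/IIH-FH; IIL-FH rare |
| infiltrate_effect | 2.0 log2 | cell-type marker shift in IIH |
| function_effect | 1.5 log2 | functional-signature shift in FH |
| checkpoint_effect | 1.0 log2 | extra checkpoint-gene shift in IIH-FH |
| cdh1_effect | -1.5 log2 | CDH1 reduction in IIH-FH (EMT-consistent) |
| il18_effect | +120 pg/mL | plasma IL-18 shift in FH (baseline 300 +- 80) |
| noise_sd | 1.0 log2 | residual spread around gene means N(5, 1.5) |
| hazard_betas | +1 HLA-DQA1; -1 DUSP4, IRF4, CCRL2 | per-SD log-hazards |
| censoring_rate | 0.3 | independent exponential, calibrated |
| response_model | (-2.5, 0.3, 2.5) | logit intercept, CPS slope, IIH-FH effect |

Expression is Gaussian on the log2 scale (a counts mode with
negative-binomial noise, dispersion 0.2, and per-sample library factors
exists to exercise the normalisation); CPS is drawn from {0..4} because the
cohorts are CPS < 5 by design; PFS is exponential with log-hazard equal to
the weighted sum of standardised hazard-gene expression (baseline median
~8 months), censored by an independent exponential whose rate is solved to
hit the target censoring fraction. The response intercept and IIH-FH
coefficient were set so that a 45-patient validation cohort has about 27%
responders with roughly two thirds of them in IIH-FH, the regime of a
CPI-exposed validation cohort; the external-cohort generator additionally
drops the rare IIL-FH stratum (three observed classes) and guarantees both
response levels.

What the generator does **not** emulate: correlated gene-gene structure
beyond the planted class shifts, batch effects, probe chemistry,
count-depth heteroscedasticity tied to expression level, or dropout.
Passing the planted-recovery tests therefore shows the pipeline recovers
the structure it assumes, under Gaussian noise of realistic magnitude — not
that the four classes exist in any particular real cohort.

# Numerical choices and degenerate inputs

* All clustering, scoring and labelling is deterministic; the only
  stochastic stages (GSEA permutation, maxstat permutation, CV folds,
  cohort generation) take explicit seeds, and the pipeline derives
  per-stage seeds from one master seed by fixed offsets.
* Zero-variance rows are dropped (with a warning) before row z-scoring;
  all-tied genes get p = 1 rather than NaN; signatures matching no genes
  are dropped with warnings; stages with unmet preconditions are skipped
  with recorded reasons, never silently.
* Duplicate gene rows on input collapse by sum (counts) or mean (log2),
  logged; gene matching is exact, case-sensitive string equality — callers
  pre-harmonise identifiers.
* BH adjustment is monotone and dominates raw p-values but is *not*
  idempotent in general; tests assert the correct properties.

# Validation design and problem sizes

The test-suite validates each component against an independent route:
Fisher's exact test against exhaustive fixed-margin enumeration; the
penalised Cox path at vanishing penalty against an unpenalised Newton Cox
fit; maxstat against naive per-cutpoint recomputation; the logistic
log-likelihood against a hand-written Newton optimiser; GSEA enrichment
scores against a plain running-sum walk and against an independent
implementation (fgsea); ssGSEA at alpha = 0 against the unweighted KS
integral; BH and the hypergeometric tail against closed forms.

Calibration is checked by simulation at sizes chosen to finish in minutes
while keeping Monte-Carlo error small: 500 null simulations per test,
4-class recovery over 20 seeded cohorts of 60 samples x 2000 genes, DE
recovery over 20 simulations of 2000 genes at 15 vs 15 samples. Two
findings deserve note:

* **Exact-test discreteness.** Fisher p-values are uniform under the null
  only up to the coarseness of their support. With sparse responder
  margins the exact p is stochastically larger than uniform by
  construction, so the distributional uniformity check runs at balanced
  response margins, while the rejection-rate check runs on
  validation-size cohorts with permuted class labels.
* **Small-sample LRT.** The chi-square LRT for CPS + class vs CPS holds
  its 5% level in its asymptotic regime (measured size 0.049 at n = 200)
  but is anticonservative at the 45-patient validation scale (measured
  size ~0.09 with ~12 responders and 2 added df, with ~5% of fits
  quasi-separating). Calibration is therefore asserted at n = 200, and a
  significant LRT at n = 45 should be read with this caveat — which
  applies equally to any study using this test at that scale.

# Limitations

* The official vendor cell-type and functional signature memberships are
  not public; the shipped GMTs are representative marker sets, editable,
  and real analyses should supply the official sets as input.
* The DE statistic is a declared substitution (rank test), so DE gene
  counts are not comparable with count-model pipelines.
* The classifier assigns cohorts, not single samples: a new sample can
  only be classified by re-clustering it with a cohort.
* No batch correction is performed; inputs are assumed batch-corrected
  upstream.
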