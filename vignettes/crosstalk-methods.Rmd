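---
title: "Risk-pathway crosstalk and drug-combination screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-pathway crosstalk and drug-combination screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosspath)
```

# The model

`crosspath` treats a cancer as a network of *risk pathways* whose pairwise
coupling (crosstalk) is what therapy should disrupt. The pipeline has seven
stages; each is an exported function, and `analyze_cohort()` /
`run_pipeline()` chain them.

## Differential screening

Each mRNA and miRNA is tested between tumor and normal samples with an
unpaired, pooled-variance (Student's) *t*-test; Welch's form is available via
`var_equal = FALSE`. A feature is *differential* when all three hold:

* FDR < 0.01 (Benjamini–Hochberg, computed **within** molecule class —
  mRNAs and miRNAs are screened as separate datasets),
* |log2 FC| > 2,
* raw *p* < 0.05.

`compute_differential()` operates on the matrix scale it is given. For a
linear-scale bundle the fold change is `log2((mean_T + c)/(mean_N + c))`
with pseudocount `c = 1e-9` guarding division by zero; for a log2 bundle it
is the difference of group means. The pipeline always tests on the **log2
scale**: abundances are approximately log-normal, and on the linear scale
the *t*-test's variance estimate is dominated by the right tail, costing
power for no benefit. Degenerate rows (zero variance in both groups, equal
means) get *p* = 1 by convention; zero variance with unequal means gives an
infinite statistic and *p* = 0.

## Co-expression modules and risk factors

The differential features' expression is clustered in the WGCNA style:

* adjacency `a_ij = |cor(i,j)|^power` (unsigned by default; signed
  `((1+cor)/2)^power` available);
* the soft power is the smallest candidate (1–20) whose connectivity
  distribution reaches scale-free fit R² ≥ 0.8 **and** retains mean
  connectivity ≥ 1, else 6. The connectivity floor matters: raising the
  power shrinks every adjacency toward zero, and a near-empty network can
  pass the scale-free screen while carrying no clusterable structure;
* topological overlap (TOM) similarity, average-linkage clustering of
  1 − TOM, and a cut of the dendrogram at `cut_height` (default 0.5)
  **relative** position between the lowest and highest merge heights.
  An absolute cut is not transferable across data sets — TOM
  dissimilarities concentrate in roughly [0.8, 1] even for strong modules —
  whereas module-internal merges always occupy the bottom of the merge
  range and between-module merges the top, so a mid-range relative cut
  separates blocks wherever separable structure exists. Trees whose merge
  heights are all equal carry no structure and yield only the grey pool,
  as do clusters below `min_module_size` (default 10);
* each module's eigengene (first principal component of the standardized
  member submatrix, sign-oriented to follow mean member expression) is
  correlated with the phenotype (tumor = 1); modules with trait *p* <
  0.05 are cancer modules.

Risk mRNAs/miRNAs are the members of the selected module(s). Both a
`"top"` mode (single module with maximal |trait r|) and an
`"all-significant"` mode are provided; the pipeline defaults to
`"all-significant"` because a cancer's risk program routinely spans several
co-expression modules, and restricting to one module discards planted (and,
in real data, biologically coherent) risk factors.

## Pathway reconstruction and risk pathways

A pathway is an undirected graph of member mRNAs. A miRNA is attached when
its targets are over-represented among the pathway's mRNAs:
`m` = targets inside the pathway, `n` = targets in the background,
`M` = pathway size, `N` = background mRNA universe, with upper-tail
hypergeometric *p* = P(X ≥ m) evaluated through the log-space CDF.
We use the conventional inclusive tail P(X ≥ m) rather than the strict
P(X > m): the strict tail assigns *p* = 0 to any maximal overlap, which
would attach miRNAs whose evidence is a single shared gene in a tiny
pathway. Both tails are exposed (`tail = "ge"` / `"gt"`). Attached miRNAs
are linked only to their in-pathway targets; those edges are treated as
undirected interactions downstream.

Risk pathways are reconstructed pathways enriched for the cancer's risk
factors by the same cumulative hypergeometric test, with `M` and `n` now
counting mRNAs *and* miRNAs — accordingly the background `N` is the
expression universe of both kinds. Pathways with raw *p* < 0.05 are kept
(no multiple-testing correction, matching the screening character of the
step; BH is available behind `correct = TRUE`).

## Crosstalk

For risk pathways *i*, *j*, every unordered feature pair spanning them
(one endpoint in each, self-pairs excluded; a feature shared by both
pathways may still pair with other members of the opposite pathway) that
carries an interaction edge — PPI for mRNA–mRNA, miRNA-target for
miRNA–mRNA; miRNA–miRNA pairs have no interaction source and are not
scored — contributes

```
CS(a, b) = -(ln P(a) + ln P(b) + ln P(a, b))
```

with P(a), P(b) the **raw** differential *t*-test *p*-values (the FDR is a
set-level quantity; the formula names per-feature test significance) and
P(a, b) the two-sided *p*-value of the Pearson correlation of the two
expression rows, `t = r sqrt((n-2)/(1-r^2))` on *n* − 2 df. All three
inputs are clamped to `[1e-300, 1]`, so CS is finite and non-negative;
`Crosstalk(i, j) = Σ CS` and the total crosstalk sums over all pathway
pairs. Correlations use all samples by default (`cor_samples = "all"`);
tumor-only correlation is available, since restricting to tumor samples
removes the phenotype-driven component of co-expression at the cost of
half the observations.

## Drug screening

Removing a target set T deletes those mRNAs/miRNAs from every risk
pathway; with `cascade = TRUE` (default) an attached miRNA whose
in-pathway targets are all gone is deleted too (one pass reaches the
fixpoint, since removing a miRNA deletes no mRNA). The destruction score
is `DS = 1 − Crosstalk_after / Crosstalk_before ∈ [0, 1]`. Because CS
terms do not change under removal, `destruction_score()` re-scores the
cached contribution list (a pair survives iff its endpoints still span the
two pathways); the test suite verifies this equals a full rebuild.

Drugs with DS > 0.01 pass the single screen. All passing pairs are scored
on the union of their target sets and *selected* when
`DS(T1 ∪ T2) ≥ DS(T1) + DS(T2)` within tolerance 1e-9 (criterion `"ge"`;
`"gt"` available). Without the cascade this criterion can only be met with
equality: destroyed pair sets satisfy
`destroyed(T1 ∪ T2) = destroyed(T1) ∪ destroyed(T2)`, so DS is subadditive
— a law the test suite checks on hundreds of random fixtures. Strict
superadditivity is therefore *exactly* the cascade phenomenon: a pathway
miRNA orphaned only by the union takes its own crosstalk terms with it.
That is why cascade removal defaults to on, and why the selection
criterion is ≥ rather than >: with > and no cascade, nothing could ever be
selected.

## Survival validation

The top selected combination's targets — restricted to features of the
pathway pairs whose crosstalk the combination changed — define a
signature. Tumor samples are standardized per feature (log2 scale),
clustered by k-means (k = 2, 10 seeded restarts; with exactly k samples
each sample is its own group), the group with the smaller Kaplan–Meier
median survival is labeled high-risk (ties toward the first group), and
the two groups are compared by the standard two-group log-rank χ² (1 df).

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fdr_threshold` | 0.01 | BH FDR cutoff, per molecule class |
| `lfc_threshold` | 2 | abs. log2 fold-change cutoff |
| `p_threshold` | 0.05 | raw *t*-test cutoff |
| `min_module_size` | 10 | smallest retained module |
| `cut_height` | 0.5 | relative dendrogram cut position |
| `module_alpha` | 0.05 | module-trait significance |
| `module_mode` | all-significant | module selection mode |
| `recon_alpha` | 0.05 | miRNA attachment threshold |
| `risk_alpha` | 0.05 | risk-pathway threshold |
| `ds_threshold` | 0.01 | single-drug DS pass level |
| `combo_criterion` | ge | superadditivity comparison |
| `cascade` | TRUE | orphaned-miRNA removal |
| `cor_samples` | all | samples used for correlations |
| `seed` | 1 | root seed (k-means restarts) |

# The synthetic cohort

`generate_cohort()` draws log2-scale expression from a latent-factor
Gaussian model and exponentiates to linear scale. A differential feature in
module *m* is

```
x = mu + s * (effect/2) * pheno + s * h_m + noise,   pheno in {+1 tumor, -1 normal}
```

with `s = +1` for mRNAs and `-1` for miRNAs — so every planted miRNA–target
edge joins anti-correlated features — and `sd(h_m)` solved so that
within-module pairwise correlation hits `within_module_rho` (default 0.8).
Note a floor: with an effect of 3 log2 units and unit noise, the phenotype
shift alone induces |cor| ≈ 0.69 between *any* two differential features
(pheno variance `(3/2)² = 2.25` against total `3.25`); a within-module
target of 0.7 would leave no between/within contrast at all, which is why
the default sits at 0.8 and module structure should not be expected below
~0.75 at this effect size.

Planted structure: 4 of 20 pathways draw ~70% of their members from the
differential mRNAs, ~60% of those from one *dominant* module each; each
differential miRNA is homed in the pathway matching its module, with 5
same-module in-pathway targets and one target in another planted pathway;
PPI bridge edges (20 per planted pathway pair, weighted toward the cascade
miRNA's targets) plus 300 random background edges. Drugs:
`drug_synA`/`drug_synB` split the cascade miRNA's 5 home targets 3/2 —
their union, and only the union, orphans it (the generator excludes PPI
edges inside that target set, since such an edge would be destroyed by both
halves and push the pair toward subadditivity); `drug_addC`/`drug_addD`
take single targets chosen to share no interacting pair (exact additivity,
probing the ≥ boundary); three moderate drugs take single "quiet" targets
(members of exactly one planted pathway); `drug_null` targets pathway-free
mRNAs. Survival is exponential with log-hazard `survival_beta` (default 1)
times the latent risk score of the combination signature (mean
sign-corrected standardized log2 expression over tumor samples), censored
uniformly on 200–2500 days (~35% censoring); baseline median 730 days.

What it does **not** emulate: batch effects, copy-number or purity
confounding, count-level mean–variance structure, realistic KEGG topology
or hub-dominated PPI degree distributions, drug polypharmacology beyond the
listed target sets. Passing the planted-truth tests shows the pipeline's
machinery recovers the signals it defines — not that the thresholds are
optimal for TCGA-scale data.

# Numerical choices

* Hypergeometric tails via the log-space CDF, exact for all testable sizes
  (verified against direct PMF enumeration for every N ≤ 12).
* *p*-value clamp `eps = 1e-300`; fold-change pseudocount `1e-9`.
* Correlation *p* from the closed-form *t*; |r| = 1 maps to *p* = 0 (then
  clamped); constant vectors give r = 0, *p* = 1.
* Eigengenes via SVD of the standardized submatrix; size-1 modules use the
  standardized feature itself.
* K-means is the only stochastic stage; it is seeded from the pipeline
  configuration, so full runs are byte-identical.
* Degenerate inputs degrade explicitly: fewer than 2 risk pathways yields
  an empty crosstalk network (warning); zero total crosstalk stops drug
  scoring with an error ("no crosstalk to destroy"); unknown drug-target
  ids are ignored.

# Problem sizes used by the tests

The suite exercises the default cohort (500 mRNAs, 50 miRNAs, 40 + 40
samples, 20 pathways, 8 drugs) across seeds 1–5, 100 random small fixtures
(≤ 8 features per pathway) against a brute-force crosstalk oracle, ~200
random target-set splits for the subadditivity law, 1000-replicate null
simulations for *t*-test and log-rank calibration, and exhaustive
hypergeometric enumeration to N = 12. These sizes make every planted
mechanism measurable while the whole suite runs in well under test-budget
time on one CPU.

# Known limitations

* Crosstalk scores are sums, so they grow with pathway size and edge
  density; no significance test or size normalization is attempted (the
  screen compares relative destruction, which divides the scale out).
* The superadditivity mechanism is the miRNA cascade by construction;
  other biological sources of synergy (dose response, pathway rewiring)
  are out of scope.
* Gene identifiers are opaque case-sensitive strings; no symbol
  normalization is performed.
* Only pairs of drugs are screened; the combinatorics of triples and the
  modeling of toxicity/pharmacokinetics are out of scope.
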