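---
title: "Methods: dynamic-threshold rule mining and TOPSIS ranking for paired omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic-threshold rule mining and TOPSIS ranking for paired omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momarules)
```

## The problem and the model

DNA methylation generally represses transcription, so genes that are
simultaneously differentially expressed and (oppositely) differentially
methylated between two sample groups are strong candidates for a regulatory
signature.  `momarules` mines *directional association rules* over such
genes: each sample becomes a market-basket transaction whose items are
`GENE+` (up-regulated *and* hypo-methylated in that sample) or `GENE-`
(down-regulated *and* hyper-methylated), and a rule such as
`STAT3+, TP53- -> MAPK3+` asserts that the antecedent states make the
consequent state likely.

The pipeline has five stages.

1. **Preprocessing.** Genes and samples are matched across the expression
   and methylation matrices, each gene row is zero-mean centred, and a
   moderated two-group t-test with empirical-Bayes variance shrinkage is run
   per probe on each layer.  The shrinkage prior $(d_0, s_0^2)$ is fitted by
   method of moments on the log sample variances; the posterior variance is
   $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and the moderated t carries
   $d + d_0$ degrees of freedom (capped at the summed residual df when the
   prior df is infinite).  P-values are BH-adjusted; per gene, the probe
   with the smallest adjusted p is retained (ties to the lexicographically
   smallest probe ID).  A gene survives iff its adjusted p is strictly below
   `alpha` in *both* layers *and* it appears in the protein–protein
   interaction (PPI) edge list.

2. **Discretization.** On the centred data, expression $>0$ codes 1 (up)
   and methylation $<0$ codes 1 (hypo).  The two binary matrices merge into
   a samples × 2n matrix: concordant $(1,1)$ sets the `+` item, concordant
   $(0,0)$ sets the `-` item, discordant states set neither — a gene never
   contributes both items to one transaction.  Empty transactions are kept
   and count in every support denominator.

3. **Network distances.** For every surviving gene pair the combined
   similarity is the product of the expression correlation, a functional
   similarity in $[0,1]$ (default all ones) and the methylation correlation,
   min–max normalized over all off-diagonal pairs into $[0,1]$.  Its
   complement is a dissimilarity, masked by the PPI adjacency
   ($w_{pq} = H_{pq}\,(1 - \mathrm{CECM}_{pq})$), and Dijkstra's algorithm
   yields the all-pairs weighted shortest distance WeSD.

4. **Dynamic-threshold mining.** FP-growth enumerates frequent directional
   gene sets at the user support `ud_min_s`.  Each pair gets a
   distance-modulated threshold
   $WV(p,q) = U \left(1 - c_1 \frac{\mathrm{WeSD}(p,q) - \mathrm{med}}
   {c_2\,\mathrm{MAD}}\right)$
   (clamped at 0, $U$ on the diagonal), and each gene set the mean of $WV$
   over its unordered gene pairs.  Sets must meet their own dynamic support
   cutoff; rules — *every* non-empty bipartition of a surviving set — must
   meet the set's dynamic confidence and lift cutoffs.  Tightly connected
   sets therefore face cutoffs *above* the user threshold, distant sets
   milder ones.

5. **TOPSIS ranking.** Each rule is scored on four criteria: support,
   confidence, lift (benefit) and the mean WeSD over its genes (cost).  The
   positive/negative ideal solutions take the per-criterion best/worst,
   city-block distances $d^+, d^-$ are computed with absolute differences,
   and the relative closeness $S = d^-/(d^+ + d^-)$ ranks the rules in
   descending order.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | BH-adjusted significance cutoff, strict `<`, both omics layers |
| `ud_min_s` | 0.3 | user minimum support (fraction of transactions; absolute count with `count_based_support`) |
| `ud_min_c` | 0.5 | user minimum confidence |
| `ud_min_l` | 1 | user minimum lift (1 = independence) |
| `c1` | 0.10 | damping of the distance deviation in the dynamic thresholds |
| `c2` | 1.4826 | Gaussian consistency constant for the MAD (belongs with the MAD, so the unscaled MAD is used) |
| `max_itemset_size` | 4 | largest mined gene set (the largest set observed in published reference rule tables) |
| `topsis$normalization` | `"none"` | raw criteria by default; `"minmax"`, `"vector"` available |
| `topsis$orientation` | `"classical"` | `S = d^-/(d^+ + d^-)`; `"literal"` flips the numerator |
| `topsis$closeness_threshold` | none | final-rule flag; no default is imposed |

`ud_min_s = 0.3` and `ud_min_c = 0.5` are conventional mid-range mining
defaults for two-group designs in which a genuine differential module
appears in roughly half the samples per direction; they are deliberately
ordinary values, not calibrated against any test outcome.

## What the synthetic generator emulates — and what it does not

`generate_paired_omics()` emulates the structure of a two-group sarcoma
multi-omics study: 13 case and 13 control samples, matched genes across
layers, and `n_modules` planted modules of co-directional genes.  A planted
"up-hypo" gene has its expression shifted by `effect_size × noise_sd`
(default 4 SD) in cases and its methylation shifted by the same amount in
the *opposite* direction, so expression and methylation are anti-correlated
as methylation-driven regulation predicts.  Module genes form PPI cliques;
background pairs get sparse Erdős–Rényi edges (density 0.02).  Noise is
Gaussian and gene-wise independent — the simplest model consistent with
zero-mean per-gene centring.

Deliberately *not* emulated: realistic methylation beta-value
distributions, batch effects, correlated background noise, and probe-level
artefacts beyond a simple k-probes-per-gene replication.  A green test on
this generator therefore establishes that the algorithmic chain recovers
planted co-directional PPI-connected modules under Gaussian noise; it says
nothing about robustness to array normalization artefacts or confounding
in real cohorts.

## Numerical choices and degenerate inputs

* **Similarity normalization.** The correlation product can be negative
  while the combined similarity is defined on $[0,1]$; min–max
  normalization over the off-diagonal pairs is the only reading that
  satisfies both, so the most anti-similar pair maps to 0.  A constant
  product matrix (no spread) maps to 0.5 with a warning.  Zero-variance
  rows get correlation 0 with a warning.
* **Exact zeros at discretization** map to 0 in both layers: centring a
  constant row yields zeros, and those must not fabricate items.
* **Unreachable gene pairs** are excluded from the median/MAD, fall back to
  the user threshold in $WV$, and contribute the maximum finite distance in
  a rule's average WeSD — neutral behaviour when no distance evidence
  exists.  A degenerate spread (MAD = 0) reverts every pairwise threshold
  to the user value, which provably reduces the whole dynamic pipeline to
  classical static-threshold mining (this reduction is asserted in the
  acceptance suite).
* **Distances with cost criteria.** Summing signed differences to an ideal
  that *minimizes* a criterion can go negative, contradicting "distance";
  absolute differences are used.  Similarly the closeness with $d^+$ in the
  numerator would rank the *worst* alternative first under descending
  order, so the classical $d^-/(d^+ + d^-)$ is the default and the literal
  form sits behind `orientation = "literal"`.
* **Ties at ranking** break by higher support, then higher confidence, then
  the lexicographically smallest rule string — ranking is a deterministic
  permutation, invariant to input order.
* **Thresholds are inclusive** (`>=`) for support, confidence and lift, and
  the significance cutoff is strict (`<`), matching the conventions of the
  procedure being implemented.

## Design decisions that were genuinely open

* The published relative-score column (0.3228–0.36) could not be mapped to
  any normalization/distance variant of the equations; the package
  reproduces the published *ranking* from the published scores exactly (a
  fixture test) but does not attempt to match the score magnitudes.  With
  `build_decision_matrix()` + `topsis_distances()` the variants are exposed
  for exploration.
* Published reference tables report lifts far below 1 alongside a lift
  cutoff of 1; the standard definitions (lift = confidence / consequent
  support) are implemented and no attempt is made to reverse-engineer that
  scale.
* The differential test runs on normalized data (normalize, then test):
  centring leaves the group contrast and row variances untouched, so the
  ordering is immaterial for the statistics but keeps a single data object
  flowing through the pipeline.
* Probe handling: probes with any missing value are dropped before
  testing; per gene the minimum-adjusted-p probe is kept.

## Known limitations

* Two-group designs only; no covariates, no multi-class contrasts.
* The moderated test matches a specific well-known implementation to
  numerical tolerance on shared fixtures, but no claim is made for exotic
  inputs (e.g. majority-zero-variance matrices).
* Rule enumeration is exponential in the itemset size; `max_itemset_size`
  (default 4) bounds it, and the miner is pure R — adequate for the tens of
  genes that survive a two-omics significance intersection, not for
  thousands of items.
* The nearest-shrunken-centroid evaluator uses expression features only by
  default (`use_methylation = TRUE` appends the methylation rows); its
  absolute accuracies on real cohorts are not comparable to published
  values obtained on protected data.

Every empirical statement above is recomputed by the test suite
(`tests/testthat/`, notably `test-acceptance.R`) or by
`scripts/acceptance.R`; neither this vignette nor the README quotes numbers
the code does not produce.
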